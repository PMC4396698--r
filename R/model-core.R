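#' Empirical-Bayes hyperparameters for the mixture model
#'
#' Centres and scales the priors on the observed (normalised) exposures:
#' `m0` is the vector of column means, `Sigma0` a diagonal matrix of squared
#' column ranges, and the Wishart scale `Phi` is built from the per-column
#' empirical variances as `diag(1 / variance) / P` (so the prior expectation
#' of each precision `Q_k` is `nu * Phi = diag(1/variance)` with `nu = P`).
#' A full-covariance alternative `Phi = solve(cov(z)) / P` is available via
#' `phi_mode = "full"`.
#'
#' @param z a [normalize_exposures()] result or a numeric matrix (missing
#'   entries allowed; statistics use observed entries only).
#' @param a,b shape and rate of the Gamma prior on the Dirichlet-process
#'   concentration `alpha` (defaults 2 and 1).
#' @param phi_mode `"diagonal"` (default) or `"full"`.
#' @param mu_df,mu_scale Student-t prior on the cluster log relative risks
#'   (defaults 7 and 2.5, mirroring the spline-coefficient prior).
#' @param beta_df,beta_scale Student-t prior on spline coefficients
#'   (defaults 7 and 2.5).
#' @param tau_shape,tau_rate Gamma prior on the precision of the day-level
#'   effect `eps_t` (defaults 5 and 0.5, weakly informative on the scale of
#'   daily log-rate variation).
#' @return object of class `profreg_hyper`.
#' @export
empirical_hyperparams <- function(z, a = 2, b = 1,
                                  phi_mode = c("diagonal", "full"),
                                  mu_df = 7, mu_scale = 2.5,
                                  beta_df = 7, beta_scale = 2.5,
                                  tau_shape = 5, tau_rate = 0.5) {
  phi_mode <- match.arg(phi_mode)
  zm <- if (inherits(z, "normalized_exposures")) z$z else as.matrix(z)
  P <- ncol(zm)
  m0 <- colMeans(zm, na.rm = TRUE)
  rng <- apply(zm, 2, function(x) diff(range(x, na.rm = TRUE)))
  v <- apply(zm, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(rng)) || any(rng == 0) || any(!is.finite(v)) || any(v == 0))
    stop("degenerate column: zero empirical range or variance")
  if (any(colSums(!is.na(zm)) < 2))
    stop("every column needs at least 2 observed values")
  Phi <- if (phi_mode == "diagonal") diag(1 / v, P) / P
         else chol2inv(chol(stats::cov(zm, use = "pairwise.complete.obs"))) / P
  structure(list(
    m0 = m0,
    Sigma0 = diag(rng^2, P),
    Phi = Phi,
    nu = P,
    a = a, b = b,
    mu_df = mu_df, mu_scale = mu_scale,
    beta_df = beta_df, beta_scale = beta_scale,
    tau_shape = tau_shape, tau_rate = tau_rate,
    P = P, phi_mode = phi_mode
  ), class = "profreg_hyper")
}

#' Stick-breaking weights
#'
#' `w_1 = V_1`, `w_k = V_k * prod_{i<k} (1 - V_i)`.  The unassigned mass
#' after `K` sticks is exactly `prod_{k<=K} (1 - V_k)`.
#'
#' @param V break proportions in `(0, 1]`.
#' @return weight vector of the same length.
#' @export
stick_breaking <- function(V) {
  if (!length(V)) return(numeric(0))
  if (any(V <= 0) || any(V > 1)) stop("stick breaks must lie in (0, 1]")
  V * cumprod(c(1, 1 - V[-length(V)]))
}

# log density of the scaled Student-t prior used for beta and mu.
dst_log <- function(x, df, scale) {
  stats::dt(x / scale, df = df, log = TRUE) - log(scale)
}

# Multivariate normal log density rows of Z (complete), precision Q with
# upper Cholesky factor R (Q = R'R) and log|Q|.
mvn_logdens_rows <- function(Z, m, R, logdetQ) {
  ZR <- Z %*% t(R)                     # quadratic form via ||R z - R m||^2
  b <- drop(R %*% m)
  q <- rowSums(ZR * ZR) - 2 * drop(ZR %*% b) + sum(b * b)
  -0.5 * ncol(Z) * log(2 * pi) + 0.5 * logdetQ - 0.5 * q
}

#' Multivariate normal log density with missing-coordinate marginalisation
#'
#' Evaluates `-(P/2) log 2pi + 0.5 log|Q| - 0.5 (z-m)' Q (z-m)` in the
#' cluster parameterisation by precision `Q`.  When `z` has missing entries
#' the marginal density of the observed sub-vector is used (covariance
#' `solve(Q)[obs, obs]`), which is how days with missing measurements enter
#' the allocation step.
#'
#' @param z numeric vector of length `P` (entries may be `NA`) or a `T x P`
#'   matrix of rows to evaluate.
#' @param m mean vector.
#' @param Q positive-definite precision matrix.
#' @return log density (vector if `z` is a matrix).
#' @export
mvn_logdensity <- function(z, m, Q) {
  R <- chol_pd(Q, "precision matrix is singular or not positive-definite")
  if (is.matrix(z) && !anyNA(z)) {
    return(mvn_logdens_rows(z, m, R, 2 * sum(log(diag(R)))))
  }
  one <- function(zt) {
    obs <- which(!is.na(zt))
    if (!length(obs)) return(0)                     # fully missing: no info
    if (length(obs) == length(zt)) {
      zc <- zt - m
      return(-0.5 * length(zt) * log(2 * pi) + sum(log(diag(R))) -
               0.5 * sum((R %*% zc)^2))
    }
    Sigma <- chol2inv(R)
    Ro <- chol_pd(Sigma[obs, obs, drop = FALSE])
    zc <- zt[obs] - m[obs]
    -0.5 * length(obs) * log(2 * pi) - sum(log(diag(Ro))) -
      0.5 * sum(backsolve(Ro, zc, transpose = TRUE)^2)
  }
  if (is.matrix(z)) apply(z, 1, one) else one(z)
}

#' Poisson log-rates and log-likelihood of the response
#'
#' `log lambda_t = log E_t + mu_{g_t} + (U beta)_t + eps_t`; the
#' log-likelihood is `sum_t y_t log lambda_t - lambda_t - log y_t!`.
#'
#' @param y counts.
#' @param offset positive offset vector `E_t`.
#' @param mu_alloc length-`T` vector of the allocated cluster's log relative
#'   risk, `mu_{g_t}`.
#' @param design_contribution length-`T` vector `(U beta)_t` (0 if none).
#' @param eps length-`T` day-level effects (0 if none).
#' @return list with `log_lambda` and `loglik`.
#' @export
poisson_logrates <- function(y, offset, mu_alloc,
                             design_contribution = 0, eps = 0) {
  log_lambda <- log(offset) + mu_alloc + design_contribution + eps
  if (any(!is.finite(log_lambda))) stop("non-finite Poisson log-rate")
  list(log_lambda = log_lambda,
       loglik = sum(stats::dpois(y, exp(log_lambda), log = TRUE)))
}

# log Wishart density W(Phi, nu) at Q (both PD); standard parameterisation
# E[Q] = nu * Phi.
log_dwishart <- function(Q, Phi, nu) {
  P <- ncol(Q)
  Rq <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(Rq)) return(-Inf)
  Rp <- chol(Phi)
  lmvg <- sum(lgamma((nu + 1 - seq_len(P)) / 2)) +
    P * (P - 1) / 4 * log(pi)
  ldQ <- 2 * sum(log(diag(Rq)))
  ldPhi <- 2 * sum(log(diag(Rp)))
  tr <- sum(chol2inv(Rp) * Q)
  0.5 * (nu - P - 1) * ldQ - 0.5 * tr -
    nu * P / 2 * log(2) - nu / 2 * ldPhi - lmvg
}

#' Joint log prior of a model state
#'
#' Sums the log prior densities of all instantiated components: Normal on
#' cluster locations, Wishart on cluster precisions, Student-t on the log
#' relative risks and spline coefficients, Beta(1, alpha) on the stick
#' breaks, Gamma(a, b) on alpha, Normal(0, sigma_eps^2) on the day effects
#' and Gamma on the day-effect precision.  Parameters outside their support
#' give `-Inf` rather than an error.
#'
#' @param state a model state as stored in a chain: list with `V`, `m`
#'   (K x P), `Q` (list of K precisions), `mu`, `beta`, `eps`, `sigma_eps`,
#'   `alpha`.
#' @param hyper a [empirical_hyperparams()] object.
#' @return scalar log prior density.
#' @export
log_prior <- function(state, hyper) {
  K <- length(state$mu)
  if (state$alpha <= 0 || state$sigma_eps <= 0) return(-Inf)
  if (any(state$V <= 0) || any(state$V >= 1)) return(-Inf)
  lp <- sum(stats::dbeta(state$V, 1, state$alpha, log = TRUE)) +
    stats::dgamma(state$alpha, hyper$a, rate = hyper$b, log = TRUE)
  sd0 <- sqrt(diag(hyper$Sigma0))          # Sigma0 is diagonal by construction
  for (k in seq_len(K)) {
    lp <- lp + sum(stats::dnorm(state$m[k, ], hyper$m0, sd0, log = TRUE))
    lw <- log_dwishart(state$Q[[k]], hyper$Phi, hyper$nu)
    if (!is.finite(lw)) return(-Inf)
    lp <- lp + lw
    lp <- lp + dst_log(state$mu[k], hyper$mu_df, hyper$mu_scale)
  }
  lp <- lp + sum(dst_log(state$beta, hyper$beta_df, hyper$beta_scale))
  tau <- 1 / state$sigma_eps^2
  lp <- lp + sum(stats::dnorm(state$eps, 0, state$sigma_eps, log = TRUE)) +
    stats::dgamma(tau, hyper$tau_shape, rate = hyper$tau_rate, log = TRUE)
  lp
}
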