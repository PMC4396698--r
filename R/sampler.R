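#' MCMC configuration
#'
#' Defaults mirror the analysis settings of the London application: 70,000
#' sweeps, 20,000 discarded as burn-in and 1-in-10 thinning, giving 5000
#' stored posterior draws.  `mcmc_config_small()` is the scaled-down
#' configuration used for simulation benchmarks (10,000 / 3,000 / 5).
#'
#' @param n_iter total sweeps.
#' @param burn_in sweeps discarded (must be `< n_iter`).
#' @param thin keep one state every `thin` post-burn-in sweeps.
#' @param init_clusters number of clusters used to initialise allocations
#'   (k-means on the exposure profiles).
#' @param seed integer seed; the chain is a deterministic function of it.
#' @param rho decay of the deterministic slice levels
#'   `xi_k = (1 - rho) rho^(k-1)`, in (0, 1).
#' @param prop_mu,prop_beta,prop_eps initial random-walk proposal s.d. for
#'   the log relative risks, spline coefficients and day effects.
#' @param adapt_batch proposal scales are tuned towards 44% acceptance in
#'   batches of this many sweeps, during burn-in only.
#' @param label_moves character subset of `c("pair", "neighbour")` selecting
#'   which label-switching moves run each sweep (default both).
#' @param disable_likelihood if `TRUE` all data terms are removed so the
#'   sampler targets the prior (used for prior-recovery validation).
#' @param fix_alpha optional fixed value for the DP concentration
#'   (disables its Gibbs update).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 70000L, burn_in = 20000L, thin = 10L,
                        init_clusters = 10L, seed = 1L, rho = 0.75,
                        prop_mu = 0.1, prop_beta = 0.02, prop_eps = 0.5,
                        adapt_batch = 50L,
                        label_moves = c("pair", "neighbour"),
                        disable_likelihood = FALSE,
                        fix_alpha = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (isFALSE(label_moves)) label_moves <- character(0)
  stopifnot(all(label_moves %in% c("pair", "neighbour")))
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 init_clusters = as.integer(init_clusters),
                 seed = as.integer(seed), rho = rho,
                 prop_mu = prop_mu, prop_beta = prop_beta,
                 prop_eps = prop_eps, adapt_batch = as.integer(adapt_batch),
                 label_moves = label_moves,
                 disable_likelihood = isTRUE(disable_likelihood),
                 fix_alpha = fix_alpha),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... overrides passed on to [mcmc_config()].
#' @export
mcmc_config_small <- function(seed = 1L, ...) {
  mcmc_config(n_iter = 10000L, burn_in = 3000L, thin = 5L, seed = seed, ...)
}

# ---------------------------------------------------------------------------
# Closed-form full conditionals (used by the sampler and directly testable).

# Beta conditional of stick k: V_k | g ~ Beta(1 + n_k, alpha + sum_{j>k} n_j)
cond_sticks <- function(n, alpha) {
  list(shape1 = 1 + n, shape2 = alpha + sum(n) - cumsum(n))
}

# alpha | V ~ Gamma(a + K+, b - sum_{k<=K+} log(1 - V_k))
cond_alpha <- function(V, a, b) {
  list(shape = a + length(V), rate = b - sum(log1p(-V)))
}

# m_k | rest: Normal with precision Sigma0^-1 + n Q and mean
# prec^-1 (Sigma0^-1 m0 + Q sum(z_i))
cond_location <- function(zsum, n, Q, m0, Sigma0inv) {
  prec <- Sigma0inv + n * Q
  R <- chol(prec)
  mean <- backsolve(R, forwardsolve(t(R), Sigma0inv %*% m0 + Q %*% zsum))
  list(mean = drop(mean), precision = prec, chol_precision = R)
}

# Q_k | rest: Wishart(scale = (Phi^-1 + S)^-1, df = nu + n)
cond_precision <- function(S, n, PhiInv, nu) {
  list(scale = chol2inv(chol(PhiInv + S)), df = nu + n)
}

# tau_eps | eps ~ Gamma(shape + T/2, rate + sum(eps^2)/2)
cond_tau <- function(eps, shape, rate) {
  list(shape = shape + length(eps) / 2, rate = rate + sum(eps^2) / 2)
}

# ---------------------------------------------------------------------------
# State handling.  The state lives in an environment mutated in place by the
# update functions; this keeps the sweep loop allocation-light.

make_state <- function(y, Z, U, E, hyper, config) {
  st <- new.env(parent = emptyenv())
  st$y <- y; st$Z <- Z; st$U <- U; st$E <- E; st$logE <- log(E)
  st$T <- length(y); st$P <- ncol(Z); st$H <- ncol(U)
  st$hyper <- hyper; st$rho <- config$rho
  st$nolik <- config$disable_likelihood
  st$miss <- is.na(Z)
  st$any_miss <- any(st$miss)
  # missingness patterns are fixed for the whole run
  if (st$any_miss) {
    # prefix the key: "" is not a matchable list name in R
    key <- apply(st$miss, 1,
                 function(r) paste0("m", paste(which(r), collapse = ",")))
    rows_by_key <- split(seq_len(st$T), key)
    st$complete_rows <- rows_by_key[["m"]] %||% integer(0)
    mk <- setdiff(names(rows_by_key), "m")
    st$patterns <- lapply(mk, function(k) {
      mis <- as.integer(strsplit(sub("^m", "", k), ",")[[1]])
      rows <- rows_by_key[[k]]
      obs <- setdiff(seq_len(st$P), mis)
      list(rows = rows, mis = mis, obs = obs,
           # transposed observed block, precomputed: columns are days
           tZ = t(Z[rows, obs, drop = FALSE]))
    })
  } else {
    st$complete_rows <- seq_len(st$T)
    st$patterns <- list()
  }
  st$pat_of <- integer(st$T)               # 0 = complete row
  for (i in seq_along(st$patterns)) st$pat_of[st$patterns[[i]]$rows] <- i
  st$Zcomp <- Z[st$complete_rows, , drop = FALSE]
  Zimp <- Z
  for (p in seq_len(st$P)) Zimp[is.na(Zimp[, p]), p] <- 0  # normalised scale
  st$Zimp <- Zimp
  st$Sigma0inv <- diag(1 / diag(hyper$Sigma0), st$P)
  st$sd0 <- sqrt(diag(hyper$Sigma0))
  st$PhiInv <- chol2inv(chol(hyper$Phi))
  st$yU <- drop(crossprod(U, y))
  st
}

prior_draw_cluster <- function(st) {
  hy <- st$hyper
  list(m = hy$m0 + stats::rnorm(st$P) * st$sd0,
       Q = stats::rWishart(1, hy$nu, hy$Phi)[, , 1],
       mu = hy$mu_scale * stats::rt(1, hy$mu_df))
}

cache_cluster_chol <- function(st, k) {
  R <- tryCatch(chol(st$Q[[k]]), error = function(e) {
    chol(st$Q[[k]] + diag(1e-8, st$P))
  })
  st$R[[k]] <- R
  st$logdetQ[k] <- 2 * sum(log(diag(R)))
  st$SigmaCache[k] <- list(NULL)     # keep the slot; [[<- NULL would drop it
}

cluster_sigma <- function(st, k) {
  S <- st$SigmaCache[[k]]
  if (is.null(S)) {
    S <- chol2inv(st$R[[k]])
    st$SigmaCache[[k]] <- S
  }
  S
}

# Instantiate clusters (sticks + parameters) up to index K.
ensure_clusters <- function(st, K) {
  while (length(st$mu) < K) {
    k <- length(st$mu) + 1L
    st$V[k] <- stats::rbeta(1, 1, st$alpha)
    pd <- prior_draw_cluster(st)
    st$m <- rbind(st$m, pd$m)
    st$Q[[k]] <- pd$Q
    st$mu[k] <- pd$mu
    cache_cluster_chol(st, k)
  }
  st$w <- stick_breaking(pmin(pmax(st$V, 1e-12), 1 - 1e-12))
  invisible(st)
}

trim_clusters <- function(st, K) {
  if (length(st$mu) > K) {
    st$V <- st$V[seq_len(K)]
    st$m <- st$m[seq_len(K), , drop = FALSE]
    st$Q <- st$Q[seq_len(K)]
    st$R <- st$R[seq_len(K)]
    st$SigmaCache <- st$SigmaCache[seq_len(K)]
    st$logdetQ <- st$logdetQ[seq_len(K)]
    st$mu <- st$mu[seq_len(K)]
    st$w <- stick_breaking(pmin(pmax(st$V, 1e-12), 1 - 1e-12))
  }
  invisible(st)
}

# Marginal exposure log-likelihood of one missingness-pattern group under
# cluster k.  The marginal precision of the observed block is the Schur
# complement W = Q_oo - Q_om Q_mm^{-1} Q_mo, with
# log|W| = log|Q| - log|Q_mm|; the missing block is small (usually one
# coordinate), so this avoids factorising the observed block.
pattern_z_loglik <- function(st, k, pt) {
  o <- pt$obs
  if (!length(o)) return(numeric(length(pt$rows)))
  po <- length(o)
  Q <- st$Q[[k]]
  mis <- pt$mis
  if (length(mis) == 1L) {
    qmm <- Q[mis, mis]
    a <- Q[o, mis]
    W <- Q[o, o, drop = FALSE] - tcrossprod(a) / qmm
    ldW <- st$logdetQ[k] - log(qmm)
  } else {
    Rm <- chol(Q[mis, mis, drop = FALSE])
    x <- backsolve(Rm, Q[mis, o, drop = FALSE], transpose = TRUE)
    W <- Q[o, o, drop = FALSE] - crossprod(x)
    ldW <- st$logdetQ[k] - 2 * sum(log(diag(Rm)))
  }
  Zc <- pt$tZ - st$m[k, o]
  q <- .colSums((W %*% Zc) * Zc, po, length(pt$rows))
  -0.5 * po * log(2 * pi) + 0.5 * ldW - 0.5 * q
}

# Exposure log-likelihood of every day under cluster k (marginal over the
# observed coordinates for days with missing entries).
cluster_z_loglik <- function(st, k) {
  out <- numeric(st$T)
  if (length(st$complete_rows))
    out[st$complete_rows] <- mvn_logdens_rows(st$Zcomp, st$m[k, ],
                                              st$R[[k]], st$logdetQ[k])
  for (pt in st$patterns)
    out[pt$rows] <- pattern_z_loglik(st, k, pt)
  out
}

# ---------------------------------------------------------------------------
# Conditional updates.  Each mutates the state environment in place.

# Dependent-slice allocation update: u_t ~ U(0, xi_{g_t}) with deterministic
# xi_k = (1 - rho) rho^(k-1); candidate set {k : xi_k > u_t}; g_t sampled
# with probability proportional to (w_k / xi_k) p(z_t | k) p(y_t | k).
update_allocations <- function(st) {
  rho <- st$rho
  xi_of <- function(k) (1 - rho) * rho^(k - 1)
  u <- stats::runif(st$T) * xi_of(st$g)
  Kmax <- pmax(st$g, floor(log(u / (1 - rho)) / log(rho)) + 1L)
  Kstar <- max(Kmax)
  ensure_clusters(st, Kstar)
  K <- length(st$mu)
  ll <- matrix(rep(log(st$w) - log(xi_of(seq_len(K))), each = st$T), st$T, K)
  if (!st$nolik) {
    for (k in seq_len(K)) ll[, k] <- ll[, k] + cluster_z_loglik(st, k)
    Ee <- exp(st$logE + st$lin + st$eps)
    ll <- ll + outer(st$y, st$mu) - outer(Ee, exp(st$mu))
  }
  ll[outer(Kmax, seq_len(K), `<`)] <- -Inf
  gumbel <- -log(-log(stats::runif(st$T * K)))
  st$g <- max.col(ll + gumbel, ties.method = "first")
  trim_clusters(st, max(st$g))
  invisible(st)
}

update_sticks_and_alpha <- function(st) {
  K <- length(st$mu)
  n <- tabulate(st$g, K)
  cs <- cond_sticks(n, st$alpha)
  st$V <- pmin(pmax(stats::rbeta(K, cs$shape1, cs$shape2), 1e-12), 1 - 1e-12)
  st$w <- stick_breaking(st$V)
  if (is.null(st$fix_alpha)) {
    ca <- cond_alpha(st$V, st$hyper$a, st$hyper$b)
    st$alpha <- stats::rgamma(1, ca$shape, rate = ca$rate)
  }
  st$n <- n
  invisible(st)
}

update_cluster_params <- function(st) {
  K <- length(st$mu)
  n <- tabulate(st$g, K)
  hy <- st$hyper
  # prior-only mode: with the exposure likelihood removed nothing in the
  # chain depends on (m_k, Q_k); leave them at their ensure_clusters() prior
  # draws instead of redrawing every sweep
  if (st$nolik) return(invisible(st))
  for (k in seq_len(K)) {
    if (n[k] == 0L) {
      pd <- prior_draw_cluster(st)
      st$m[k, ] <- pd$m
      st$Q[[k]] <- pd$Q
    } else {
      rows <- which(st$g == k)
      Zk <- st$Zimp[rows, , drop = FALSE]
      cl <- cond_location(colSums(Zk), n[k], st$Q[[k]], hy$m0, st$Sigma0inv)
      st$m[k, ] <- cl$mean + backsolve(cl$chol_precision, stats::rnorm(st$P))
      Zc <- Zk - rep(st$m[k, ], each = nrow(Zk))
      cp <- cond_precision(crossprod(Zc), n[k], st$PhiInv, hy$nu)
      st$Q[[k]] <- stats::rWishart(1, cp$df, cp$scale)[, , 1]
    }
    cache_cluster_chol(st, k)
  }
  invisible(st)
}

update_response_params <- function(st) {
  hy <- st$hyper
  K <- length(st$mu)
  nolik <- st$nolik                # prior-only mode: data terms zeroed, the
  n <- tabulate(st$g, K)           # Metropolis machinery itself unchanged
  base <- exp(st$logE + st$lin + st$eps)
  # --- cluster log relative risks: random-walk Metropolis on sufficient sums
  for (k in seq_len(K)) {
    if (n[k] == 0L && !nolik) {
      st$mu[k] <- hy$mu_scale * stats::rt(1, hy$mu_df)
      next
    }
    rows <- st$g == k
    Sy <- if (nolik) 0 else sum(st$y[rows])
    SE <- if (nolik) 0 else sum(base[rows])
    cur <- st$mu[k]
    prop <- cur + stats::rnorm(1, 0, st$scale_mu)
    logr <- (prop - cur) * Sy - (exp(prop) - exp(cur)) * SE +
      dst_log(prop, hy$mu_df, hy$mu_scale) - dst_log(cur, hy$mu_df, hy$mu_scale)
    st$att_mu <- st$att_mu + 1L
    if (log(stats::runif(1)) < logr) {
      st$mu[k] <- prop
      st$acc_mu <- st$acc_mu + 1L
    }
  }
  # --- spline coefficients: component-wise random-walk Metropolis
  eta <- st$logE + st$mu[st$g] + st$lin + st$eps
  lam <- exp(eta)
  for (h in seq_len(st$H)) {
    delta <- stats::rnorm(1, 0, st$scale_beta[h])
    uh <- st$U[, h]
    lam_new <- lam * exp(uh * delta)
    logr <- (if (nolik) 0 else
      st$yU[h] * delta - (sum(lam_new) - sum(lam))) +
      dst_log(st$beta[h] + delta, hy$beta_df, hy$beta_scale) -
      dst_log(st$beta[h], hy$beta_df, hy$beta_scale)
    st$att_beta[h] <- st$att_beta[h] + 1L
    if (log(stats::runif(1)) < logr) {
      st$beta[h] <- st$beta[h] + delta
      st$lin <- st$lin + uh * delta
      lam <- lam_new
      st$acc_beta[h] <- st$acc_beta[h] + 1L
    }
  }
  # --- day effects: eps_t are conditionally independent, so elementwise
  # Metropolis over the whole vector is a single vectorised step
  prop <- st$eps + stats::rnorm(st$T, 0, st$scale_eps)
  logr <- if (nolik) -0.5 * st$tau * (prop^2 - st$eps^2) else {
    cvec <- exp(st$logE + st$mu[st$g] + st$lin)
    st$y * (prop - st$eps) - cvec * (exp(prop) - exp(st$eps)) -
      0.5 * st$tau * (prop^2 - st$eps^2)
  }
  acc <- log(stats::runif(st$T)) < logr
  st$eps[acc] <- prop[acc]
  st$att_eps <- st$att_eps + st$T
  st$acc_eps <- st$acc_eps + sum(acc)
  # --- recentering move: mu_k and the cluster's day effects are only
  # jointly identified through the zero-mean prior on eps; shift them along
  # the likelihood-invariant direction (mu_k + d, eps_t - d for t in k),
  # accepted on the prior ratio.  Without this the day effects can absorb
  # the cluster risks and mix extremely slowly.
  # The shift is proposed from the ridge conditional d ~ N(mean(eps_k),
  # sigma^2/n_k); the proposal-density ratio cancels the Gaussian eps term,
  # so acceptance reduces to the Student-t prior ratio on mu_k.
  for (k in seq_len(K)) {
    if (n[k] == 0L) next
    rows <- which(st$g == k)
    ebar <- mean(st$eps[rows])
    d <- stats::rnorm(1, ebar, 1 / sqrt(st$tau * n[k]))
    logr <- dst_log(st$mu[k] + d, hy$mu_df, hy$mu_scale) -
      dst_log(st$mu[k], hy$mu_df, hy$mu_scale)
    if (log(stats::runif(1)) < logr) {
      st$mu[k] <- st$mu[k] + d
      st$eps[rows] <- st$eps[rows] - d
    }
  }
  # Same trick for each spline coefficient (beta_h + d, eps - d u_h).
  for (h in seq_len(st$H)) {
    uh <- st$U[, h]
    su2 <- sum(uh^2)
    if (su2 == 0) next
    dbar <- sum(st$eps * uh) / su2
    d <- stats::rnorm(1, dbar, 1 / sqrt(st$tau * su2))
    logr <- dst_log(st$beta[h] + d, hy$beta_df, hy$beta_scale) -
      dst_log(st$beta[h], hy$beta_df, hy$beta_scale)
    if (log(stats::runif(1)) < logr) {
      st$beta[h] <- st$beta[h] + d
      st$eps <- st$eps - d * uh
      st$lin <- st$lin + d * uh
    }
  }
  # --- day-effect precision: conjugate Gamma
  ct <- cond_tau(st$eps, hy$tau_shape, hy$tau_rate)
  st$tau <- stats::rgamma(1, ct$shape, rate = ct$rate)
  invisible(st)
}

# Draw missing coordinates from the conditional MVN of the allocated cluster
# given the day's observed coordinates.
update_imputation <- function(st) {
  if (!st$any_miss || st$nolik) return(invisible(st))
  for (pt in st$patterns) {
    by_k <- split(pt$rows, st$g[pt$rows])
    for (ks in names(by_k)) {
      k <- as.integer(ks)
      rows <- by_k[[ks]]
      Sigma <- cluster_sigma(st, k)
      mis <- pt$mis; obs <- pt$obs
      if (length(obs)) {
        So_inv <- chol2inv(chol_pd(Sigma[obs, obs, drop = FALSE]))
        A <- Sigma[mis, obs, drop = FALSE] %*% So_inv
        condS <- Sigma[mis, mis, drop = FALSE] -
          A %*% Sigma[obs, mis, drop = FALSE]
        Zc <- sweep(st$Z[rows, obs, drop = FALSE], 2, st$m[k, obs], `-`)
        mean_rows <- sweep(Zc %*% t(A), 2, st$m[k, mis], `+`)
      } else {
        condS <- Sigma
        mean_rows <- matrix(st$m[k, mis], length(rows), length(mis),
                            byrow = TRUE)
      }
      Rc <- chol_pd(condS + diag(1e-12, length(mis)))
      noise <- matrix(stats::rnorm(length(rows) * length(mis)),
                      length(rows)) %*% Rc
      st$Zimp[rows, mis] <- mean_rows + noise
    }
  }
  invisible(st)
}

# Label-switching moves.  Move 1 swaps the contents (parameters and
# allocations) of two random clusters while leaving the stick weights in
# place; its Metropolis ratio is (w_k/w_j)^(n_j - n_k).  Move 2 swaps the
# contents of two neighbouring clusters together with a weight-preserving
# transformation of (V_j, V_{j+1}) -- a deterministic involution whose
# acceptance probability is the Jacobian (1 - V_j)/(1 - V_j').  Size-biased
# stick conditionals make naive (V, contents) swaps almost never accepted,
# which is precisely why these two moves are needed for label mixing.
swap_state_clusters <- function(st, i, j, swap_sticks = TRUE) {
  if (swap_sticks) st$V[c(i, j)] <- st$V[c(j, i)]
  st$m[c(i, j), ] <- st$m[c(j, i), ]
  st$Q[c(i, j)] <- st$Q[c(j, i)]
  st$R[c(i, j)] <- st$R[c(j, i)]
  st$SigmaCache[c(i, j)] <- st$SigmaCache[c(j, i)]
  st$logdetQ[c(i, j)] <- st$logdetQ[c(j, i)]
  st$mu[c(i, j)] <- st$mu[c(j, i)]
  gi <- st$g == i
  st$g[st$g == j] <- i
  st$g[gi] <- j
  st$w <- stick_breaking(st$V)
  invisible(st)
}

alloc_weight_term <- function(V, n) {
  w <- stick_breaking(V)
  occ <- n > 0
  if (any(w[occ] == 0)) return(-Inf)
  sum(n[occ] * log(w[occ]))
}

update_label_moves <- function(st, moves) {
  K <- length(st$mu)
  if (K < 2) return(invisible(st))
  n <- tabulate(st$g, K)
  if ("pair" %in% moves) {
    ij <- sort(sample.int(K, 2))
    i <- ij[1]; j <- ij[2]
    logr <- (n[i] - n[j]) * (log(st$w[j]) - log(st$w[i]))
    st$att_label <- st$att_label + 1L
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      swap_state_clusters(st, i, j, swap_sticks = FALSE)
      n <- tabulate(st$g, K)
      st$acc_label <- st$acc_label + 1L
    }
  }
  if ("neighbour" %in% moves && K >= 2) {
    j <- sample.int(K - 1, 1)
    a <- st$V[j]; b <- st$V[j + 1]
    a2 <- (1 - a) * b                  # new V_j so that w_j' = w_{j+1}
    b2 <- a / (1 - a2)                 # new V_{j+1} so that w_{j+1}' = w_j
    logr <- log1p(-a) - log1p(-a2)     # Jacobian of the involution
    st$att_label <- st$att_label + 1L
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      swap_state_clusters(st, j, j + 1L, swap_sticks = FALSE)
      st$V[j] <- min(max(a2, 1e-12), 1 - 1e-12)
      st$V[j + 1] <- min(max(b2, 1e-12), 1 - 1e-12)
      st$w <- stick_breaking(st$V)
      st$acc_label <- st$acc_label + 1L
    }
  }
  invisible(st)
}

# Full data log-likelihood at the current state (Poisson + marginal MVN).
state_data_loglik <- function(st) {
  if (st$nolik) return(0)
  lam <- exp(st$logE + st$mu[st$g] + st$lin + st$eps)
  ll <- sum(stats::dpois(st$y, lam, log = TRUE))
  for (k in unique(st$g)) {
    rows <- which(st$g == k)
    rc <- rows[st$pat_of[rows] == 0L]
    if (length(rc))
      ll <- ll + sum(mvn_logdens_rows(st$Z[rc, , drop = FALSE],
                                      st$m[k, ], st$R[[k]], st$logdetQ[k]))
    rp <- rows[st$pat_of[rows] > 0L]
    for (pi in unique(st$pat_of[rp])) {
      pt <- st$patterns[[pi]]
      zl <- pattern_z_loglik(st, k, pt)
      ll <- ll + sum(zl[pt$rows %in% rp])
    }
  }
  ll
}

# ---------------------------------------------------------------------------

#' Run the dependent-slice MCMC sampler
#'
#' Full sweep order: allocations, sticks and DP concentration, cluster
#' locations/precisions, response parameters (log relative risks, spline
#' coefficients, day effects and their precision), imputation of missing
#' exposures, label-switching moves.  Proposal scales adapt towards 44%
#' acceptance during burn-in only, preserving detailed balance afterwards.
#' Cluster storage grows lazily to whatever index the slice variables
#' expose; no fixed truncation level is imposed, and empty clusters are
#' refreshed from the prior each sweep.
#'
#' @param y count vector (length `T`).
#' @param z normalised exposure matrix (`T x P`, `NA` allowed) or a
#'   [normalize_exposures()] object.
#' @param design a [build_spline_design()] object (or a plain basis matrix).
#' @param offset positive offset vector from [compute_offset()].
#' @param hyper a [empirical_hyperparams()] object.
#' @param config a [mcmc_config()].
#' @return object of class `profreg_chain`: list with `states` (thinned
#'   snapshots: allocations, sticks, weights, cluster parameters, response
#'   parameters), `allocations` (draws x T matrix), `traces` (per-sweep
#'   alpha, sigma_eps, occupied clusters, data log-likelihood),
#'   `acceptance`, `config` and `hyper`.
#' @export
run_mcmc <- function(y, z, design, offset, hyper, config = mcmc_config()) {
  Z <- if (inherits(z, "normalized_exposures")) z$z else as.matrix(z)
  U <- if (inherits(design, "spline_design")) design$basis else as.matrix(design)
  stopifnot(length(y) == nrow(Z), length(offset) == length(y),
            nrow(U) == length(y))
  if (!is_count_vector(y)) stop("y must be a vector of non-negative counts")
  set.seed(config$seed)
  st <- make_state(y, Z, U, offset, hyper, config)
  st$fix_alpha <- config$fix_alpha
  # --- initialisation
  st$alpha <- config$fix_alpha %||% 1
  K0 <- max(1L, min(config$init_clusters, st$T - 1L))
  st$g <- if (K0 == 1L) rep(1L, st$T) else {
    km <- suppressWarnings(stats::kmeans(st$Zimp, centers = K0,
                                         nstart = 1, iter.max = 30))
    as.integer(km$cluster)
  }
  K0 <- max(st$g)
  st$V <- rep(0.5, K0); st$m <- matrix(0, K0, st$P)
  st$Q <- rep(list(diag(st$P)), K0)
  st$R <- vector("list", K0); st$SigmaCache <- vector("list", K0)
  st$logdetQ <- numeric(K0)
  for (k in seq_len(K0)) cache_cluster_chol(st, k)
  init_fit <- tryCatch(
    stats::glm.fit(cbind(1, U), y, family = stats::poisson(),
                   offset = st$logE),
    error = function(e) NULL)
  co <- if (!is.null(init_fit)) init_fit$coefficients else rep(0, st$H + 1)
  co[!is.finite(co)] <- 0
  st$mu <- rep(co[1], K0)
  st$beta <- co[-1]
  st$lin <- drop(U %*% st$beta)
  st$eps <- numeric(st$T)
  st$tau <- hyper$tau_shape / hyper$tau_rate
  update_sticks_and_alpha(st)
  update_cluster_params(st)
  # --- bookkeeping
  st$scale_mu <- config$prop_mu
  st$scale_beta <- rep(config$prop_beta, st$H)
  st$scale_eps <- config$prop_eps
  st$att_mu <- st$acc_mu <- 0L
  st$att_beta <- st$acc_beta <- integer(st$H)
  st$att_eps <- st$acc_eps <- 0L
  st$att_label <- st$acc_label <- 0L
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  states <- vector("list", n_keep)
  alloc <- matrix(NA_integer_, n_keep, st$T)
  tr_alpha <- tr_sigma <- tr_ll <- numeric(config$n_iter)
  tr_nocc <- integer(config$n_iter)
  batch_att <- list(mu = 0L, beta = integer(st$H), eps = 0L)
  batch_acc <- list(mu = 0L, beta = integer(st$H), eps = 0L)
  kept <- 0L
  for (it in seq_len(config$n_iter)) {
    a0 <- c(st$acc_mu, st$acc_eps); t0 <- c(st$att_mu, st$att_eps)
    ab0 <- st$acc_beta; tb0 <- st$att_beta
    update_allocations(st)
    update_sticks_and_alpha(st)
    update_cluster_params(st)
    update_response_params(st)
    update_imputation(st)
    if (length(config$label_moves))
      update_label_moves(st, config$label_moves)
    # adaptive proposal tuning, burn-in only
    if (it <= config$burn_in) {
      batch_acc$mu <- batch_acc$mu + (st$acc_mu - a0[1])
      batch_att$mu <- batch_att$mu + (st$att_mu - t0[1])
      batch_acc$eps <- batch_acc$eps + (st$acc_eps - a0[2])
      batch_att$eps <- batch_att$eps + (st$att_eps - t0[2])
      batch_acc$beta <- batch_acc$beta + (st$acc_beta - ab0)
      batch_att$beta <- batch_att$beta + (st$att_beta - tb0)
      if (it %% config$adapt_batch == 0L) {
        step <- 1 / sqrt(it / config$adapt_batch)
        tune <- function(scale, acc, att) {
          rate <- ifelse(att > 0, acc / att, 0.44)
          pmin(pmax(scale * exp(step * (rate - 0.44)), 1e-3), 10)
        }
        st$scale_mu <- tune(st$scale_mu, batch_acc$mu, batch_att$mu)
        st$scale_eps <- tune(st$scale_eps, batch_acc$eps, batch_att$eps)
        st$scale_beta <- tune(st$scale_beta, batch_acc$beta, batch_att$beta)
        batch_att <- list(mu = 0L, beta = integer(st$H), eps = 0L)
        batch_acc <- list(mu = 0L, beta = integer(st$H), eps = 0L)
      }
    }
    tr_alpha[it] <- st$alpha
    tr_sigma[it] <- 1 / sqrt(st$tau)
    tr_nocc[it] <- length(unique(st$g))
    ll <- state_data_loglik(st)
    tr_ll[it] <- ll
    if (!is.finite(ll) || !all(is.finite(st$mu)) || !all(is.finite(st$beta)))
      stop("non-finite joint density at sweep ", it,
           " (occupied clusters: ", tr_nocc[it], ")")
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      alloc[kept, ] <- st$g
      states[[kept]] <- list(
        g = st$g, V = st$V, w = st$w, m = st$m, Q = st$Q,
        mu = st$mu, beta = st$beta,
        sigma_eps = 1 / sqrt(st$tau), alpha = st$alpha,
        n_occupied = tr_nocc[it])
    }
  }
  acc_rate <- function(a, t) if (sum(t) > 0) sum(a) / sum(t) else NA_real_
  rates <- c(mu = acc_rate(st$acc_mu, st$att_mu),
             beta = acc_rate(st$acc_beta, st$att_beta),
             eps = acc_rate(st$acc_eps, st$att_eps),
             label = acc_rate(st$acc_label, st$att_label))
  for (nm in c("mu", "beta", "eps")) {
    r <- rates[[nm]]
    if (!is.na(r) && (r <= 0 || r >= 1))
      warning("acceptance rate for ", nm, " pinned at ", round(r, 3))
  }
  structure(list(
    states = states,
    allocations = alloc,
    traces = data.frame(iter = seq_len(config$n_iter), alpha = tr_alpha,
                        sigma_eps = tr_sigma, n_occupied = tr_nocc,
                        data_loglik = tr_ll),
    acceptance = rates,
    n_draws = n_keep,
    config = config,
    hyper = hyper
  ), class = "profreg_chain")
}

#' @export
print.profreg_chain <- function(x, ...) {
  cat("profreg_chain:", x$n_draws, "stored draws over",
      ncol(x$allocations), "days;",
      "median occupied clusters:",
      stats::median(x$traces$n_occupied[-seq_len(x$config$burn_in)]), "\n")
  invisible(x)
}
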