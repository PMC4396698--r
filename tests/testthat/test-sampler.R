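# Direct checks of the sampler's conditional updates on pinned states, plus
# chain-level contracts that are cheap enough for routine runs.

simple_hyper <- function(P = 2) {
  set.seed(99)
  empirical_hyperparams(matrix(rnorm(60 * P), 60, P))
}

test_that("configuration invariants are enforced", {
  expect_error(mcmc_config(burn_in = 100, n_iter = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(rho = 1.2), "rho")
  cfg <- mcmc_config()
  expect_equal((cfg$n_iter - cfg$burn_in) %/% cfg$thin, 5000)
})

test_that("stick and concentration conditionals have the conjugate form", {
  cs <- profregts:::cond_sticks(c(10, 0, 0), alpha = 1)
  expect_equal(cs$shape1, c(11, 1, 1))
  expect_equal(cs$shape2, c(1, 1, 1))
  expect_equal(cs$shape1[1] / (cs$shape1[1] + cs$shape2[1]), 11 / 12)
  # no data: the prior Beta(1, alpha)
  cs0 <- profregts:::cond_sticks(c(0, 0), alpha = 3)
  expect_equal(cs0$shape1, c(1, 1))
  expect_equal(cs0$shape2, c(3, 3))
  V <- c(0.3, 0.2, 0.4)
  ca <- profregts:::cond_alpha(V, a = 2, b = 1)
  expect_equal(ca$shape, 5)
  expect_equal(ca$rate, 1 - sum(log1p(-V)))
  # Monte-Carlo check of the Gamma mean
  set.seed(11)
  draws <- rgamma(2e4, ca$shape, rate = ca$rate)
  expect_lt(abs(mean(draws) - ca$shape / ca$rate),
            3 * sd(draws) / sqrt(2e4))
})

test_that("location conditional collapses to the sample mean without prior", {
  set.seed(12)
  Zk <- matrix(rnorm(100, mean = 3), 100, 1)
  huge <- diag(1e8, 1)
  cl <- profregts:::cond_location(colSums(Zk), 100, diag(1), m0 = 0,
                                  Sigma0inv = solve(huge))
  expect_equal(cl$mean, mean(Zk), tolerance = 1e-4)
  # and to the prior with no data
  cl0 <- profregts:::cond_location(c(0, 0), 0, diag(2), m0 = c(1, 2),
                                   Sigma0inv = diag(0.5, 2))
  expect_equal(cl0$mean, c(1, 2))
  expect_equal(cl0$precision, diag(0.5, 2))
})

test_that("precision and day-effect conditionals match closed forms", {
  set.seed(13)
  Zc <- matrix(rnorm(40), 20, 2)
  PhiInv <- diag(2, 2)
  cp <- profregts:::cond_precision(crossprod(Zc), 20, PhiInv, nu = 2)
  expect_equal(cp$df, 22)
  expect_equal(cp$scale, solve(PhiInv + crossprod(Zc)), tolerance = 1e-10)
  ct <- profregts:::cond_tau(rep(0, 100), 5, 0.5)
  expect_equal(ct$shape, 55)
  expect_equal(ct$rate, 0.5)
  eps <- rnorm(50, 0, 0.3)
  ct2 <- profregts:::cond_tau(eps, 5, 0.5)
  expect_equal(ct2$rate, 0.5 + sum(eps^2) / 2, tolerance = 1e-12)
})

test_that("pattern-grouped exposure likelihood marginalises missing cells", {
  set.seed(18)
  P <- 4; Tn <- 30
  Z <- matrix(rnorm(Tn * P), Tn, P)
  Z[sample(length(Z), 25)] <- NA           # mixed patterns incl. complete
  hy <- simple_hyper(P)
  A <- matrix(rnorm(16), 4)
  Q1 <- crossprod(A) + diag(4)
  st <- pinned_state(rpois(Tn, 20), Z, matrix(0, Tn, 1), rep(20, Tn), hy,
                     g = rep(1L, Tn), V = 0.999,
                     m = matrix(rnorm(4), 1), Q = list(Q1), mu = 0)
  expect_equal(profregts:::cluster_z_loglik(st, 1),
               mvn_logdensity(Z, st$m[1, ], Q1), tolerance = 1e-10)
})

test_that("imputation draws from the conditional of the allocated cluster", {
  P <- 2
  hy <- simple_hyper(P)
  Tn <- 400
  rho_z <- 0.9
  Sigma <- matrix(c(1, rho_z, rho_z, 1), 2)
  Z <- matrix(rnorm(Tn * P), Tn, P)
  Z[, 2] <- NA                       # coordinate 2 always missing
  Z[, 1] <- 2                        # observed coordinate pinned at m + 2 sd
  y <- rpois(Tn, 20)
  U <- matrix(0, Tn, 1)
  st <- pinned_state(y, Z, U, rep(20, Tn), hy,
                     g = rep(1L, Tn), V = 0.999,
                     m = matrix(0, 1, P), Q = list(solve(Sigma)),
                     mu = 0)
  set.seed(14)
  profregts:::update_imputation(st)
  imp <- st$Zimp[, 2]
  # conditional mean 0 + rho * 2 = 1.8, conditional sd sqrt(1 - rho^2)
  expect_lt(abs(mean(imp) - 1.8), 3 * sqrt((1 - rho_z^2) / Tn))
  expect_lt(abs(var(imp) - (1 - rho_z^2)), 3 * (1 - rho_z^2) / sqrt(Tn))
  # identity covariance: conditional equals the marginal
  st2 <- pinned_state(y, Z, U, rep(20, Tn), hy,
                      g = rep(1L, Tn), V = 0.999,
                      m = matrix(c(0.5, 0.7), 1, P), Q = list(diag(P)),
                      mu = 0)
  profregts:::update_imputation(st2)
  expect_lt(abs(mean(st2$Zimp[, 2]) - 0.7), 3 / sqrt(Tn))
})

test_that("label moves preserve the joint density bookkeeping", {
  P <- 2
  hy <- simple_hyper(P)
  Tn <- 40
  set.seed(15)
  Z <- matrix(rnorm(Tn * P), Tn, P)
  y <- rpois(Tn, 20)
  U <- matrix(rnorm(Tn), Tn, 1)
  g <- rep(c(1L, 2L), each = Tn / 2)
  V <- c(0.6, 0.3, 0.2, 0.4)
  m <- rbind(c(-1, 0), c(1, 0), c(0, 0), c(0.5, -0.5))
  Q <- rep(list(diag(P)), 4)
  mu <- c(-0.2, 0.2, 0, 0.1)
  st <- pinned_state(y, Z, U, rep(20, Tn), hy, g = g, V = V, m = m, Q = Q,
                     mu = mu, beta = 0.1, eps = rnorm(Tn, 0, 0.1))
  # swapping the contents of two empty clusters (3 and 4) is always
  # accepted: the move-1 ratio (w_j/w_i)^(n_i - n_j) is exactly 1
  n <- tabulate(st$g, 4)
  expect_equal((n[3] - n[4]) * (log(st$w[4]) - log(st$w[3])), 0)
  # an accepted swap changes the joint only via the allocation-weight term
  lj_before <- state_log_joint(st)
  wt_before <- profregts:::alloc_weight_term(st$V, tabulate(st$g, 4))
  profregts:::swap_state_clusters(st, 1L, 2L)
  lj_after <- state_log_joint(st)
  wt_after <- profregts:::alloc_weight_term(st$V, tabulate(st$g, 4))
  expect_equal(lj_after - lj_before, wt_after - wt_before,
               tolerance = 1e-8)
})

test_that("label moves let a symmetric two-cluster target switch labels", {
  P <- 1
  set.seed(16)
  # two exactly symmetric clusters at +-2
  Z <- matrix(c(rnorm(30, -2, 0.3), rnorm(30, 2, 0.3)), ncol = 1)
  y <- rpois(60, 20)
  hy <- empirical_hyperparams(Z)
  cfg <- mcmc_config(n_iter = 3000, burn_in = 500, thin = 5, seed = 3,
                     init_clusters = 2)
  ch <- run_mcmc(y, Z, matrix(0, 60, 1), rep(20, 60), hy, cfg)
  # day 1 should appear under more than one stick index across sweeps
  expect_gt(length(unique(ch$allocations[, 1])), 1)
})

test_that("successive-conditional cycles keep the conjugate updates at the prior", {
  # one fixed cluster, P = 2, T = 20: draw (m, Q, tau) from the prior,
  # generate data, apply one conditional update; the updated draws must
  # remain marginally prior-distributed.
  P <- 2; Tn <- 20; N <- 2000
  hy <- simple_hyper(P)
  set.seed(17)
  m_upd <- matrix(NA_real_, N, P)
  q11_upd <- tau_upd <- numeric(N)
  Sigma0inv <- diag(1 / diag(hy$Sigma0), P)
  for (i in seq_len(N)) {
    Q <- stats::rWishart(1, hy$nu, hy$Phi)[, , 1]
    m <- hy$m0 + rnorm(P) * sqrt(diag(hy$Sigma0))
    tau <- rgamma(1, hy$tau_shape, rate = hy$tau_rate)
    Zk <- mvtnorm::rmvnorm(Tn, m, solve(Q))
    eps <- rnorm(Tn, 0, 1 / sqrt(tau))
    cl <- profregts:::cond_location(colSums(Zk), Tn, Q, hy$m0, Sigma0inv)
    m_new <- cl$mean + backsolve(cl$chol_precision, rnorm(P))
    Zc <- Zk - rep(m_new, each = Tn)
    cp <- profregts:::cond_precision(crossprod(Zc), Tn, solve(hy$Phi), hy$nu)
    Q_new <- stats::rWishart(1, cp$df, cp$scale)[, , 1]
    ct <- profregts:::cond_tau(eps, hy$tau_shape, hy$tau_rate)
    m_upd[i, ] <- m_new
    q11_upd[i] <- Q_new[1, 1]
    tau_upd[i] <- rgamma(1, ct$shape, rate = ct$rate)
  }
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(m_upd[, 1]) - hy$m0[1]), 3 * se(m_upd[, 1]))
  expect_lt(abs(mean(m_upd[, 2]) - hy$m0[2]), 3 * se(m_upd[, 2]))
  expect_lt(abs(mean(q11_upd) - hy$nu * hy$Phi[1, 1]), 3 * se(q11_upd))
  expect_lt(abs(mean(tau_upd) - hy$tau_shape / hy$tau_rate),
            3 * se(tau_upd))
})

test_that("chains are reproducible, finite, and the right length", {
  ser <- tiny_series()
  al <- lag_exposures(ser)
  norm <- normalize_exposures(al$exposures)
  design <- build_spline_design(seq_along(al$outcome), al$temperature,
                                time_df_per_year = 6, temp_df = 3)
  E <- compute_offset(al$outcome)
  hy <- empirical_hyperparams(norm)
  cfg <- mcmc_config(n_iter = 400, burn_in = 150, thin = 5, seed = 23,
                     init_clusters = 4)
  ch1 <- run_mcmc(al$outcome, norm, design, E, hy, cfg)
  ch2 <- run_mcmc(al$outcome, norm, design, E, hy, cfg)
  expect_equal(ch1$n_draws, (400 - 150) %/% 5)
  expect_identical(ch1$allocations, ch2$allocations)
  expect_equal(ch1$traces, ch2$traces)
  expect_true(all(is.finite(ch1$traces$data_loglik)))
  expect_true(all(ch1$traces$n_occupied >= 1))
  # snapshots carry complete per-cluster parameters
  s <- ch1$states[[ch1$n_draws]]
  expect_gte(length(s$mu), max(s$g))
  expect_equal(length(s$Q), nrow(s$m))
  expect_equal(s$w, stick_breaking(s$V), tolerance = 1e-12)
})
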