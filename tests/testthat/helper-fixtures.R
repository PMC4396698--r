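# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but non-trivial synthetic series (3 well-separated groups).
tiny_series <- function() memo("tiny_series", {
  P <- 3
  cfg <- scenario_config(
    T = 220, P = P, K_true = 2,
    true_weights = c(0.65, 0.35),
    true_means = rbind(rep(0, P), rep(4, P)),
    true_covariances = rep(list(diag(P)), 2),
    true_log_rr = c(-0.25, 0.35),
    baseline_rate = 20,
    sigma_eps = 0.05,
    seed = 5L)
  simulate_profile_series(cfg)
})

# A short fitted chain on the tiny series, reused across test files.
tiny_fit <- function() memo("tiny_fit", {
  profile_regression(tiny_series(), k_range = 2:4,
                     mcmc = mcmc_config(n_iter = 1500, burn_in = 500,
                                        thin = 5, init_clusters = 5,
                                        seed = 17))
})

# Build a sampler state environment with pinned parameters, for direct tests
# of the conditional updates.
pinned_state <- function(y, Z, U, E, hyper, g, V, m, Q, mu,
                         beta = numeric(ncol(U)), eps = numeric(length(y)),
                         tau = 10, alpha = 1, rho = 0.75) {
  cfg <- mcmc_config(n_iter = 10, burn_in = 5, thin = 1, seed = 1, rho = rho)
  st <- profregts:::make_state(y, Z, U, E, hyper, cfg)
  st$fix_alpha <- NULL
  st$g <- as.integer(g)
  K <- length(mu)
  st$V <- V
  st$m <- m
  st$Q <- Q
  st$R <- vector("list", K)
  st$SigmaCache <- vector("list", K)
  st$logdetQ <- numeric(K)
  for (k in seq_len(K)) profregts:::cache_cluster_chol(st, k)
  st$w <- stick_breaking(pmin(pmax(V, 1e-12), 1 - 1e-12))
  st$mu <- mu
  st$beta <- beta
  st$lin <- drop(st$U %*% beta)
  st$eps <- eps
  st$tau <- tau
  st$alpha <- alpha
  st$scale_mu <- 0.1
  st$scale_beta <- rep(0.02, st$H)
  st$scale_eps <- 0.5
  st$att_mu <- st$acc_mu <- 0L
  st$att_beta <- st$acc_beta <- integer(st$H)
  st$att_eps <- st$acc_eps <- 0L
  st$att_label <- st$acc_label <- 0L
  st
}

# Restore pinned cluster parameters after a sweep (the slice sampler trims
# and regrows its cluster list; restoring fixed values keeps the transition
# kernel on (u, g) exactly the pinned-parameter kernel).
repin_state <- function(st, V, m, Q, mu) {
  K <- length(mu)
  st$V <- V
  st$m <- m
  st$Q <- Q[seq_len(K)]
  st$R <- vector("list", K)
  st$SigmaCache <- vector("list", K)
  st$logdetQ <- numeric(K)
  for (k in seq_len(K)) profregts:::cache_cluster_chol(st, k)
  st$w <- stick_breaking(pmin(pmax(V, 1e-12), 1 - 1e-12))
  st$mu <- mu
  invisible(st)
}

# Full joint log density (prior + data likelihood) of a pinned state.
state_log_joint <- function(st) {
  fake <- list(V = st$V, m = st$m, Q = st$Q, mu = st$mu, beta = st$beta,
               eps = st$eps, sigma_eps = 1 / sqrt(st$tau), alpha = st$alpha)
  lp <- log_prior(fake, st$hyper)
  # allocation term: sum_t log w_{g_t}
  lp + sum(log(st$w[st$g])) + profregts:::state_data_loglik(st)
}
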