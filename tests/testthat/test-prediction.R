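# A hand-pinned chain with two well-separated clusters and known relative
# risks, replicated across draws: lets the predictive machinery be checked
# against analytic values.
pinned_chain <- function(ndraw = 400, rr2 = 1.35, sigma_eps = 0) {
  P <- 2
  state <- list(
    g = rep(c(1L, 2L), each = 10),
    V = c(0.5, 0.999),
    w = stick_breaking(c(0.5, 0.999)),
    m = rbind(rep(-4, P), rep(4, P)),
    Q = rep(list(diag(P)), 2),
    mu = c(0, log(rr2)),
    beta = numeric(1),
    sigma_eps = sigma_eps, alpha = 1, n_occupied = 2L)
  structure(list(states = rep(list(state), ndraw),
                 allocations = matrix(rep(state$g, each = ndraw), ndraw),
                 traces = NULL, acceptance = NULL, n_draws = ndraw,
                 config = mcmc_config(n_iter = 2, burn_in = 1, thin = 1),
                 hyper = NULL), class = "profreg_chain")
}

fake_norm <- function(P = 2) {
  structure(list(z = NULL, medians = rep(0, P), mads = rep(1, P)),
            class = "normalized_exposures")
}

test_that("scenario days are allocated to the matching cluster", {
  ch <- pinned_chain()
  set.seed(41)
  zA <- matrix(rnorm(2 * 60, mean = -4), 60, 2)   # cluster 1 profile
  scA <- new_scenario(zA, fake_norm(), normalized = TRUE)
  pr <- predict_scenario(ch, scA, offset = 20, design = NULL, seed = 2,
                         draw_counts = FALSE)
  # cluster 1 has mu = 0: expected rate = E on virtually every day
  expect_lt(mean(abs(pr$counts - 20) > 1e-9), 0.01)
})

test_that("a degenerate one-cluster chain predicts the offset", {
  ch <- pinned_chain()
  # collapse to one cluster by using profiles at cluster 1 exactly
  one <- lapply(ch$states, function(s) {
    s$w <- 1; s$V <- 0.999999; s$m <- s$m[1, , drop = FALSE]
    s$Q <- s$Q[1]; s$mu <- 0; s$g <- rep(1L, 20); s
  })
  ch$states <- one
  sc <- new_scenario(matrix(rnorm(40, -4), 20, 2), fake_norm(),
                     normalized = TRUE)
  pr <- predict_scenario(ch, sc, offset = 21.6, design = NULL, seed = 3,
                         draw_counts = FALSE)
  expect_equal(unname(pr$daily_mean), rep(21.6, 20), tolerance = 1e-9)
})

test_that("shifting days between clusters changes rates by the risk ratio", {
  ch <- pinned_chain(ndraw = 600)
  set.seed(42)
  ndays <- 365
  zB <- matrix(rnorm(2 * ndays, mean = 4), ndays, 2)    # RR 1.35 cluster
  zA <- matrix(rnorm(2 * ndays, mean = -4), ndays, 2)   # RR 1.00 cluster
  scB <- new_scenario(zB, fake_norm(), normalized = TRUE)
  scA <- new_scenario(zA, fake_norm(), normalized = TRUE)
  prB <- predict_scenario(ch, scB, offset = 20, design = NULL, seed = 4)
  prA <- predict_scenario(ch, scA, offset = 20, design = NULL, seed = 5)
  ratio <- mean(prA$total) / mean(prB$total)
  se <- ratio * sqrt(var(prA$total) / mean(prA$total)^2 +
                       var(prB$total) / mean(prB$total)^2) / sqrt(600)
  expect_lt(abs(ratio - 1 / 1.35), 3 * se + 0.002)
  pc <- percent_change(prB, prA)
  expect_lt(abs(pc$mean - 100 * (1 / 1.35 - 1)), 1.5)
  expect_lt(pc$upper, 0)
})

test_that("percent change is exact on constant totals and centred on nulls", {
  mk_pred <- function(counts) structure(list(counts = counts),
                                        class = "scenario_prediction")
  pA <- mk_pred(matrix(50, 40, 2))     # total 100 per draw
  pB <- mk_pred(matrix(45, 40, 2))     # total 90 per draw
  pc <- percent_change(pA, pB)
  expect_equal(pc$mean, -10)
  expect_equal(pc$lower, -10); expect_equal(pc$upper, -10)
  # identical scenarios: centred at zero
  ch <- pinned_chain(ndraw = 500)
  sc <- new_scenario(matrix(rnorm(2 * 200, 4), 200, 2), fake_norm(),
                     normalized = TRUE)
  p1 <- predict_scenario(ch, sc, offset = 20, design = NULL, seed = 6)
  p2 <- predict_scenario(ch, sc, offset = 20, design = NULL, seed = 7)
  pc0 <- percent_change(p1, p2)
  se0 <- sd(pc0$draws) / sqrt(length(pc0$draws))
  expect_lt(abs(pc0$mean), 3 * se0 + 0.05)
  # swap consistency: (1 + pc_AB/100)(1 + pc_BA/100) = 1 draw by draw
  pcAB <- percent_change(pA, pB); pcBA <- percent_change(pB, pA)
  expect_equal((1 + pcAB$draws / 100) * (1 + pcBA$draws / 100),
               rep(1, 40), tolerance = 1e-12)
  # designed 5% reduction
  pC <- mk_pred(matrix(50 * 0.95, 40, 2))
  expect_equal(percent_change(pA, pC)$mean, -5, tolerance = 1e-12)
  # zero-denominator draws excluded with a warning
  pz <- mk_pred(rbind(matrix(50, 39, 2), c(0, 0)))
  expect_warning(pcz <- percent_change(pz, pB), "zero baseline")
  expect_length(pcz$draws, 39)
})

test_that("predictive draws are reproducible and schema-checked", {
  ch <- pinned_chain(ndraw = 50)
  sc <- new_scenario(matrix(rnorm(20, 4), 10, 2), fake_norm(),
                     normalized = TRUE)
  p1 <- predict_scenario(ch, sc, 20, NULL, seed = 9)
  p2 <- predict_scenario(ch, sc, 20, NULL, seed = 9)
  expect_identical(p1$counts, p2$counts)
  expect_error(new_scenario(matrix(0, 5, 3), fake_norm(2)), "columns")
})

test_that("prediction on training exposures reproduces fitted rates", {
  fit <- tiny_fit()
  sc <- new_scenario(fit$data$exposures, fit$normalization,
                     temperature = fit$data$temperature)
  pr <- predict_scenario(fit$chain, sc, fit$offset, fit$design, seed = 10,
                         draw_counts = FALSE)
  # posterior-mean fitted rate per day, eps marginalised (E[exp(eps)] term
  # included since the predictive draws a fresh eps)
  lam_fit <- sapply(seq_len(fit$chain$n_draws), function(s) {
    stt <- fit$chain$states[[s]]
    tc <- mean(fit$design$basis[, fit$design$cols$time] %*%
                 stt$beta[fit$design$cols$time])
    wc <- fit$design$basis[, fit$design$cols$temperature] %*%
      stt$beta[fit$design$cols$temperature]
    fit$offset[1] * exp(stt$mu[stt$g] + tc + wc + stt$sigma_eps^2 / 2)
  })
  expect_lt(mean(abs(pr$daily_mean - rowMeans(lam_fit))) / mean(lam_fit),
            0.05)
})

test_that("cross-validation on exchangeable synthetic data is calibrated", {
  ser <- tiny_series()
  cv <- cross_validate(ser, split_date = ser$dates[166], lag = 1,
                       time_df_per_year = 6,
                       mcmc = mcmc_config(n_iter = 1200, burn_in = 400,
                                          thin = 4, init_clusters = 4,
                                          seed = 29))
  expect_gte(cv$coverage, 0.85)
  expect_lte(cv$coverage, 1.0)
  expect_lt(cv$mae_validation, 2 * cv$mae_training + 1)
  expect_error(cross_validate(ser, split_date = min(ser$dates)), "split")
})
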