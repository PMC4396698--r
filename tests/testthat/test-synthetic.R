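test_that("exposure generation matches the configured mixture", {
  P <- 2
  cfg <- scenario_config(T = 10000, P = P, K_true = 1,
                         true_weights = 1,
                         true_means = matrix(0, 1, P),
                         true_covariances = list(diag(P)),
                         true_log_rr = 0, seed = 3L)
  ex <- generate_exposures(cfg)
  # column means within 3 standard errors of 0
  expect_true(all(abs(colMeans(ex$exposures)) < 3 / sqrt(10000)))

  cfg2 <- scenario_config(T = 50, P = P, K_true = 2,
                          true_weights = c(1, 0),
                          true_means = rbind(rep(0, P), rep(5, P)),
                          true_covariances = rep(list(diag(P)), 2),
                          true_log_rr = c(0, 0), seed = 3L)
  expect_true(all(generate_exposures(cfg2)$labels == 1L))

  cfg3 <- scenario_config(T = 2000, P = P, K_true = 2,
                          true_weights = c(0.5, 0.5),
                          true_means = rbind(rep(-5, P), rep(5, P)),
                          true_covariances = rep(list(diag(P)), 2),
                          true_log_rr = c(0, 0), seed = 3L)
  ex3 <- generate_exposures(cfg3)
  # nearest-mean classification recovers nearly all labels at separation 10
  d1 <- rowSums((ex3$exposures + 5)^2)
  d2 <- rowSums((ex3$exposures - 5)^2)
  guess <- ifelse(d1 < d2, 1L, 2L)
  expect_gte(mean(guess == ex3$labels), 0.99)

  # non-positive-definite covariance rejected at configuration time
  expect_error(
    scenario_config(T = 10, P = 2, K_true = 1, true_weights = 1,
                    true_means = matrix(0, 1, 2),
                    true_covariances = list(matrix(c(1, 2, 2, 1), 2)),
                    true_log_rr = 0),
    "positive-definite")
})

test_that("label frequencies follow the configured weights", {
  w <- c(0.6, 0.25, 0.15)
  cfg <- scenario_config(T = 10000, P = 2, K_true = 3, true_weights = w,
                         true_means = matrix(0, 3, 2),
                         true_covariances = rep(list(diag(2)), 3),
                         true_log_rr = c(0, 0, 0), seed = 9L)
  labs <- generate_exposures(cfg)$labels
  gof <- stats::chisq.test(tabulate(labs, 3), p = w)
  expect_gt(gof$p.value, 0.01)
})

test_that("per-cluster empirical covariance converges to the truth", {
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  frob <- vapply(c(200, 20000), function(Tn) {
    cfg <- scenario_config(T = Tn, P = 2, K_true = 1, true_weights = 1,
                           true_means = matrix(0, 1, 2),
                           true_covariances = list(S),
                           true_log_rr = 0, seed = 4L)
    norm(stats::cov(generate_exposures(cfg)$exposures) - S, "F")
  }, numeric(1))
  expect_lt(frob[2], frob[1])
  expect_lt(frob[2], 0.05)
})

test_that("temperature surrogate is seasonal with the expected range", {
  cfg <- scenario_config(T = 730, P = 1, K_true = 1, true_weights = 1,
                         true_means = matrix(0, 1, 1),
                         true_covariances = list(diag(1)),
                         true_log_rr = 0, seed = 2L)
  cf <- generate_confounders(cfg)
  expect_length(cf$temperature, 730)
  expect_identical(cf$day_index, 1:730)
  # lag-365 autocorrelation dominated by the annual cycle
  x <- cf$temperature
  expect_gt(stats::cor(x[1:365], x[366:730]), 0.8)
  # roughly the London range
  expect_gt(min(x), -8); expect_lt(max(x), 35)
  # deterministic given the seed
  expect_identical(cf, generate_confounders(cfg))
  # degenerate case: no amplitude, no noise -> constant
  cfg0 <- scenario_config(T = 10, P = 1, K_true = 1, true_weights = 1,
                          true_means = matrix(0, 1, 1),
                          true_covariances = list(diag(1)),
                          true_log_rr = 0, temp_amplitude = 0,
                          temp_noise_sd = 0, seed = 2L)
  expect_true(all(generate_confounders(cfg0)$temperature == cfg0$temp_mean))
})

test_that("outcome generation hits the configured rate scale", {
  Tn <- 20000
  base_cfg <- function(lrr, sigma, baseline) {
    scenario_config(T = Tn, P = 1, K_true = 1, true_weights = 1,
                    true_means = matrix(0, 1, 1),
                    true_covariances = list(diag(1)),
                    true_log_rr = lrr, baseline_rate = baseline,
                    sigma_eps = sigma, seed = 6L)
  }
  y0 <- generate_outcome(rep(1L, Tn), base_cfg(0, 0, 21.6), rep(0, Tn))
  expect_lt(abs(mean(y0) - 21.6), 3 * sqrt(21.6 / Tn))
  y2 <- generate_outcome(rep(1L, Tn), base_cfg(log(2), 0, 10), rep(0, Tn))
  expect_lt(abs(mean(y2) - 20), 3 * sqrt(20 / Tn))
  # log-normal mixing inflates the variance/mean ratio
  yb <- generate_outcome(rep(1L, Tn), base_cfg(0, 0.5, 21.6), rep(0, Tn))
  expect_gt(stats::var(yb) / mean(yb), stats::var(y0) / mean(y0))
  # rate overflow guarded
  expect_error(generate_outcome(rep(1L, Tn), base_cfg(60, 0, 21.6),
                                rep(0, Tn)), "overflow")
})

test_that("MCAR masking has the right rate and never touches the outcome", {
  X <- matrix(rnorm(1461 * 12), 1461, 12)
  expect_identical(inject_missingness(X, 0), X)
  Xm <- inject_missingness(X, 0.05, seed = 8)
  rate <- mean(is.na(Xm))
  se <- sqrt(0.05 * 0.95 / length(X))
  expect_lt(abs(rate - 0.05), 3 * se)
  expect_identical(Xm, inject_missingness(X, 0.05, seed = 8))
  expect_error(inject_missingness(X, 1), "rate")
  ser <- simulate_profile_series(preset_recovery(seed = 1, missing_rate = 0.1))
  expect_false(anyNA(ser$outcome))
  expect_true(anyNA(ser$exposures))
})

test_that("simulation is a pure function of the config", {
  a <- simulate_profile_series(preset_recovery(seed = 21))
  b <- simulate_profile_series(preset_recovery(seed = 21))
  expect_identical(a, b)
  c <- simulate_profile_series(preset_recovery(seed = 22))
  expect_false(identical(a$outcome, c$outcome))
})

test_that("the london-scale preset has the documented scale", {
  ser <- simulate_profile_series(preset_london_like(seed = 2))
  expect_length(ser$outcome, 1461)
  expect_equal(ncol(ser$exposures), 12)
  expect_lt(abs(mean(ser$outcome) - 21.6), 1.5)
  expect_lt(abs(mean(is.na(ser$exposures)) - 0.05), 0.01)
  expect_equal(sort(unique(ser$true_labels)), 1:3)
})

test_that("series CSV round-trips", {
  ser <- tiny_series()
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ser, path)
  back <- read_series_csv(path)
  expect_equal(back$dates, ser$dates)
  expect_equal(back$outcome, as.integer(ser$outcome))
  expect_equal(unname(back$exposures), unname(ser$exposures))
  expect_equal(back$temperature, ser$temperature, tolerance = 1e-12)
  expect_equal(back$true_labels, ser$true_labels)
})
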