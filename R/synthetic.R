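#' Configure a synthetic multipollutant time series
#'
#' Defines the generative model used by [simulate_profile_series()]: days fall
#' into `K_true` latent groups with multivariate normal exposure profiles (on
#' the normalised scale), and daily counts follow an overdispersed Poisson
#' whose log-rate combines a group-specific log relative risk, smooth
#' trend/seasonal/temperature contributions and a day-level Gaussian effect.
#'
#' @param T number of days.
#' @param P number of exposure metrics.
#' @param K_true number of latent day groups.
#' @param true_weights probability vector of length `K_true` (must sum to 1).
#' @param true_means `K_true x P` matrix of group means (normalised scale).
#' @param true_covariances list of `K_true` positive-definite `P x P` matrices.
#' @param true_log_rr length-`K_true` vector of log relative risks.
#' @param baseline_rate expected counts per day at relative risk 1
#'   (default 21.6, the London-scale daily respiratory deaths).
#' @param trend_amplitude amplitude (log-rate scale) of the long-term linear
#'   trend across the series.
#' @param seasonal_amplitude amplitude (log-rate scale) of the annual cycle in
#'   the outcome.
#' @param temperature_effect log-rate change per standard deviation of
#'   temperature.
#' @param sigma_eps standard deviation of the day-level log-rate effect
#'   (extra-Poisson variation).
#' @param missing_rate probability that an exposure cell is missing (MCAR),
#'   in `[0, 1)`.
#' @param exposure_lag days between an exposure profile and the outcome it
#'   drives (default 1, matching the analysis exposure window): day `t`'s
#'   count responds to the group of day `t - exposure_lag`.
#' @param temp_mean,temp_amplitude,temp_noise_sd mean (deg C), seasonal
#'   amplitude and day-to-day noise of the temperature surrogate; defaults
#'   give a range of roughly -1 to 29 deg C.
#' @param start_date first calendar day of the series.
#' @param seed integer seed; the whole generation is a pure function of
#'   (config, seed).
#' @return An object of class `scenario_config`.
#' @seealso [preset_recovery()], [preset_london_like()], [preset_null()]
#' @export
scenario_config <- function(T, P, K_true,
                            true_weights,
                            true_means,
                            true_covariances,
                            true_log_rr,
                            baseline_rate = 21.6,
                            trend_amplitude = 0.05,
                            seasonal_amplitude = 0.1,
                            temperature_effect = 0.04,
                            sigma_eps = 0.05,
                            missing_rate = 0,
                            exposure_lag = 1L,
                            temp_mean = 14.0,
                            temp_amplitude = 10.5,
                            temp_noise_sd = 2.0,
                            start_date = as.Date("2002-01-01"),
                            seed = 1L) {
  T <- as.integer(T); P <- as.integer(P); K_true <- as.integer(K_true)
  stopifnot(T >= 1, P >= 1, K_true >= 1)
  if (length(true_weights) != K_true || any(true_weights < 0))
    stop("true_weights must be a non-negative vector of length K_true")
  if (abs(sum(true_weights) - 1) > 1e-8)
    stop("true_weights must sum to 1")
  true_means <- as.matrix(true_means)
  if (!all(dim(true_means) == c(K_true, P)))
    stop("true_means must be a K_true x P matrix")
  if (length(true_covariances) != K_true)
    stop("true_covariances must be a list of K_true matrices")
  for (k in seq_len(K_true)) {
    S <- true_covariances[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("covariance ", k, " is not symmetric")
    chol_pd(S, paste0("covariance ", k, " is not positive-definite"))
  }
  if (length(true_log_rr) != K_true)
    stop("true_log_rr must have length K_true")
  stopifnot(baseline_rate > 0, sigma_eps >= 0)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(
    T = T, P = P, K_true = K_true,
    true_weights = as.numeric(true_weights),
    true_means = true_means,
    true_covariances = true_covariances,
    true_log_rr = as.numeric(true_log_rr),
    baseline_rate = baseline_rate,
    trend_amplitude = trend_amplitude,
    seasonal_amplitude = seasonal_amplitude,
    temperature_effect = temperature_effect,
    sigma_eps = sigma_eps,
    missing_rate = missing_rate,
    exposure_lag = as.integer(exposure_lag),
    temp_mean = temp_mean,
    temp_amplitude = temp_amplitude,
    temp_noise_sd = temp_noise_sd,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Draw latent day groups and exposure profiles
#'
#' Group labels are multinomial with the configured weights; row `t` of the
#' exposure matrix is drawn from the multivariate normal of its group.
#'
#' @param config a [scenario_config()].
#' @return list with `exposures` (`T x P` matrix, complete) and `labels`.
#' @export
generate_exposures <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$seed, "exposures"))
  labels <- sample.int(config$K_true, config$T, replace = TRUE,
                       prob = config$true_weights)
  X <- matrix(NA_real_, config$T, config$P)
  for (k in seq_len(config$K_true)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    R <- chol_pd(config$true_covariances[[k]])
    noise <- matrix(stats::rnorm(length(idx) * config$P), length(idx)) %*% R
    X[idx, ] <- sweep(noise, 2, config$true_means[k, ], `+`)
  }
  colnames(X) <- paste0("z_", seq_len(config$P))
  list(exposures = X, labels = labels)
}

#' Generate the temperature surrogate and calendar index
#'
#' Temperature is a sinusoid with period 365.25 days (peak in mid July) plus
#' Gaussian noise, parameterised so its range roughly matches daily mean
#' temperatures observed in central London (about -1 to 29 deg C).  Only its
#' role as a smooth confounder matters downstream.
#'
#' @param config a [scenario_config()].
#' @return list with `temperature` (length `T`) and `day_index` (`1:T`).
#' @export
generate_confounders <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$seed, "confounders"))
  t_idx <- seq_len(config$T)
  seasonal <- config$temp_amplitude * sin(2 * pi * (t_idx - 105) / 365.25)
  noise <- if (config$temp_noise_sd > 0)
    stats::rnorm(config$T, 0, config$temp_noise_sd) else 0
  list(temperature = config$temp_mean + seasonal + noise,
       day_index = t_idx)
}

# Smooth log-rate contribution of the confounders: centred linear long-term
# trend + annual cosine + linear-in-standardised-temperature effect.
outcome_contributions <- function(config, temperature, day_index) {
  tc <- 2 * (day_index - (config$T + 1) / 2) / config$T   # in [-1, 1]
  seas <- cos(2 * pi * day_index / 365.25)
  z_temp <- if (stats::sd(temperature) > 0)
    (temperature - mean(temperature)) / stats::sd(temperature)
  else rep(0, length(temperature))
  config$trend_amplitude * tc +
    config$seasonal_amplitude * seas +
    config$temperature_effect * z_temp
}

#' Generate daily counts given group labels and smooth contributions
#'
#' `y_t ~ Poisson(E exp(mu_g_t + contribution_t + eps_t))` with
#' `eps_t ~ N(0, sigma_eps^2)` and offset `E = baseline_rate`.
#'
#' @param labels integer group labels (length `T`).
#' @param config a [scenario_config()].
#' @param spline_contributions length-`T` smooth log-rate contribution.
#' @return integer count vector of length `T`.
#' @export
generate_outcome <- function(labels, config, spline_contributions) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(spline_contributions) != config$T)
    stop("spline_contributions must have length T")
  set.seed(stage_seed(config$seed, "outcome"))
  eps <- if (config$sigma_eps > 0)
    stats::rnorm(config$T, 0, config$sigma_eps) else numeric(config$T)
  log_rate <- log(config$baseline_rate) + config$true_log_rr[labels] +
    spline_contributions + eps
  if (any(abs(log_rate) > 50))
    stop("log-rate overflow: |log rate| > 50; check configured effects")
  y <- stats::rpois(config$T, exp(log_rate))
  attr(y, "log_rate") <- log_rate            # realised rate, useful as truth
  y
}

#' Set exposure cells missing completely at random
#'
#' Each cell is masked independently with probability `rate` (MCAR).  The
#' outcome is never masked.
#'
#' @param x exposure matrix.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed (fixed seed gives an identical mask).
#' @return `x` with masked entries set to `NA`.
#' @export
inject_missingness <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(x)
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(x)) < rate, nrow(x))
  x[mask] <- NA_real_
  x
}

#' Simulate a complete synthetic series
#'
#' Composes [generate_exposures()], [generate_confounders()],
#' [generate_outcome()] and [inject_missingness()] into one dataset carrying
#' dates, exposures (with missing cells), counts, temperature and the true
#' labels.  The whole object is a pure function of the config (which includes
#' the seed).
#'
#' @param config a [scenario_config()].
#' @return An object of class `profile_series`: a list with `dates`,
#'   `exposures`, `outcome`, `temperature`, `true_labels` and the `config`;
#'   the smooth log-rate contribution is kept in attribute `"contributions"`.
#' @export
simulate_profile_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ex <- generate_exposures(config)
  cf <- generate_confounders(config)
  contrib <- outcome_contributions(config, cf$temperature, cf$day_index)
  # day t's count responds to the exposure profile of day t - exposure_lag
  # (the first lag days fall back to their own-day group; the analysis drops
  # them anyway when aligning by date)
  lab_eff <- ex$labels[pmax(seq_len(config$T) - config$exposure_lag, 1L)]
  y <- generate_outcome(lab_eff, config, contrib)
  lr <- attr(y, "log_rate")
  Z <- inject_missingness(ex$exposures, config$missing_rate,
                          stage_seed(config$seed, "missing"))
  out <- structure(list(
    dates = config$start_date + cf$day_index - 1L,
    exposures = Z,
    outcome = as.integer(y),
    temperature = cf$temperature,
    true_labels = ex$labels,
    config = config
  ), class = "profile_series")
  attr(out, "contributions") <- contrib
  attr(out, "log_rate") <- lr
  out
}

#' @export
print.profile_series <- function(x, ...) {
  cat("profile_series:", length(x$outcome), "days,",
      ncol(x$exposures), "exposure metrics,",
      sum(is.na(x$exposures)), "missing cells\n")
  invisible(x)
}

#' Synthetic presets
#'
#' `preset_recovery()` is the boosted-effect recovery benchmark: 730 days,
#' 6 metrics, 3 groups with weights 0.6/0.25/0.15, group means separated by
#' more than 3 standard deviations, log relative risks -0.3/0/0.3 and
#' `sigma_eps = 0.05` -- effects large enough that a scaled-down MCMC run has
#' power to recover both the partition and the risks.
#' `preset_london_like()` emulates the scale of the London analysis: 1461
#' days, 12 correlated metrics, group weights 0.79/0.04/0.17 (mimicking
#' cluster sizes 1156/63/242), baseline 21.6 deaths/day, relative risks
#' 0.98/1.00/1.02 and 5% MCAR missingness.
#' `preset_null()` has a single group at relative risk 1 for calibration
#' checks.
#'
#' @param seed integer seed.
#' @param missing_rate MCAR missingness rate for the recovery preset
#'   (default 0; set to 0.05 for missingness-robustness checks).
#' @return A [scenario_config()].
#' @export
preset_recovery <- function(seed = 1L, missing_rate = 0) {
  P <- 6
  means <- rbind(rep(0, P),
                 c(3.5, 3.5, 3.5, 0, 0, 0),
                 c(0, 0, 0, 3.5, 3.5, 3.5))
  scenario_config(
    T = 730, P = P, K_true = 3,
    true_weights = c(0.6, 0.25, 0.15),
    true_means = means,
    true_covariances = rep(list(diag(P)), 3),
    true_log_rr = c(-0.3, 0, 0.3),
    baseline_rate = 21.6,
    sigma_eps = 0.05,
    missing_rate = missing_rate,
    seed = seed
  )
}

#' @rdname preset_recovery
#' @export
preset_london_like <- function(seed = 1L) {
  P <- 12
  # Qualitative profile structure: group 1 low on most metrics, group 2 high
  # on primary/traffic metrics, group 3 dominated by secondary (non-primary)
  # particles; equicorrelated within-group covariance.
  m1 <- rep(-0.2, P); m1[2] <- 0.2
  m2 <- rep(0, P); m2[c(1, 5, 9)] <- 1.6; m2[c(2, 3, 4)] <- -0.5
  m3 <- rep(0.3, P); m3[c(3, 4, 10, 11)] <- 1.8; m3[2] <- -0.5
  S <- 0.7 * diag(P) + 0.3
  scenario_config(
    T = 1461, P = P, K_true = 3,
    true_weights = c(0.79, 0.04, 0.17),
    true_means = rbind(m1, m2, m3),
    true_covariances = rep(list(S), 3),
    true_log_rr = c(log(0.98), 0, log(1.02)),
    baseline_rate = 21.6,
    sigma_eps = 0.05,
    missing_rate = 0.05,
    seed = seed
  )
}

#' @rdname preset_recovery
#' @export
preset_null <- function(seed = 1L) {
  P <- 6
  scenario_config(
    T = 730, P = P, K_true = 1,
    true_weights = 1,
    true_means = matrix(0, 1, P),
    true_covariances = list(diag(P)),
    true_log_rr = 0,
    baseline_rate = 21.6,
    sigma_eps = 0.05,
    missing_rate = 0,
    seed = seed
  )
}

#' Write / read a synthetic series as CSV
#'
#' Columns: `date` (ISO-8601), `y`, `z_1..z_P`, `temperature`, `true_label`.
#' Missing exposure cells are written as empty fields and read back as `NA`.
#'
#' @param series a `profile_series`.
#' @param path file path.
#' @return `write_series_csv()` returns `path` invisibly;
#'   `read_series_csv()` returns a `profile_series` (without a config).
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "profile_series"))
  df <- data.frame(date = format(series$dates, "%Y-%m-%d"),
                   y = series$outcome,
                   series$exposures,
                   temperature = series$temperature,
                   true_label = series$true_labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"))
  zcols <- grep("^z_", names(df), value = TRUE)
  structure(list(
    dates = as.Date(df$date),
    exposures = as.matrix(df[zcols]),
    outcome = as.integer(df$y),
    temperature = df$temperature,
    true_labels = if ("true_label" %in% names(df)) df$true_label else NULL,
    config = NULL
  ), class = "profile_series")
}
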