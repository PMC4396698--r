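#' Define a new exposure scenario
#'
#' A scenario carries daily exposure profiles in original units, which are
#' normalised with the TRAINING medians and MADs (the model's covariate
#' space is defined by the training normalisation).  Temperature is
#' optional; when absent the temperature contribution is fixed at its
#' training mean per draw.
#'
#' @param exposures matrix of daily exposures in original units, columns in
#'   the training column order (missing cells allowed).
#' @param normalization the training [normalize_exposures()] object.
#' @param temperature optional daily temperature series.
#' @param dates optional dates.
#' @param normalized set `TRUE` if `exposures` is already on the normalised
#'   scale.
#' @return object of class `exposure_scenario`.
#' @export
new_scenario <- function(exposures, normalization, temperature = NULL,
                         dates = NULL, normalized = FALSE) {
  X <- as.matrix(exposures)
  P <- length(normalization$medians)
  if (ncol(X) != P)
    stop("scenario has ", ncol(X), " exposure columns but the model was ",
         "trained with ", P)
  nm <- names(normalization$medians)
  if (!is.null(colnames(X)) && !is.null(nm) && any(nzchar(nm)) &&
      !identical(colnames(X), nm))
    stop("scenario exposure columns must match the training column order")
  z <- if (normalized) X else
    sweep(sweep(X, 2, normalization$medians, `-`), 2, normalization$mads, `/`)
  if (!is.null(temperature) && length(temperature) != nrow(X))
    stop("temperature must have one value per scenario day")
  structure(list(z = z, temperature = temperature, dates = dates),
            class = "exposure_scenario")
}

# Allocation log-probabilities of one state's occupied clusters for each
# scenario day (marginal MVN over observed coordinates).
scenario_alloc_logprob <- function(stt, z) {
  ks <- sort(unique(stt$g))
  lp <- matrix(-Inf, nrow(z), length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    lp[, i] <- log(stt$w[k]) + mvn_logdensity(z, stt$m[k, ], stt$Q[[k]])
  }
  list(ks = ks, lp = lp)
}

#' Posterior predictive counts under an exposure scenario
#'
#' For each retained posterior draw and scenario day: the day is allocated
#' to one of that draw's occupied clusters with probability proportional to
#' `w_k p(z* | Theta_k)`; the rate is
#' `lambda* = E exp(mu_k + confounder contribution + eps*)` with a fresh
#' day effect `eps* ~ N(0, sigma_eps^2)`, and a count is drawn Poisson.
#' The calendar-time spline contribution is fixed at its training-period
#' mean (or the final training year's mean); the temperature contribution
#' uses the scenario's own temperature when provided, else its training
#' mean.
#'
#' @param chain a `profreg_chain`.
#' @param scenario a [new_scenario()].
#' @param offset scalar expected count (or the training offset vector).
#' @param design the training [build_spline_design()].
#' @param time_reference `"training_mean"` (default) or `"final_year"`.
#' @param seed integer seed for the predictive draws.
#' @param draw_counts if `FALSE`, return expected rates without Poisson
#'   noise.
#' @return object of class `scenario_prediction`: list with `counts`
#'   (draws x days), `total` (per-draw total over the scenario days),
#'   `daily_mean`, `daily_lower`, `daily_upper` and `summary`.
#' @export
predict_scenario <- function(chain, scenario, offset, design,
                             time_reference = c("training_mean",
                                                "final_year"),
                             seed = 1L, draw_counts = TRUE) {
  stopifnot(inherits(chain, "profreg_chain"),
            inherits(scenario, "exposure_scenario"))
  time_reference <- match.arg(time_reference)
  E <- offset[1]
  ndays <- nrow(scenario$z)
  ndraw <- chain$n_draws
  has_design <- inherits(design, "spline_design")
  if (has_design) {
    Ut <- sweep(design$parts$time, 2, design$col_means$time)
    time_rows <- if (time_reference == "final_year")
      seq(max(1L, nrow(Ut) - 364L), nrow(Ut)) else seq_len(nrow(Ut))
    Uw_train <- sweep(design$parts$temperature, 2,
                      design$col_means$temperature)
    Uw_new <- if (!is.null(scenario$temperature))
      sweep(stats::predict(design$parts$temperature, scenario$temperature),
            2, design$col_means$temperature) else NULL
  }
  set.seed(as.integer(seed))
  counts <- matrix(NA_real_, ndraw, ndays)
  for (s in seq_len(ndraw)) {
    stt <- chain$states[[s]]
    al <- scenario_alloc_logprob(stt, scenario$z)
    gm <- al$lp - log(-log(stats::runif(ndays * ncol(al$lp))))
    k_star <- al$ks[max.col(gm, ties.method = "first")]
    if (has_design) {
      bt <- stt$beta[design$cols$time]
      bw <- stt$beta[design$cols$temperature]
      time_part <- mean(Ut[time_rows, , drop = FALSE] %*% bt)
      temp_part <- if (!is.null(Uw_new)) drop(Uw_new %*% bw) else
        mean(Uw_train %*% bw)
    } else {
      time_part <- 0; temp_part <- 0
    }
    eps_star <- stats::rnorm(ndays, 0, stt$sigma_eps)
    lam <- E * exp(stt$mu[k_star] + time_part + temp_part + eps_star)
    counts[s, ] <- if (draw_counts) stats::rpois(ndays, lam) else lam
  }
  total <- rowSums(counts)
  qs <- apply(counts, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
  structure(list(
    counts = counts,
    total = total,
    daily_mean = colMeans(counts),
    daily_lower = qs[1, ],
    daily_upper = qs[2, ],
    summary = c(mean_total = mean(total),
                lower_total = stats::quantile(total, 0.025, names = FALSE),
                upper_total = stats::quantile(total, 0.975, names = FALSE))
  ), class = "scenario_prediction")
}

#' Percent change between two scenario predictions
#'
#' Per posterior draw, `100 (total_B - total_A) / total_A`, paired by draw;
#' summarised by the mean and a central 95% interval.  Draws with a zero
#' denominator are excluded with a warning.
#'
#' @param pred_A,pred_B [predict_scenario()] results with equally many
#'   draws; totals are aligned to equal day counts (truncated to the
#'   shorter scenario) before comparison.
#' @return list with `draws`, `mean`, `lower`, `upper`.
#' @export
percent_change <- function(pred_A, pred_B) {
  if (nrow(pred_A$counts) != nrow(pred_B$counts))
    stop("predictions must hold the same number of posterior draws")
  nd <- min(ncol(pred_A$counts), ncol(pred_B$counts))
  tA <- rowSums(pred_A$counts[, seq_len(nd), drop = FALSE])
  tB <- rowSums(pred_B$counts[, seq_len(nd), drop = FALSE])
  keep <- tA > 0
  if (!all(keep))
    warning(sum(!keep), " draws with zero baseline total excluded")
  pc <- 100 * (tB[keep] - tA[keep]) / tA[keep]
  list(draws = pc, mean = mean(pc),
       lower = stats::quantile(pc, 0.025, names = FALSE),
       upper = stats::quantile(pc, 0.975, names = FALSE))
}

#' Predictive cross-validation
#'
#' Splits the series at a date, fits the full model on the training part
#' only, predicts the held-out days from their (lagged) exposures and
#' temperature, and reports the coverage of the observed counts by the 95%
#' predictive intervals together with mean absolute errors.
#'
#' @param series a `profile_series`.
#' @param split_date first day of the validation sample.
#' @param lag exposure lag in days.
#' @param time_df_per_year,temp_df spline df for the confounders.
#' @param mcmc a [mcmc_config()].
#' @param seed seed for the predictive draws.
#' @return list with `coverage`, `mae_validation`, `mae_training`,
#'   `prediction` and the training `fit`.
#' @export
cross_validate <- function(series, split_date, lag = 1L,
                           time_df_per_year = 8, temp_df = 3,
                           mcmc = mcmc_config_small(), seed = 1L) {
  split_date <- as.Date(split_date)
  dates <- as.Date(series$dates)
  if (split_date <= min(dates) || split_date > max(dates))
    stop("split_date must fall inside the series")
  train_idx <- which(dates < split_date)
  valid_idx <- which(dates >= split_date)
  subset_series <- function(idx) structure(list(
    dates = dates[idx],
    exposures = series$exposures[idx, , drop = FALSE],
    outcome = series$outcome[idx],
    temperature = series$temperature[idx],
    true_labels = series$true_labels[idx],
    config = series$config), class = "profile_series")
  fit <- profile_regression(subset_series(train_idx), lag = lag,
                            time_df_per_year = time_df_per_year,
                            temp_df = temp_df, mcmc = mcmc)
  if (length(unique(fit$partition$labels)) < 2)
    warning("training partition has fewer than 2 occupied clusters")
  valid <- lag_exposures(subset_series(valid_idx), lag = lag)
  scen <- new_scenario(valid$exposures, fit$normalization,
                       temperature = valid$temperature, dates = valid$dates)
  pred <- predict_scenario(fit$chain, scen, fit$offset, fit$design,
                           seed = stage_seed(seed, "cv"))
  y_v <- valid$outcome
  coverage <- mean(y_v >= pred$daily_lower & y_v <= pred$daily_upper)
  scen_tr <- new_scenario(fit$data$exposures, fit$normalization,
                          temperature = fit$data$temperature)
  pred_tr <- predict_scenario(fit$chain, scen_tr, fit$offset, fit$design,
                              seed = stage_seed(seed, "predict"))
  list(coverage = coverage,
       mae_validation = mean(abs(y_v - pred$daily_mean)),
       mae_training = mean(abs(fit$data$outcome - pred_tr$daily_mean)),
       prediction = pred,
       fit = fit)
}
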