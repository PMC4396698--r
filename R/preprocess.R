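#' Modified z-score normalisation
#'
#' Robust scaling `z = (x - Median(x)) / Median(|x - Median(x)|)` computed
#' over the observed entries only; missing entries stay missing.  After
#' normalisation the observed values have median 0 and median absolute
#' deviation 1, putting heterogeneous particle metrics on a comparable scale.
#'
#' @param x numeric vector, possibly with `NA`.
#' @return list with `z`, `median` and `mad` (both in original units).
#' @export
modified_zscore <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2)
    stop("degenerate column: fewer than 2 distinct observed values")
  med <- stats::median(obs)
  mad_raw <- stats::median(abs(obs - med))
  if (mad_raw == 0)
    stop("degenerate column: median absolute deviation is 0; ",
         "drop or recode this metric rather than dividing by zero")
  list(z = (x - med) / mad_raw, median = med, mad = mad_raw)
}

#' Normalise an exposure matrix column-wise
#'
#' Applies [modified_zscore()] per column, keeping the per-column medians and
#' MADs so summaries (and new scenarios) can be mapped back to original
#' units.
#'
#' @param x `T x P` exposure matrix (missing entries allowed).
#' @return object of class `normalized_exposures`: list with `z`, `medians`,
#'   `mads`.
#' @export
normalize_exposures <- function(x) {
  x <- as.matrix(x)
  P <- ncol(x)
  z <- x
  medians <- mads <- numeric(P)
  for (p in seq_len(P)) {
    r <- tryCatch(modified_zscore(x[, p]), error = function(e)
      stop("column ", colnames(x)[p] %||% p, ": ", conditionMessage(e),
           call. = FALSE))
    z[, p] <- r$z; medians[p] <- r$median; mads[p] <- r$mad
  }
  names(medians) <- names(mads) <- colnames(x)
  structure(list(z = z, medians = medians, mads = mads),
            class = "normalized_exposures")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map normalised values back to original units
#'
#' @param z normalised matrix (columns in the training column order).
#' @param medians,mads training normalisation constants.
#' @return matrix in original units.
#' @export
denormalize_exposures <- function(z, medians, mads) {
  sweep(sweep(as.matrix(z), 2, mads, `*`), 2, medians, `+`)
}

#' Align outcomes with lagged exposures by date
#'
#' Pairs the outcome (and temperature) of day `t` with the exposure profile
#' of day `t - lag`, aligning by calendar date so that gaps in the series are
#' respected: an outcome day whose `t - lag` date is absent is excluded
#' rather than paired with the wrong row.
#'
#' @param series a `profile_series` (or list with `dates`, `exposures`,
#'   `outcome`, `temperature`, optionally `true_labels`).
#' @param lag non-negative integer number of days (default 1, the exposure
#'   window used for particles).
#' @return a `profile_series` of the aligned rows; attribute
#'   `"exposure_dates"` records the date each exposure row was measured.
#' @export
lag_exposures <- function(series, lag = 1L) {
  lag <- as.integer(lag)
  Tn <- length(series$outcome)
  if (lag < 0) stop("lag must be non-negative")
  if (lag >= Tn) stop("lag must be smaller than the series length")
  dates <- as.Date(series$dates)
  src <- match(dates - lag, dates)         # exposure row feeding each outcome day
  keep <- which(!is.na(src))
  out <- structure(list(
    dates = dates[keep],
    exposures = series$exposures[src[keep], , drop = FALSE],
    outcome = series$outcome[keep],
    temperature = series$temperature[keep],
    true_labels = if (!is.null(series$true_labels))
      series$true_labels[src[keep]] else NULL,
    config = series$config
  ), class = "profile_series")
  attr(out, "exposure_dates") <- dates[src[keep]]
  out
}

#' Natural cubic spline basis
#'
#' Wraps [splines::ns()]: interior knots at equally spaced quantiles of the
#' values, boundary knots at the data extremes.  The returned object keeps
#' the knot attributes, so `predict()` evaluates the same basis at new
#' values.
#'
#' @param values numeric vector (finite).
#' @param df degrees of freedom (number of basis columns), `>= 1`.
#' @return an `ns` basis matrix with `df` columns.
#' @export
natural_spline_basis <- function(values, df) {
  df <- as.integer(df)
  if (df < 1) stop("df must be >= 1")
  if (!all(is.finite(values))) stop("values must be finite")
  if (df > length(unique(values)))
    stop("df exceeds the number of distinct values")
  splines::ns(values, df = df)
}

#' Build the fixed confounder design matrix
#'
#' Natural cubic spline bases for calendar time (`time_df_per_year` df per
#' year, 8 by default) and temperature (`temp_df` df, 3 by default), built
#' once and entered into the model as fixed data.
#'
#' @param day_index integer day index (1..T, may have gaps).
#' @param temperature daily mean temperature.
#' @param time_df_per_year df per 365.25 days of calendar time.
#' @param temp_df df for temperature.
#' @param time_df optional total df for time, overriding the per-year rule.
#' @return object of class `spline_design`: list with `basis` (`T x H`),
#'   `parts` (the `ns` objects), `df` and column index `cols` per variable.
#' @export
build_spline_design <- function(day_index, temperature,
                                time_df_per_year = 8, temp_df = 3,
                                time_df = NULL) {
  n_years <- length(day_index) / 365.25
  if (is.null(time_df)) time_df <- max(1L, round(time_df_per_year * n_years))
  bt <- natural_spline_basis(day_index, time_df)
  bw <- natural_spline_basis(temperature, temp_df)
  # centre each column over the training days: the smooths then exclude
  # constants, so the overall level is identified through the cluster log
  # relative risks (the standard identifiability constraint for additive
  # smooth terms)
  cm <- list(time = colMeans(bt), temperature = colMeans(bw))
  basis <- cbind(sweep(bt, 2, cm$time), sweep(bw, 2, cm$temperature))
  if (!all(is.finite(basis))) stop("spline basis contains non-finite values")
  colnames(basis) <- c(paste0("time_", seq_len(ncol(bt))),
                       paste0("temp_", seq_len(ncol(bw))))
  structure(list(
    basis = basis,
    parts = list(time = bt, temperature = bw),
    col_means = cm,
    df = c(time = ncol(bt), temperature = ncol(bw)),
    cols = list(time = seq_len(ncol(bt)),
                temperature = ncol(bt) + seq_len(ncol(bw)))
  ), class = "spline_design")
}

#' Select spline degrees of freedom by AIC/BIC
#'
#' Fits a log-linear Poisson regression of the counts on the joint
#' time + temperature spline design with a log offset, for every candidate
#' (time df, temperature df) pair, and tabulates AIC and BIC.  The default
#' choice minimises AIC, breaking ties towards the smaller total df.  The
#' partial autocorrelation function of the deviance residuals at the chosen
#' df is returned for inspection of residual serial structure.
#'
#' @param y count vector.
#' @param day_index,temperature confounder values.
#' @param offset positive offset vector (e.g. from [compute_offset()]).
#' @param time_df_grid,temp_df_grid integer candidate grids (total df).
#' @return list with `choice` (named vector), `table` (one row per candidate
#'   with AIC/BIC and convergence flag) and `residual_pacf`.
#' @export
select_df <- function(y, day_index, temperature, offset,
                      time_df_grid, temp_df_grid = 3L) {
  if (!length(time_df_grid) || !length(temp_df_grid))
    stop("candidate grids must be non-empty")
  grid <- expand.grid(time_df = sort(as.integer(time_df_grid)),
                      temp_df = sort(as.integer(temp_df_grid)))
  grid <- grid[order(grid$time_df + grid$temp_df,
                     grid$time_df, grid$temp_df), , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- tryCatch({
      X <- cbind(natural_spline_basis(day_index, grid$time_df[i]),
                 natural_spline_basis(temperature, grid$temp_df[i]))
      stats::glm(y ~ X, family = stats::poisson(), offset = log(offset))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged)
      return(list(aic = NA_real_, bic = NA_real_, fit = NULL))
    list(aic = stats::AIC(fit), bic = stats::BIC(fit), fit = fit)
  })
  tab <- cbind(grid,
               aic = vapply(res, `[[`, numeric(1), "aic"),
               bic = vapply(res, `[[`, numeric(1), "bic"))
  tab$converged <- !is.na(tab$aic)
  if (!any(tab$converged)) stop("no candidate fit converged")
  best <- which.min(tab$aic)               # grid sorted by df: ties -> smaller
  fit <- res[[best]]$fit
  pacf_res <- stats::pacf(stats::residuals(fit, type = "deviance"),
                          plot = FALSE)
  list(choice = c(time_df = tab$time_df[best], temp_df = tab$temp_df[best]),
       table = tab,
       residual_pacf = pacf_res)
}

#' Constant expected-count offset
#'
#' The offset is the arithmetic mean of the daily counts over the full study
#' period, so `exp(mu_k)` reads as a relative risk against the period
#' average.
#'
#' @param y count vector.
#' @return numeric vector of length `length(y)`, all equal to `mean(y)`.
#' @export
compute_offset <- function(y) {
  if (!length(y)) stop("empty outcome vector")
  E <- mean(y)
  if (E == 0) stop("degenerate offset: all counts are zero, model undefined")
  rep(E, length(y))
}

#' Black smoke from black carbon
#'
#' Scales aethalometer black-carbon measurements onto the black smoke scale
#' using a fixed adjustment factor (0.27).
#'
#' @param x black carbon values.
#' @param factor scalar adjustment factor.
#' @return scaled values.
#' @export
bs_from_black_carbon <- function(x, factor = 0.27) x * factor
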