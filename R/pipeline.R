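#' Fit the joint profile-regression model to a daily series
#'
#' High-level wrapper composing the full analysis: lag alignment,
#' modified-z-score normalisation, spline design for calendar time and
#' temperature, constant offset, empirical-Bayes hyperparameters, MCMC, and
#' the representative-partition post-processing.
#'
#' @param series a `profile_series` (from [simulate_profile_series()] or
#'   [read_timeseries_csv()]).
#' @param lag exposure lag in days (default 1).
#' @param time_df_per_year,temp_df spline degrees of freedom (defaults 8 per
#'   year and 3).
#' @param mcmc a [mcmc_config()].
#' @param alpha_prior length-2 vector `(a, b)` of the Gamma prior on the DP
#'   concentration (default `c(2, 1)`).
#' @param phi_mode `"diagonal"` or `"full"` Wishart scale construction.
#' @param k_range candidate numbers of representative clusters.
#' @return object of class `profreg_fit`: list with `chain`, `partition`,
#'   `similarity`, `summaries`, `design`, `normalization`, `offset` and the
#'   aligned `data`.
#' @export
profile_regression <- function(series, lag = 1L,
                               time_df_per_year = 8, temp_df = 3,
                               mcmc = mcmc_config_small(),
                               alpha_prior = c(2, 1),
                               phi_mode = "diagonal",
                               k_range = 2:6) {
  aligned <- lag_exposures(series, lag = lag)
  norm <- normalize_exposures(aligned$exposures)
  design <- build_spline_design(seq_along(aligned$outcome),
                                aligned$temperature,
                                time_df_per_year = time_df_per_year,
                                temp_df = temp_df)
  offset <- compute_offset(aligned$outcome)
  hyper <- empirical_hyperparams(norm, a = alpha_prior[1], b = alpha_prior[2],
                                 phi_mode = phi_mode)
  chain <- run_mcmc(aligned$outcome, norm, design, offset, hyper, mcmc)
  S <- similarity_matrix(chain)
  partition <- representative_partition(S, k_range = k_range)
  summaries <- cluster_summaries(chain, partition, norm)
  structure(list(chain = chain, partition = partition, similarity = S,
                 summaries = summaries, design = design,
                 normalization = norm, offset = offset, data = aligned,
                 settings = list(lag = lag,
                                 time_df_per_year = time_df_per_year,
                                 temp_df = temp_df,
                                 alpha_prior = alpha_prior,
                                 phi_mode = phi_mode, k_range = k_range)),
            class = "profreg_fit")
}

#' @export
print.profreg_fit <- function(x, ...) {
  print(x$partition)
  rr <- x$summaries$relative_risk
  for (i in seq_len(nrow(rr)))
    cat(sprintf("cluster %d (%d days): RR %.3f (%.3f, %.3f)\n",
                rr$cluster[i], rr$size[i], rr$mean[i], rr$lower[i],
                rr$upper[i]))
  invisible(x)
}

#' Read / write a daily time-series CSV
#'
#' Schema: `date` (ISO-8601), `y` (counts), `z_1..z_P` exposures,
#' `temperature`.  Empty cells and `"NA"` both parse as missing.  Duplicate
#' dates are a schema error naming the offending dates; calendar gaps are
#' reported as an attribute.
#'
#' @param path CSV file path.
#' @return a `profile_series` (attribute `"gaps"` lists missing calendar
#'   days, if any).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"))
  need <- c("date", "y", "temperature")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "),
         " and z_1..z_P")
  dates <- as.Date(df$date)
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop("unparseable dates at rows: ", paste(utils::head(bad, 5),
                                              collapse = ", "))
  }
  if (anyDuplicated(dates)) {
    dup <- unique(dates[duplicated(dates)])
    stop("duplicate dates: ", paste(format(dup), collapse = ", "))
  }
  zcols <- grep("^z_", names(df), value = TRUE)
  if (!length(zcols)) stop("no exposure columns (z_1..z_P) found")
  if (anyNA(df$y) || anyNA(suppressWarnings(as.numeric(df$y))))
    stop("unparseable or missing outcome counts")
  out <- structure(list(
    dates = dates,
    exposures = as.matrix(df[zcols]),
    outcome = as.integer(df$y),
    temperature = as.numeric(df$temperature),
    true_labels = if ("true_label" %in% names(df)) df$true_label else NULL,
    config = NULL
  ), class = "profile_series")
  full <- seq(min(dates), max(dates), by = "day")
  gaps <- setdiff(format(full), format(dates))
  if (length(gaps)) attr(out, "gaps") <- gaps
  out
}

#' Run the full analysis end to end and write all outputs
#'
#' Reads the input CSV (or takes a `profile_series` directly), fits the
#' model, and writes: similarity matrix, partition labels, cluster summary
#' tables, membership probabilities, trace summaries, a run manifest
#' (settings, seed, package version) and a human-readable report.  Rerunning
#' with an identical configuration and seed reproduces the outputs exactly.
#'
#' @param input path to a time-series CSV or a `profile_series`.
#' @param output_dir directory for outputs (created if needed).
#' @param ... passed to [profile_regression()].
#' @param mcmc a [mcmc_config()].
#' @return the `profreg_fit`, invisibly; outputs on disk.
#' @export
run_full_analysis <- function(input, output_dir, mcmc = mcmc_config_small(),
                              ...) {
  series <- if (inherits(input, "profile_series")) input else
    read_timeseries_csv(input)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "fit"
  fit <- tryCatch(profile_regression(series, mcmc = mcmc, ...),
                  error = function(e) {
                    manifest <- list(status = "error", stage = stage,
                                     message = conditionMessage(e))
                    jsonlite::write_json(manifest,
                                         file.path(output_dir, "manifest.json"),
                                         auto_unbox = TRUE)
                    stop("stage '", stage, "' failed: ",
                         conditionMessage(e), call. = FALSE)
                  })
  utils::write.csv(as.data.frame(unclass(fit$similarity)),
                   file.path(output_dir, "similarity_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(date = format(fit$data$dates),
                              label = fit$partition$labels,
                              silhouette = fit$partition$silhouette_width),
                   file.path(output_dir, "partition.csv"), row.names = FALSE)
  utils::write.csv(fit$summaries$relative_risk,
                   file.path(output_dir, "relative_risk.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$summaries$profiles,
                   file.path(output_dir, "cluster_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(membership_probabilities(fit$chain,
                                                          fit$partition)),
                   file.path(output_dir, "membership_probabilities.csv"),
                   row.names = FALSE)
  diag <- chain_diagnostics(fit$chain)
  utils::write.csv(diag$summary, file.path(output_dir, "diagnostics.csv"),
                   row.names = FALSE)
  manifest <- list(
    status = "ok",
    package_version = as.character(utils::packageVersion("profregts")),
    r_version = R.version.string,
    seed = fit$chain$config$seed,
    mcmc = fit$chain$config[c("n_iter", "burn_in", "thin", "init_clusters",
                              "rho")],
    settings = fit$settings,
    n_days = length(fit$data$outcome),
    n_draws = fit$chain$n_draws,
    acceptance = as.list(fit$chain$acceptance)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  rr <- fit$summaries$relative_risk
  report <- c(
    sprintf("Representative clustering: %d clusters of sizes %s",
            fit$partition$k,
            paste(rr$size, collapse = "/")),
    sprintf("cluster %d: RR %.3f (95%% CI %.3f, %.3f)",
            rr$cluster, rr$mean, rr$lower, rr$upper),
    sprintf("median occupied clusters per sweep: %.0f",
            stats::median(diag$traces$n_occupied)),
    sprintf("acceptance rates: mu %.2f, beta %.2f, eps %.2f",
            fit$chain$acceptance["mu"], fit$chain$acceptance["beta"],
            fit$chain$acceptance["eps"]))
  writeLines(report, file.path(output_dir, "report.txt"))
  invisible(fit)
}

#' Sensitivity of the clustering to the DP concentration prior
#'
#' Refits the model under each Gamma prior for the concentration parameter
#' and reports, per prior: the median number of occupied clusters per sweep,
#' the median number of well-populated clusters (occupancy above a day
#' threshold, default 9 days), the representative cluster sizes, and the
#' pairwise adjusted Rand index between the representative partitions.
#'
#' @param series a `profile_series`.
#' @param alpha_priors list of length-2 vectors `(a, b)`, at least two.
#' @param well_populated_min clusters with more than this many days in a
#'   sweep count as well populated.
#' @param mcmc a [mcmc_config()].
#' @param ... passed to [profile_regression()].
#' @return object of class `sensitivity_report`: list with `per_prior`
#'   (data frame), `pairwise_ari` (matrix) and the `fits`.
#' @export
run_sensitivity <- function(series, alpha_priors,
                            well_populated_min = 9L,
                            mcmc = mcmc_config_small(), ...) {
  if (!is.list(alpha_priors) || length(alpha_priors) < 2)
    stop("provide at least two (a, b) prior settings")
  fits <- lapply(alpha_priors, function(pr)
    profile_regression(series, mcmc = mcmc, alpha_prior = pr, ...))
  per_prior <- do.call(rbind, lapply(seq_along(fits), function(i) {
    ch <- fits[[i]]$chain
    occ <- ch$traces$n_occupied[ch$traces$iter > ch$config$burn_in]
    wp <- vapply(ch$states, function(s) {
      sum(tabulate(s$g, max(s$g)) > well_populated_min)
    }, integer(1))
    data.frame(a = alpha_priors[[i]][1], b = alpha_priors[[i]][2],
               median_occupied = stats::median(occ),
               median_well_populated = stats::median(wp),
               representative_k = fits[[i]]$partition$k)
  }))
  n <- length(fits)
  ari <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ari[i, j] <- ari[j, i] <- adjusted_rand(fits[[i]]$partition$labels,
                                            fits[[j]]$partition$labels)
  }
  structure(list(per_prior = per_prior, pairwise_ari = ari, fits = fits),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  print(x$per_prior, row.names = FALSE)
  cat("minimum pairwise ARI:", round(min(x$pairwise_ari), 3), "\n")
  invisible(x)
}
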