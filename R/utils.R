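#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same days.
#' Thin wrapper around [mclust::adjustedRandIndex()], exposed because
#' partition agreement is reported throughout sensitivity and recovery
#' analyses.
#'
#' @param a,b integer (or factor) label vectors of equal length.
#' @return A single number in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  mclust::adjustedRandIndex(a, b)
}

# Per-stage RNG streams derived from one user seed.  Offsets are fixed so a
# stage rerun in isolation reproduces its in-pipeline draws; kept small so the
# derived seed stays a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(exposures = 11L, confounders = 23L, outcome = 37L,
               missing = 53L, mcmc = 71L, predict = 89L, cv = 101L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer(seed) + offsets[[stage]]
}

# Validates a symmetric positive-definite matrix; returns its upper Cholesky
# factor or signals `msg`.
chol_pd <- function(x, msg = "matrix is not positive-definite") {
  ch <- tryCatch(chol(x), error = function(e) NULL)
  if (is.null(ch)) stop(msg, call. = FALSE)
  ch
}

is_count_vector <- function(y) {
  is.numeric(y) && all(is.finite(y)) && all(y >= 0) && all(y == round(y))
}
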