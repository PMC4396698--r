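#' Posterior similarity matrix
#'
#' `S[i, j]` is the fraction of stored sweeps in which days `i` and `j` were
#' allocated to the same cluster.  Computed by accumulating the co-clustering
#' indicator over sweeps (block products of the one-hot allocation matrices).
#'
#' @param chain a `profreg_chain`, or an allocation matrix (draws x T).
#' @param chunk number of sweeps per accumulation block.
#' @return `T x T` symmetric matrix with unit diagonal, class `psm`.
#' @export
similarity_matrix <- function(chain, chunk = 200L) {
  A <- if (inherits(chain, "profreg_chain")) chain$allocations else
    as.matrix(chain)
  if (!nrow(A)) stop("chain has no stored draws")
  Tn <- ncol(A)
  S <- matrix(0, Tn, Tn)
  for (start in seq(1L, nrow(A), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(A))
    Ks <- apply(A[rows, , drop = FALSE], 1, max)
    M <- matrix(0, Tn, sum(Ks))
    off <- 0L
    for (i in seq_along(rows)) {
      M[cbind(seq_len(Tn), off + A[rows[i], ])] <- 1
      off <- off + Ks[i]
    }
    S <- S + tcrossprod(M)
  }
  S <- S / nrow(A)
  diag(S) <- 1
  structure(S, class = c("psm", "matrix"))
}

#' Representative partition by partitioning around medoids
#'
#' Runs PAM on the dissimilarity `1 - S` for each candidate number of
#' clusters and keeps the partition with the largest average silhouette
#' width (ties go to the smallest `k`).  Cluster labels are relabelled in
#' decreasing size order; the medoid days are members of their clusters by
#' construction.
#'
#' @param S a [similarity_matrix()].
#' @param k_range candidate numbers of clusters, a subset of `2:(T-1)`.
#' @return object of class `rep_partition`: list with `labels`, `medoids`
#'   (day indices), `k`, `avg_silhouette` (per candidate `k`) and
#'   `silhouette_width` per day.
#' @export
representative_partition <- function(S, k_range = 2:6) {
  S <- unclass(S)
  Tn <- nrow(S)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= Tn))
    stop("k_range must lie within 2..(T-1)")
  d <- stats::as.dist(1 - S)
  fits <- lapply(k_range, function(k)
    cluster::pam(d, k = k, diss = TRUE, cluster.only = FALSE))
  avg_sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  best <- which.max(avg_sil)                  # first max: smallest k wins ties
  fit <- fits[[best]]
  labels <- fit$clustering
  medoids <- fit$id.med
  # relabel by decreasing size, keeping medoids attached
  ord <- order(tabulate(labels, k_range[best]), decreasing = TRUE)
  relab <- match(labels, ord)
  sil <- cluster::silhouette(relab, d)
  structure(list(
    labels = relab,
    medoids = medoids[ord],
    k = k_range[best],
    avg_silhouette = stats::setNames(avg_sil, k_range),
    silhouette_width = sil[, "sil_width"]
  ), class = "rep_partition")
}

#' @export
print.rep_partition <- function(x, ...) {
  cat("rep_partition:", x$k, "clusters of sizes",
      paste(tabulate(x$labels, x$k), collapse = "/"),
      sprintf("(avg silhouette %.3f)\n", max(x$avg_silhouette)))
  invisible(x)
}

#' Model-averaged cluster summaries
#'
#' For every stored sweep, each day carries the parameters of the cluster it
#' is allocated to in that sweep; averaging those day-level parameters over
#' the days of a representative cluster gives one draw of that cluster's
#' profile and relative risk.  Summaries across sweeps are posterior means
#' and central 95% credible intervals.  With stored normalisation constants
#' the exposure profiles are also reported in original units.
#'
#' @param chain a `profreg_chain`.
#' @param partition a [representative_partition()].
#' @param normalization optional [normalize_exposures()] object (medians and
#'   MADs used to back-transform profiles).
#' @return object of class `cluster_summary`: list with `relative_risk`
#'   (data frame: cluster, size, mean, lower, upper), `profiles` (long data
#'   frame per cluster and metric, normalised and original scale) and the
#'   per-sweep draw matrices.
#' @export
cluster_summaries <- function(chain, partition, normalization = NULL) {
  stopifnot(inherits(chain, "profreg_chain"),
            inherits(partition, "rep_partition"))
  Tn <- ncol(chain$allocations)
  if (length(partition$labels) != Tn)
    stop("partition and chain cover different numbers of days")
  C <- partition$k
  sizes <- tabulate(partition$labels, C)
  if (any(sizes == 0)) stop("empty representative cluster")
  P <- ncol(chain$states[[1]]$m)
  ndraw <- chain$n_draws
  rr_draws <- matrix(NA_real_, ndraw, C)
  prof_draws <- array(NA_real_, c(ndraw, C, P))
  group <- factor(partition$labels, levels = seq_len(C))
  for (s in seq_len(ndraw)) {
    stt <- chain$states[[s]]
    rr_day <- exp(stt$mu[stt$g])
    m_day <- stt$m[stt$g, , drop = FALSE]
    rr_draws[s, ] <- tapply(rr_day, group, mean)
    prof_draws[s, , ] <- rowsum(m_day, group) / sizes
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  rr <- data.frame(cluster = seq_len(C), size = sizes,
                   mean = colMeans(rr_draws),
                   lower = apply(rr_draws, 2, function(x) qs(x)[1]),
                   upper = apply(rr_draws, 2, function(x) qs(x)[2]))
  prof <- do.call(rbind, lapply(seq_len(C), function(c) {
    M <- prof_draws[, c, , drop = FALSE]
    dim(M) <- c(ndraw, P)
    data.frame(cluster = c, metric = seq_len(P),
               mean = colMeans(M),
               lower = apply(M, 2, function(x) qs(x)[1]),
               upper = apply(M, 2, function(x) qs(x)[2]))
  }))
  if (!is.null(normalization)) {
    md <- normalization$medians[prof$metric]
    sc <- normalization$mads[prof$metric]
    prof$mean_orig <- prof$mean * sc + md
    prof$lower_orig <- prof$lower * sc + md
    prof$upper_orig <- prof$upper * sc + md
  }
  structure(list(relative_risk = rr, profiles = prof,
                 rr_draws = rr_draws, profile_draws = prof_draws),
            class = "cluster_summary")
}

#' Per-day membership probabilities for the representative clusters
#'
#' Row `t` gives the fraction of sweeps in which day `t` was co-clustered
#' with each representative cluster's medoid, normalised to sum to 1 (two
#' medoids can occasionally share a sweep-cluster).
#'
#' @param chain a `profreg_chain`.
#' @param partition a [representative_partition()].
#' @return `T x k` probability matrix with rows summing to 1.
#' @export
membership_probabilities <- function(chain, partition) {
  A <- chain$allocations
  med <- partition$medoids
  Pm <- vapply(med, function(d) colMeans(A == A[, d]), numeric(ncol(A)))
  rs <- rowSums(Pm)
  rs[rs == 0] <- 1
  Pm / rs
}

#' Effective sample size of a scalar trace
#'
#' Wraps [coda::effectiveSize()]; a zero-variance trace is reported as ESS 0
#' with a `constant` flag rather than an error.
#'
#' @param x numeric vector.
#' @return list with `ess` and `constant`.
#' @export
effective_size <- function(x) {
  if (stats::var(x) == 0) return(list(ess = 0, constant = TRUE))
  list(ess = unname(coda::effectiveSize(coda::mcmc(x))), constant = FALSE)
}

#' Convergence diagnostics for the global parameters
#'
#' Per-sweep traces of the DP concentration, the day-effect standard
#' deviation, the number of occupied clusters and the data log-likelihood,
#' with lag-1 autocorrelation and effective sample sizes (post burn-in).
#'
#' @param chain a `profreg_chain`.
#' @return list with `summary` (data frame) and the post-burn-in `traces`.
#' @export
chain_diagnostics <- function(chain) {
  tr <- chain$traces[chain$traces$iter > chain$config$burn_in, ]
  vars <- c("alpha", "sigma_eps", "n_occupied", "data_loglik")
  rows <- lapply(vars, function(v) {
    x <- tr[[v]]
    es <- effective_size(x)
    ac1 <- if (es$constant) NA_real_ else
      stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
    data.frame(parameter = v, mean = mean(x), sd = stats::sd(x),
               lag1_acf = ac1, ess = es$ess, constant = es$constant)
  })
  list(summary = do.call(rbind, rows), traces = tr)
}
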