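#' Two-group hierarchical clustering of samples
#'
#' Agglomerative hierarchical clustering of the samples (columns) of a
#' standardised expression dataset, cut into exactly two clusters. The
#' distance between two samples is one minus the Pearson correlation of
#' their expression profiles, the convention of the co-expression clustering
#' ecosystem this mirrors.
#'
#' @param ds An [expression_dataset()], log2-transformed and per-gene
#'   z-scored (see [log2_z_transform()]), with at least 4 samples.
#' @param linkage `"average"` or `"complete"`.
#' @return Named integer vector of cluster labels (1/2) per sample id.
#' @export
cluster_samples <- function(ds, linkage = c("average", "complete")) {
  stopifnot(inherits(ds, "expression_dataset"))
  linkage <- match.arg(linkage)
  if (ncol(ds$values) < 4) stop("need at least 4 samples to cluster")
  d <- stats::as.dist(1 - stats::cor(ds$values))
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = 2)
  stats::setNames(as.integer(labels), ds$samples$sample_id)
}

#' Estimate the developmental demarcation interval from cluster labels
#'
#' Samples are ordered by age and every age cut (a boundary between two
#' distinct adjacent ages) is scored by how many samples disagree with a
#' perfect early/late split at that cut; replicates of one age are never
#' separated, so a cluster split within an age counts as disagreement. The
#' cut minimising disagreement defines the demarcation interval: the last age
#' on its early side and the first age on its late side. Ties are resolved
#' toward the earliest cut (the conservative, earliest-plausible transition).
#' Purity is `1 - disagreements / n`; alternating labels give purity near
#' 0.5 and are flagged unreliable.
#'
#' @param labels Two-cluster labels as returned by [cluster_samples()].
#' @param samples Sample metadata data frame (`sample_id`, `age_pcd`, ...).
#' @return A list of class `demarcation_result` with `labels`,
#'   `demarcation_interval` (last early age, first late age), `purity`, and
#'   `reliable` (purity >= 0.75).
#' @export
estimate_demarcation <- function(labels, samples) {
  if (length(unique(labels)) != 2)
    stop("degenerate labelling: need exactly two clusters")
  idx <- match(samples$sample_id, names(labels))
  if (anyNA(idx)) stop("labels and samples do not match")
  lab <- labels[idx]
  o <- order(samples$age_pcd)
  lab <- lab[o]
  age <- samples$age_pcd[o]
  n <- length(lab)
  cuts <- which(diff(age) > 0)
  if (length(cuts) == 0) stop("all samples share one age; no cut exists")
  disagreement <- vapply(cuts, function(k) {
    side <- c(rep(1L, k), rep(2L, n - k))
    min(sum(side != lab), sum(3L - side != lab))
  }, integer(1))
  best <- cuts[which.min(disagreement)]  # which.min takes the earliest tie
  structure(list(
    labels = labels,
    demarcation_interval = c(last_early_age_pcd = age[best],
                             first_late_age_pcd = age[best + 1L]),
    purity = 1 - min(disagreement) / n,
    reliable = (1 - min(disagreement) / n) >= 0.75),
    class = "demarcation_result")
}

#' Detect the demarcation point of a developmental expression series
#'
#' Runs [cluster_samples()] with both average and complete linkage on a
#' standardised dataset, estimates the demarcation interval for each, and
#' reports whether the two linkage methods agree (the robustness check used
#' when calling a two-stage structure).
#'
#' @param ds A standardised [expression_dataset()] (see [log2_z_transform()]).
#' @param linkages Linkage methods to run (default both).
#' @return A list of class `demarcation_result` combining the per-linkage
#'   results, with `demarcation_interval` taken from the first linkage,
#'   `consistent` indicating interval agreement across linkages, and
#'   `per_linkage` holding the individual results.
#' @export
demarcate <- function(ds, linkages = c("average", "complete")) {
  per <- lapply(linkages, function(lk)
    estimate_demarcation(cluster_samples(ds, lk), ds$samples))
  names(per) <- linkages
  intervals <- vapply(per, function(r) r$demarcation_interval, numeric(2))
  out <- per[[1L]]
  out$linkage <- linkages[1L]
  out$consistent <- all(apply(intervals, 1, function(v) length(unique(v)) == 1))
  out$per_linkage <- per
  out
}

#' @export
print.demarcation_result <- function(x, ...) {
  iv <- x$demarcation_interval
  cat("demarcation_result: interval ", iv[1], "-", iv[2], " PCD (",
      round(iv[1] / 7, 1), "-", round(iv[2] / 7, 1), " PCW)\n", sep = "")
  cat("  purity ", round(x$purity, 3),
      if (!is.null(x$consistent))
        paste0("; linkage methods agree: ", x$consistent),
      "\n", sep = "")
  if (!x$reliable) cat("  WARNING: low purity; two-stage structure unreliable\n")
  invisible(x)
}
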