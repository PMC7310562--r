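#' Sliding sample windows over a developmental series
#'
#' Overlapping windows of `width` consecutive samples (sorted by age), moved
#' by `step` samples, covering the whole series; the final window is added
#' even if the step pattern would skip past it. Each window's centre age is
#' the median age of its samples.
#'
#' @param samples Sample metadata data frame, sorted by `age_pcd`.
#' @param width Window width in samples (>= 3).
#' @param step Step between window starts (>= 1).
#' @return A list of windows, each a list with `index` (sample indices) and
#'   `center_age_pcd`.
#' @export
sliding_windows <- function(samples, width = 4, step = 1) {
  ages <- samples$age_pcd
  if (is.unsorted(ages)) stop("samples must be sorted by age")
  n <- length(ages)
  if (width > n) stop("window width exceeds the number of samples")
  if (width < 3) stop("window width must be at least 3")
  if (step < 1) stop("step must be at least 1")
  starts <- seq(1L, n - width + 1L, by = step)
  if (starts[length(starts)] != n - width + 1L)
    starts <- c(starts, n - width + 1L)
  lapply(seq_along(starts), function(w) {
    idx <- starts[w] + seq_len(width) - 1L
    list(window_index = w, index = idx,
         center_age_pcd = stats::median(ages[idx]))
  })
}

#' Candidate dominant gene groups within a window
#'
#' Genes are clustered on the distance one minus the absolute Pearson
#' correlation computed across the window's samples; the dendrogram (average
#' linkage) is cut at height `1 - corr_cut` and clusters with at least
#' `min_size` members are returned as candidate dominant groups.
#'
#' @param window_expr Gene-by-sample submatrix for one window.
#' @param min_size Minimum group size (default 5).
#' @param corr_cut Absolute-correlation threshold defining the cut height
#'   (default 0.75).
#' @return A list of character vectors of gene ids (possibly empty).
#' @export
candidate_groups <- function(window_expr, min_size = 5, corr_cut = 0.75) {
  v <- row_vars(window_expr)
  keep <- which(v > 1e-12)
  if (length(keep) < min_size) return(list())
  x <- window_expr[keep, , drop = FALSE]
  d <- stats::as.dist(1 - abs(stats::cor(t(x))))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = 1 - corr_cut)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_size])
  lapply(big, function(k) rownames(x)[cl == k])
}

#' Composite index of a candidate DNB group in one window
#'
#' The dynamic network biomarker composite index
#' `CI = SD_d * PCC_d / PCC_o`, where `SD_d` is the mean within-window
#' standard deviation of the group's genes, `PCC_d` the mean absolute
#' Pearson correlation over all within-group gene pairs, and `PCC_o` the
#' mean absolute correlation between group and non-group genes. A rising
#' `SD_d` and `PCC_d` with falling `PCC_o` - hence a sharply peaking CI - is
#' the signature of an imminent critical transition.
#'
#' @param window_expr Gene-by-sample submatrix for one window (genes must
#'   include the group and at least one non-group gene).
#' @param group Character vector of group gene ids (>= 2).
#' @return A list of class `dnb_window_score` with `member_genes`, `SD_d`,
#'   `PCC_d`, `PCC_o` and `CI`. When `PCC_o` is exactly zero the CI is
#'   reported as `Inf` with a flag rather than NaN.
#' @export
composite_index <- function(window_expr, group) {
  group <- intersect(rownames(window_expr), group)
  if (length(group) < 2) stop("group must contain at least 2 genes")
  others <- setdiff(rownames(window_expr), group)
  if (length(others) == 0) stop("need at least one non-group gene")
  gx <- window_expr[group, , drop = FALSE]
  ox <- window_expr[others, , drop = FALSE]

  sds <- row_sds(gx)
  const <- sds < 1e-12
  if (any(const)) {
    warning("constant gene(s) inside group excluded from correlation terms")
    if (sum(!const) < 2) stop("fewer than 2 non-constant genes in group")
  }
  SD_d <- mean(sds)

  gc <- abs(stats::cor(t(gx[!const, , drop = FALSE])))
  PCC_d <- mean(gc[upper.tri(gc)])

  ov <- row_vars(ox) > 1e-12
  oc <- abs(stats::cor(t(gx[!const, , drop = FALSE]),
                       t(ox[ov, , drop = FALSE])))
  PCC_o <- mean(oc)

  CI <- if (PCC_o <= 0 || !is.finite(PCC_o) || length(oc) == 0) Inf
        else SD_d * PCC_d / PCC_o
  structure(list(member_genes = group, SD_d = SD_d, PCC_d = PCC_d,
                 PCC_o = PCC_o, CI = CI,
                 pcc_o_zero = !is.finite(CI)),
            class = "dnb_window_score")
}

#' Detect a critical transition with the sliding-window DNB composite index
#'
#' For every sliding window the candidate dominant groups are scored with
#' [composite_index()] and the maximum-CI group kept as that window's
#' dominant group; the window with the overall maximum CI marks the
#' transition, its centre age is the transition age and its dominant group
#' the DNB membership. A transition is only called when the peak CI exceeds
#' `peak_factor` times the median window CI, the guard against reading a
#' flat CI profile as a transition.
#'
#' @param ds An [expression_dataset()], z-scored per gene across all samples
#'   (global standardisation, so within-window SD reflects local
#'   fluctuation).
#' @param width,step Sliding-window geometry (see [sliding_windows()]).
#' @param min_size,corr_cut Dominant-group search parameters (see
#'   [candidate_groups()]).
#' @param peak_factor Peak CI must exceed this multiple of the median window
#'   CI to call a transition (default 2).
#' @return A list of class `dnb_result`: `window_scores` (one
#'   `dnb_window_score` per window, with window index and centre age),
#'   `peak_window`, `transition_age_pcd`, `dnb_genes`, and
#'   `transition_called`.
#' @export
detect_transition <- function(ds, width = 4, step = 1, min_size = 5,
                              corr_cut = 0.75, peak_factor = 2) {
  stopifnot(inherits(ds, "expression_dataset"))
  o <- order(ds$samples$age_pcd)
  ds <- ds[, o]
  windows <- sliding_windows(ds$samples, width, step)
  scores <- lapply(windows, function(w) {
    x <- ds$values[, w$index, drop = FALSE]
    groups <- candidate_groups(x, min_size, corr_cut)
    best <- NULL
    for (g in groups) {
      sc <- composite_index(x, g)
      if (is.null(best) || sc$CI > best$CI) best <- sc
    }
    if (is.null(best))
      best <- structure(list(member_genes = character(), SD_d = 0,
                             PCC_d = 0, PCC_o = 0, CI = 0,
                             pcc_o_zero = FALSE),
                        class = "dnb_window_score")
    best$window_index <- w$window_index
    best$center_age_pcd <- w$center_age_pcd
    best
  })
  ci <- vapply(scores, `[[`, numeric(1), "CI")
  if (all(ci == 0)) {
    return(structure(list(window_scores = scores, peak_window = NA_integer_,
                          transition_age_pcd = NA_real_,
                          dnb_genes = character(),
                          transition_called = FALSE),
                     class = "dnb_result"))
  }
  peak <- which.max(ci)
  called <- ci[peak] >= peak_factor * stats::median(ci)
  structure(list(window_scores = scores,
                 peak_window = peak,
                 transition_age_pcd = scores[[peak]]$center_age_pcd,
                 dnb_genes = scores[[peak]]$member_genes,
                 transition_called = called),
            class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  if (is.na(x$peak_window)) {
    cat("dnb_result: no scorable window (no transition)\n")
    return(invisible(x))
  }
  cat("dnb_result: peak CI ", round(x$window_scores[[x$peak_window]]$CI, 3),
      " at window ", x$peak_window, " (centre ",
      round(x$transition_age_pcd, 1), " PCD, ",
      round(x$transition_age_pcd / 7, 1), " PCW)\n", sep = "")
  cat("  ", length(x$dnb_genes), " DNB member genes; transition called: ",
      x$transition_called, "\n", sep = "")
  invisible(x)
}

#' Plot the CI profile of a DNB analysis
#'
#' Composite index against window centre age (log2 x-axis), the standard
#' read-out for locating a critical transition phase.
#'
#' @param x A `dnb_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dnb_result <- function(x, ...) {
  ages <- vapply(x$window_scores, `[[`, numeric(1), "center_age_pcd")
  ci <- vapply(x$window_scores, `[[`, numeric(1), "CI")
  graphics::plot(ages, ci, type = "b", log = "x", xlab = "window centre age (PCD)",
                 ylab = "composite index (CI)", ...)
  if (!is.na(x$peak_window))
    graphics::abline(v = x$transition_age_pcd, lty = 2)
  invisible(x)
}
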