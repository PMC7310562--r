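#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: the
#' standard step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Early-versus-late differential expression
#'
#' Per-gene Welch's unequal-variance t-test on log2-scale expression between
#' the two stages, Benjamini-Hochberg adjustment over all tested genes, and
#' the joint FDR / fold-change decision rule: a gene is differential only
#' when `fdr < fdr_cut` **and** its linear fold change exceeds `fc_cut`.
#' `log2fc` is the late minus early mean difference, so `direction` is
#' `"up_late"` for positive significant changes and `"up_early"` for
#' negative ones.
#'
#' @param early,late [expression_dataset()]s on log2 scale with identical
#'   gene lists and at least 2 samples each.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fc_cut Linear fold-change threshold (default 1.5).
#' @return A data frame of class `deg_result` with per-gene `log2fc`,
#'   `fold_change` (direction-signed linear FC), `pvalue`, `fdr` and
#'   `direction`; thresholds kept as attributes.
#' @export
differential_expression <- function(early, late, fdr_cut = 0.05, fc_cut = 1.5) {
  stopifnot(inherits(early, "expression_dataset"),
            inherits(late, "expression_dataset"))
  if (!identical(early$gene_ids, late$gene_ids))
    stop("early and late datasets must share the same gene list")
  if (early$scale != "log2" || late$scale != "log2")
    stop("differential expression expects log2-scale values")
  x <- early$values
  y <- late$values
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per stage")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pvalue <- 2 * stats::pt(-abs(tstat), df)
  pvalue[se2 == 0] <- 1  # identical constant groups
  fdr <- bh_adjust(pvalue)
  log2fc <- m2 - m1
  fold_change <- sign(log2fc) * 2^abs(log2fc)
  signif <- fdr < fdr_cut & 2^abs(log2fc) > fc_cut
  direction <- ifelse(!signif, "ns", ifelse(log2fc > 0, "up_late", "up_early"))
  out <- data.frame(gene = early$gene_ids, log2fc = log2fc,
                    fold_change = fold_change, pvalue = pvalue, fdr = fdr,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "fc_cut") <- fc_cut
  class(out) <- c("deg_result", "data.frame")
  out
}

#' @export
print.deg_result <- function(x, ...) {
  cat("deg_result: ", nrow(x), " genes tested; ",
      sum(x$direction == "up_late"), " up in late, ",
      sum(x$direction == "up_early"), " up in early (FDR < ",
      attr(x, "fdr_cut"), ", FC > ", attr(x, "fc_cut"), ")\n", sep = "")
  invisible(as.data.frame(x))
}

#' Derive cell-type marker gene sets from a cell-type mean table
#'
#' A gene is a marker of a cell type when its mean expression there is at
#' least `fold` times its maximum mean in every other type. Genes expressed
#' in exactly one type (all other means zero) are markers of that type; a
#' small epsilon guards the ratio.
#'
#' @param means Cell-type-by-gene matrix of mean expression (linear scale,
#'   nonnegative), row names = cell types.
#' @param fold Fold threshold (default 5).
#' @return A [gene_set_collection()] with one (possibly empty set dropped)
#'   marker set per cell type; the universe is all genes of the table.
#' @export
select_markers <- function(means, fold = 5) {
  means <- as.matrix(means)
  if (nrow(means) < 2) stop("need at least 2 cell types")
  if (any(means < 0)) stop("cell-type means must be nonnegative")
  genes <- colnames(means)
  top <- apply(means, 2, which.max)
  markers <- lapply(seq_len(nrow(means)), function(ct) {
    own <- means[ct, ]
    other_max <- apply(means[-ct, , drop = FALSE], 2, max)
    is_marker <- own > 0 & own >= fold * pmax(other_max, 1e-9) |
      (own > 0 & other_max <= 1e-9)
    genes[is_marker]
  })
  names(markers) <- rownames(means)
  markers <- markers[vapply(markers, length, 1L) > 0]
  gene_set_collection(markers, universe = genes)
}

#' Fisher's exact over-representation test of a query gene list
#'
#' For each gene set, the one-sided (over-representation) Fisher's exact
#' p-value of the 2x2 table formed by query membership and set membership
#' within the universe, with Benjamini-Hochberg adjustment across sets. The
#' odds ratio gets a Haldane 0.5 correction when any table cell is zero.
#' Sets are intersected with the universe first; the query must be a subset
#' of the universe.
#'
#' @param query Character vector of query gene ids.
#' @param sets A [gene_set_collection()] or named list of gene id vectors.
#' @param universe Character vector: the gene universe. Defaults to the
#'   collection's universe.
#' @return A data frame of class `enrichment_result` with per-set counts
#'   (`overlap`, `query_size`, `set_size`, `universe_size`), `odds_ratio`,
#'   `pvalue` and `fdr`.
#' @export
fisher_enrichment <- function(query, sets, universe = NULL) {
  if (inherits(sets, "gene_set_collection")) {
    if (is.null(universe)) universe <- sets$universe
    sets <- sets$sets
  }
  if (is.null(universe) || length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  nq <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ns <- length(s)
    k <- length(intersect(query, s))
    p <- if (ns == 0) 1 else
      stats::phyper(k - 1, ns, N - ns, nq, lower.tail = FALSE)
    a <- k; b <- nq - k; c_ <- ns - k; d <- N - nq - ns + k
    h <- if (min(a, b, c_, d) == 0) 0.5 else 0
    data.frame(set = nm, overlap = k, query_size = nq, set_size = ns,
               universe_size = N,
               odds_ratio = ((a + h) * (d + h)) / ((b + h) * (c_ + h)),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result: ", nrow(x), " sets tested, ",
      sum(x$fdr < 0.05), " at FDR < 0.05\n", sep = "")
  invisible(as.data.frame(x))
}
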