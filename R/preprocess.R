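#' Keep genes expressed in a minimum fraction of samples
#'
#' A gene counts as expressed in a sample if its linear-scale value is
#' strictly positive. Genes expressed in at least `min_fraction` of the
#' samples are retained, in their original order. Filtering on detection in
#' 80% of samples is the standard guard against genes dominated by technical
#' zeros in developmental expression series.
#'
#' @param ds An [expression_dataset()] on linear scale.
#' @param min_fraction Minimum fraction of samples with value > 0
#'   (default 0.8).
#' @return The filtered `expression_dataset`. A warning (not an error) is
#'   raised when no gene survives.
#' @export
filter_expressed <- function(ds, min_fraction = 0.8) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale != "linear")
    stop("filter_expressed expects linear-scale values")
  frac <- rowMeans(ds$values > 0)
  keep <- frac >= min_fraction
  if (!any(keep)) warning("no gene passes the expression filter")
  ds[keep, ]
}

#' Log2-transform and per-gene z-score an expression matrix
#'
#' Values are transformed to `log2(x + pseudocount)` and every gene row is
#' standardised to mean 0 and variance 1. The z-score divides by the
#' population standard deviation (denominator n) by default; set
#' `sd_type = "sample"` for the n-1 convention. Constant rows cannot be
#' standardised: they become all-zero rows and are recorded in the
#' `constant_genes` attribute.
#'
#' @param ds An [expression_dataset()] on linear scale with values >= 0.
#' @param pseudocount Added before the log (default 1).
#' @param sd_type `"population"` (divide by n, default) or `"sample"` (n-1).
#' @param log Set to `FALSE` if `ds` is already on log2 scale and only the
#'   z-step should run.
#' @return An `expression_dataset` on `"log2"` scale whose non-constant rows
#'   have mean 0 and variance 1; attribute `constant_genes` lists flattened
#'   rows.
#' @export
log2_z_transform <- function(ds, pseudocount = 1,
                             sd_type = c("population", "sample"),
                             log = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  sd_type <- match.arg(sd_type)
  x <- ds$values
  if (log) {
    if (ds$scale != "linear") stop("values are already on log2 scale")
    if (any(x < 0)) stop("negative input value")
    x <- log2(x + pseudocount)
  }
  n <- ncol(x)
  mu <- rowMeans(x)
  cx <- x - mu
  ss <- rowSums(cx^2)
  denom <- if (sd_type == "population") n else n - 1L
  s <- sqrt(ss / denom)
  constant <- s < 1e-12
  s[constant] <- 1
  z <- cx / s
  z[constant, ] <- 0
  out <- expression_dataset(z, ds$gene_ids, ds$samples, scale = "log2")
  attr(out, "constant_genes") <- ds$gene_ids[constant]
  out
}

#' Log2-transform an expression dataset without standardising
#'
#' @param ds An [expression_dataset()] on linear scale with values >= 0.
#' @param pseudocount Added before the log (default 1).
#' @return An `expression_dataset` on `"log2"` scale.
#' @export
log2_transform <- function(ds, pseudocount = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$scale != "linear") stop("values are already on log2 scale")
  if (any(ds$values < 0)) stop("negative input value")
  expression_dataset(log2(ds$values + pseudocount), ds$gene_ids, ds$samples,
                     scale = "log2")
}

#' Split a dataset into early and late stages at an age boundary
#'
#' Samples with `age_pcd <= boundary_pcd` form the early stage and the rest
#' the late stage; a sample sitting exactly on the boundary goes to the early
#' side, matching the convention that the demarcation age labels the last
#' early time point. The boundary must lie strictly inside the observed age
#' range so that both sides are non-empty.
#'
#' @param ds An [expression_dataset()].
#' @param boundary_pcd Age boundary in postconception days.
#' @return A list with elements `early` and `late`, both `expression_dataset`s
#'   whose `stage` metadata column is filled in.
#' @export
split_by_age <- function(ds, boundary_pcd) {
  stopifnot(inherits(ds, "expression_dataset"))
  ages <- ds$samples$age_pcd
  if (boundary_pcd < min(ages) || boundary_pcd >= max(ages))
    stop("boundary outside the observed age range")
  early_idx <- which(ages <= boundary_pcd)
  late_idx <- which(ages > boundary_pcd)
  if (length(early_idx) == 0 || length(late_idx) == 0)
    stop("age split leaves an empty side")
  early <- ds[, early_idx]
  late <- ds[, late_idx]
  early$samples$stage <- "early"
  late$samples$stage <- "late"
  list(early = early, late = late)
}

#' Residualise expression on sample covariates
#'
#' Per-gene linear regression on the given covariate columns of the sample
#' metadata; the returned dataset holds the residuals (plus the gene mean so
#' the scale flag stays meaningful). Used to remove, e.g., sex or region
#' effects before network construction. With no covariates the dataset is
#' returned unchanged.
#'
#' @param ds An [expression_dataset()].
#' @param covariates Character vector of column names in `ds$samples`.
#' @return An `expression_dataset` of residualised values.
#' @export
residualize_covariates <- function(ds, covariates = character()) {
  stopifnot(inherits(ds, "expression_dataset"))
  covariates <- intersect(covariates, names(ds$samples))
  if (length(covariates) == 0) return(ds)
  mm <- stats::model.matrix(
    stats::reformulate(covariates),
    data = ds$samples)
  fit <- stats::lm.fit(mm, t(ds$values))
  res <- t(fit$residuals) + rowMeans(ds$values)
  expression_dataset(res, ds$gene_ids, ds$samples, ds$scale)
}
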