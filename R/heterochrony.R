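#' Log2 age transform
#'
#' Developmental ages are analysed on the log2 scale, which makes the
#' relationship between age and expression approximately linear over
#' development.
#'
#' @param age_pcd Positive ages in postconception days, or a sample metadata
#'   data frame with an `age_pcd` column.
#' @return `log2(age_pcd)`.
#' @export
log2_age <- function(age_pcd) {
  if (is.data.frame(age_pcd)) age_pcd <- age_pcd$age_pcd
  if (any(age_pcd <= 0)) stop("nonpositive age")
  log2(age_pcd)
}

#' Test a gene for age-related expression change
#'
#' Polynomial regression of expression on log2 age for degrees 1 to 3; the
#' degree with the largest adjusted R-squared wins and the p-value is the
#' overall F-test of that model against the intercept-only model. When the
#' data carry fewer distinct ages than a cubic needs, the maximum degree is
#' degraded with a warning.
#'
#' @param expr Numeric expression vector.
#' @param log2ages Matching log2-transformed ages.
#' @param max_degree Highest polynomial degree considered (default 3).
#' @return A list with `pvalue`, `best_degree` and `adj_r2`.
#' @export
age_related_test <- function(expr, log2ages, max_degree = 3) {
  stopifnot(length(expr) == length(log2ages))
  k <- length(unique(log2ages))
  deg_max <- min(max_degree, k - 2L)
  if (deg_max < max_degree)
    warning("only ", k, " distinct ages; polynomial degree capped at ", deg_max)
  if (deg_max < 1) stop("too few distinct ages for any age trend")
  fits <- lapply(seq_len(deg_max), function(d)
    stats::lm(expr ~ stats::poly(log2ages, d, raw = TRUE)))
  adj <- vapply(fits, function(f) summary(f)$adj.r.squared, numeric(1))
  best <- which.max(adj)
  fstat <- summary(fits[[best]])$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  list(pvalue = unname(p), best_degree = best, adj_r2 = adj[best])
}

#' Test a gene for expression divergence between species
#'
#' Analysis of covariance: the full model with a species main effect and
#' species-by-age-polynomial interactions is compared with the reduced model
#' containing only the shared age polynomial, by partial F-test. A small
#' p-value indicates the two species' expression trajectories differ in
#' level and/or shape.
#'
#' @param expr_h,ages_h Human expression values and ages (PCD).
#' @param expr_m,ages_m Macaque expression values and ages (PCD).
#' @param degree Polynomial degree (typically the age-test `best_degree`).
#' @return The partial F-test p-value.
#' @export
species_divergence_test <- function(expr_h, ages_h, expr_m, ages_m, degree = 2) {
  if (length(expr_h) < degree + 2 || length(expr_m) < degree + 2)
    stop("each species needs at least degree + 2 samples")
  y <- c(expr_h, expr_m)
  t_age <- log2_age(c(ages_h, ages_m))
  species <- factor(rep(c("human", "macaque"), c(length(expr_h), length(expr_m))))
  reduced <- stats::lm(y ~ stats::poly(t_age, degree, raw = TRUE))
  full <- stats::lm(y ~ stats::poly(t_age, degree, raw = TRUE) * species)
  if (full$rank < length(stats::coef(full)) - sum(is.na(stats::coef(full))))
    stop("rank-deficient design")
  av <- stats::anova(reduced, full)
  av[["Pr(>F)"]][2L]
}

# registration coordinates, fitted curves and alignment machinery ----------

# Map each species' samples into the alignment coordinate and build the
# common evaluation grid. normalized: each species' observed log2-age span
# is affinely mapped to [0,1] (shifts reported in human log2-age units);
# log2age: the raw log2-age axis, grid on the overlap of the two ranges.
registration_frame <- function(ages_h, ages_m,
                               registration = c("normalized", "log2age"),
                               grid_points = 50) {
  registration <- match.arg(registration)
  lh <- log2_age(ages_h)
  lm_ <- log2_age(ages_m)
  if (registration == "normalized") {
    rh <- range(lh); rm_ <- range(lm_)
    list(t_h = (lh - rh[1]) / diff(rh),
         t_m = (lm_ - rm_[1]) / diff(rm_),
         grid = seq(0, 1, length.out = grid_points),
         disp_to_units = diff(rh),
         registration = registration)
  } else {
    lo <- max(min(lh), min(lm_)); hi <- min(max(lh), max(lm_))
    if (hi <= lo) stop("species age ranges do not overlap")
    list(t_h = lh, t_m = lm_,
         grid = seq(lo, hi, length.out = grid_points),
         disp_to_units = hi - lo,
         registration = registration)
  }
}

poly_design <- function(t, degree) outer(t, 0:degree, `^`)

# least-squares coefficient projector (X'X)^-1 X'
poly_projector <- function(t, degree) {
  X <- poly_design(t, degree)
  qr.solve(crossprod(X), t(X))
}

fit_curve <- function(expr, t, grid, degree) {
  coefs <- poly_projector(t, degree) %*% expr
  drop(poly_design(grid, degree) %*% coefs)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(NULL)
  (x - mean(x)) / s
}

#' Estimate the expression time shift between species by dynamic time warping
#'
#' Per-species polynomial trajectories are fitted on the alignment
#' coordinate, evaluated on a common grid, z-scored and aligned by dynamic
#' time warping (symmetric step pattern, both endpoints pinned). The shift is
#' a displacement statistic of the warping path - by default the mean signed
#' displacement of the human grid position relative to the matched macaque
#' position - converted to human log2-age units. Positive shifts mean the
#' human trajectory is delayed (neoteny); negative means advanced
#' (acceleration).
#'
#' @param expr_h,ages_h Human expression values and ages (PCD).
#' @param expr_m,ages_m Macaque expression values and ages (PCD).
#' @param degree Polynomial degree for the trajectory fits.
#' @param registration `"normalized"` (each species' log2-age span mapped to
#'   \[0,1\]; the default) or `"log2age"` (raw log2-age axis, overlap only).
#' @param statistic `"mean"` (default) or `"max"` signed path displacement.
#' @param grid_points Grid resolution (default 50).
#' @return A list of class `dtw_shift` with `shift_log2age`, the alignment
#'   path (`i`, `j`, `displacement`), the fitted `curve_h`/`curve_m`, and the
#'   registration settings. `shift_log2age` is `NA` when either fitted curve
#'   is flat (a time shift of a constant is undefined).
#' @export
dtw_shift <- function(expr_h, ages_h, expr_m, ages_m, degree = 3,
                      registration = c("normalized", "log2age"),
                      statistic = c("mean", "max"),
                      grid_points = 50) {
  statistic <- match.arg(statistic)
  fr <- registration_frame(ages_h, ages_m, registration, grid_points)
  ch <- zscore(fit_curve(expr_h, fr$t_h, fr$grid, degree))
  cm <- zscore(fit_curve(expr_m, fr$t_m, fr$grid, degree))
  if (is.null(ch) || is.null(cm)) {
    return(structure(list(shift_log2age = NA_real_, alignment = NULL,
                          statistic = statistic,
                          registration = fr$registration),
                     class = "dtw_shift"))
  }
  al <- .dtw_align_cpp(ch, cm)
  disp <- if (statistic == "mean") al$mean_displacement else al$max_displacement
  structure(list(shift_log2age = disp * fr$disp_to_units,
                 alignment = al, curve_h = ch, curve_m = cm,
                 grid = fr$grid, statistic = statistic,
                 registration = fr$registration),
            class = "dtw_shift")
}

#' @export
print.dtw_shift <- function(x, ...) {
  cat("dtw_shift: ", round(x$shift_log2age, 3), " log2-age units (",
      x$statistic, " displacement, ", x$registration, " registration)\n",
      sep = "")
  invisible(x)
}

#' Parametric-bootstrap significance of a DTW time shift
#'
#' The null hypothesis is a shared trajectory: one polynomial is fitted to
#' both species pooled on the alignment coordinate, and `n_sims` null gene
#' datasets are built by adding residuals resampled within species to the
#' pooled fitted values. The shift statistic is recomputed for each and the
#' p-value is the add-one-corrected fraction of null shifts at least as
#' large in magnitude as the observed one.
#'
#' @inheritParams dtw_shift
#' @param n_sims Number of bootstrap simulations (>= 100).
#' @return A list with `shift_log2age`, `pvalue` and `null_shifts`.
#' @export
shift_significance <- function(expr_h, ages_h, expr_m, ages_m, degree = 3,
                               n_sims = 1000,
                               registration = c("normalized", "log2age"),
                               statistic = c("mean", "max"),
                               grid_points = 50) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  statistic <- match.arg(statistic)
  obs <- dtw_shift(expr_h, ages_h, expr_m, ages_m, degree,
                   registration, statistic, grid_points)
  if (is.na(obs$shift_log2age))
    return(list(shift_log2age = NA_real_, pvalue = NA_real_,
                null_shifts = numeric(0)))
  fr <- registration_frame(ages_h, ages_m, registration, grid_points)
  nh <- length(expr_h); nm <- length(expr_m)
  pooled_t <- c(fr$t_h, fr$t_m)
  pooled_y <- c(expr_h, expr_m)
  Xp <- poly_design(pooled_t, degree)
  fitted_all <- drop(Xp %*% qr.solve(crossprod(Xp), crossprod(Xp, pooled_y)))
  resid_all <- pooled_y - fitted_all
  idx_h <- matrix(sample.int(nh, n_sims * nh, replace = TRUE), n_sims)
  idx_m <- matrix(sample.int(nm, n_sims * nm, replace = TRUE), n_sims)
  null_shifts <- .dtw_boot_cpp(
    idx_h, idx_m,
    fitted_all[seq_len(nh)], fitted_all[nh + seq_len(nm)],
    resid_all[seq_len(nh)], resid_all[nh + seq_len(nm)],
    poly_projector(fr$t_h, degree), poly_projector(fr$t_m, degree),
    poly_design(fr$grid, degree), poly_design(fr$grid, degree),
    fr$disp_to_units, statistic == "max")
  ok <- !is.na(null_shifts)
  pvalue <- (1 + sum(abs(null_shifts[ok]) >= abs(obs$shift_log2age))) /
    (sum(ok) + 1)
  list(shift_log2age = obs$shift_log2age, pvalue = pvalue,
       null_shifts = null_shifts)
}

#' Classify a time shift as acceleration, neoteny or neither
#'
#' Human neoteny is a significantly positive shift (human trajectory
#' delayed); human acceleration a significantly negative one; anything
#' non-significant (or undefined) is `"none"`.
#'
#' @param shift Estimated shift in log2-age units.
#' @param pvalue Shift significance.
#' @param p_cut Significance threshold (default 0.05).
#' @return `"acceleration"`, `"neoteny"` or `"none"`.
#' @export
classify_heterochrony <- function(shift, pvalue, p_cut = 0.05) {
  ifelse(is.na(shift) | is.na(pvalue) | pvalue >= p_cut | shift == 0, "none",
         ifelse(shift > 0, "neoteny", "acceleration"))
}

#' Screen genes for age-related, species-divergent expression
#'
#' Stage one of the heterochrony analysis: every gene is tested for (i)
#' significant expression change with age (polynomial regression on log2
#' age, pooled samples, degree by adjusted R-squared) and (ii) significant
#' expression divergence between the species (ANCOVA partial F-test at the
#' chosen degree). Both screens use nominal p < `p_cut` with no multiple-
#' testing correction, a deliberate fidelity choice of this screening
#' design.
#'
#' @param human,macaque [expression_dataset()]s (log2 scale) sharing a gene
#'   universe.
#' @param genes Optional subset of gene ids to screen.
#' @param p_cut Screen significance threshold (default 0.05).
#' @return Data frame with columns `gene`, `age_pvalue`, `best_degree`,
#'   `adj_r2`, `species_pvalue`, `passes`.
#' @export
heterochrony_screen <- function(human, macaque, genes = NULL, p_cut = 0.05) {
  stopifnot(inherits(human, "expression_dataset"),
            inherits(macaque, "expression_dataset"))
  genes <- if (is.null(genes)) intersect(human$gene_ids, macaque$gene_ids)
           else intersect(genes, intersect(human$gene_ids, macaque$gene_ids))
  ages_h <- human$samples$age_pcd
  ages_m <- macaque$samples$age_pcd
  pooled_l2 <- log2_age(c(ages_h, ages_m))
  res <- lapply(genes, function(g) {
    eh <- human$values[g, ]
    em <- macaque$values[g, ]
    at <- age_related_test(c(eh, em), pooled_l2)
    sp <- species_divergence_test(eh, ages_h, em, ages_m, at$best_degree)
    data.frame(gene = g, age_pvalue = at$pvalue, best_degree = at$best_degree,
               adj_r2 = at$adj_r2, species_pvalue = sp,
               passes = at$pvalue < p_cut && sp < p_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full heterochrony analysis of two species' expression datasets
#'
#' Runs the [heterochrony_screen()], then for every passing gene estimates
#' the DTW time shift and its bootstrap significance, and classifies the
#' gene as human-accelerated, human-neotenic or neither.
#'
#' @inheritParams heterochrony_screen
#' @param n_sims Bootstrap simulations per gene (default 1000).
#' @param registration,statistic,grid_points Passed to [dtw_shift()].
#' @return A data frame of class `heterochrony_result`: the screen columns
#'   plus `shift_log2age`, `shift_pvalue` and `class`.
#' @export
heterochrony_analysis <- function(human, macaque, genes = NULL, p_cut = 0.05,
                                  n_sims = 1000,
                                  registration = c("normalized", "log2age"),
                                  statistic = c("mean", "max"),
                                  grid_points = 50) {
  registration <- match.arg(registration)
  statistic <- match.arg(statistic)
  screen <- heterochrony_screen(human, macaque, genes, p_cut)
  screen$shift_log2age <- NA_real_
  screen$shift_pvalue <- NA_real_
  screen$class <- "none"
  ages_h <- human$samples$age_pcd
  ages_m <- macaque$samples$age_pcd
  for (k in which(screen$passes)) {
    g <- screen$gene[k]
    sig <- shift_significance(human$values[g, ], ages_h,
                              macaque$values[g, ], ages_m,
                              degree = screen$best_degree[k], n_sims = n_sims,
                              registration = registration,
                              statistic = statistic,
                              grid_points = grid_points)
    screen$shift_log2age[k] <- sig$shift_log2age
    screen$shift_pvalue[k] <- sig$pvalue
    screen$class[k] <- classify_heterochrony(sig$shift_log2age, sig$pvalue, p_cut)
  }
  class(screen) <- c("heterochrony_result", "data.frame")
  screen
}

#' @export
print.heterochrony_result <- function(x, ...) {
  cat("heterochrony_result: ", nrow(x), " genes screened, ",
      sum(x$passes), " passed\n", sep = "")
  cat("  neoteny: ", sum(x$class == "neoteny"), "; acceleration: ",
      sum(x$class == "acceleration"), "\n", sep = "")
  invisible(as.data.frame(x))
}
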