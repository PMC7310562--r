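#' Choose the soft-thresholding power by the scale-free topology criterion
#'
#' Unsigned adjacency `|cor|^power` is computed for each candidate power;
#' connectivity is binned and the model R-squared of the log-log regression
#' of frequency on mean connectivity (sign-corrected so that only a
#' decreasing degree distribution counts) is the scale-free fit index. The
#' smallest power reaching `target_r2` wins; if none does, the power with
#' the maximum fit is returned with a warning.
#'
#' @param expr Gene-by-sample matrix (>= 20 genes).
#' @param powers Candidate powers (default 1:20).
#' @param target_r2 Scale-free fit threshold (default 0.8).
#' @param n_bins Connectivity bins for the fit (default 10).
#' @return The chosen integer power, with attribute `fit_r2`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, target_r2 = 0.8, n_bins = 10) {
  if (nrow(expr) < 20) stop("need at least 20 genes")
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fits <- vapply(powers, function(p) {
    k <- rowSums(ac^p)
    if (stats::sd(k) < 1e-12) return(0)
    cut_k <- cut(k, n_bins, include.lowest = TRUE)
    freq <- tapply(k, cut_k, length) / length(k)
    kmean <- tapply(k, cut_k, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3) return(0)
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    r2 <- suppressWarnings(summary(fit)$r.squared)  # degenerate at high powers
    -sign(stats::coef(fit)[2L]) * r2
  }, numeric(1))
  hit <- which(fits >= target_r2)
  if (length(hit) > 0) {
    p <- powers[hit[1L]]
    r2 <- fits[hit[1L]]
  } else {
    warning("no power reaches the scale-free target R^2; using the best fit")
    p <- powers[which.max(fits)]
    r2 <- max(fits)
  }
  structure(as.integer(p), fit_r2 = unname(r2))
}

#' Topological overlap matrix
#'
#' Unsigned TOM of an adjacency matrix:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with a
#' unit diagonal. Topological overlap promotes gene pairs that share
#' neighbours, which stabilises module detection against single noisy
#' correlations.
#'
#' @param adjacency Square symmetric matrix with entries in \[0, 1\] and
#'   zero diagonal.
#' @return The TOM, symmetric with values in \[0, 1\] and diagonal 1.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be square and symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than `min_module_size` are
#' dissolved into module 0 (unassigned). Surviving modules are renumbered
#' by decreasing size.
#'
#' @param tom Topological overlap matrix (see [topological_overlap()]).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.99).
#' @return A list of class `module_set` with `assignment` (named integer
#'   vector, 0 = unassigned) and `modules` (list of gene id vectors).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  assignment <- integer(length(cl))
  modules <- list()
  for (ord in order(-sizes[as.character(keep)])) {
    k <- keep[ord]
    m <- length(modules) + 1L
    assignment[cl == k] <- m
    modules[[paste0("module", m)]] <- genes[cl == k]
  }
  names(assignment) <- genes
  structure(list(assignment = assignment, modules = modules,
                 min_module_size = min_module_size, cut_height = cut_height),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set: ", length(x$modules), " modules (min size ",
      x$min_module_size, "), ", sum(x$assignment == 0),
      " unassigned genes\n", sep = "")
  if (length(x$modules) > 0) {
    sz <- vapply(x$modules, length, 1L)
    cat("  sizes: ", paste(sz, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$module_mdc)) {
    for (nm in names(x$module_mdc))
      cat("  ", nm, ": MDC ", round(x$module_mdc[[nm]]$mdc_value, 3), " (",
          x$module_mdc[[nm]]$class, ")\n", sep = "")
  }
  invisible(x)
}

#' Modular differential connectivity between two stages
#'
#' Connectivity of a gene pair is its unsigned soft adjacency
#' `|cor|^power`, computed within each stage. The MDC value is the log2
#' ratio of the mean pairwise connectivity of the module in the early stage
#' over the late stage: positive values mean gain of connectivity (tighter
#' early co-regulation), negative loss. The log makes the stated sign rule
#' coherent for a ratio statistic.
#'
#' Because all pairwise correlations of a co-regulated module fluctuate
#' together, the MDC of an unchanged module is noisy even at moderate
#' sample sizes; a fixed threshold alone cannot separate gain/loss from
#' that noise. Classification therefore combines an effect-size gate
#' (`|MDC| > tau`) with a stage-label permutation test: samples are
#' reshuffled between the stages `n_perm` times and a module is only called
#' gain or loss when its |MDC| exceeds the permutation null at level
#' `alpha`.
#'
#' @param module_genes Character vector of module gene ids (>= 3).
#' @param early_expr,late_expr Gene-by-sample matrices for the two stages
#'   (>= 4 samples each) containing the module genes.
#' @param power Soft-threshold power (default 6).
#' @param tau Minimal-effect threshold on |MDC| (default 0.1).
#' @param n_subsample When the two stages have unequal sample counts, the
#'   larger stage's connectivity is averaged over this many random
#'   subsamples at the smaller count (default 5). Sampled correlations are
#'   biased away from zero, more so at smaller n, so comparing stages at
#'   unequal depth would mistake sampling noise for connectivity change;
#'   equalising the counts removes that bias.
#' @param n_perm Stage-label permutations for the significance gate
#'   (default 60).
#' @param alpha Significance level of the permutation gate (default 0.05).
#' @return A list with `mdc_value`, `pvalue` (permutation) and `class`
#'   (`"gain"`, `"loss"` or `"none"`); `mdc_value` is `Inf` (flagged) when
#'   the late-stage connectivity is zero.
#' @export
mdc <- function(module_genes, early_expr, late_expr, power = 6, tau = 0.1,
                n_subsample = 5, n_perm = 60, alpha = 0.05) {
  if (length(module_genes) < 3) stop("module must have at least 3 genes")
  if (ncol(early_expr) < 4 || ncol(late_expr) < 4)
    stop("need at least 4 samples per stage")
  ex <- early_expr[module_genes, , drop = FALSE]
  lx <- late_expr[module_genes, , drop = FALSE]
  conn1 <- function(expr) {
    a <- abs(stats::cor(t(expr)))^power
    mean(a[upper.tri(a)])
  }
  n_min <- min(ncol(ex), ncol(lx))
  conn <- function(expr) {
    if (ncol(expr) == n_min) return(conn1(expr))
    mean(vapply(seq_len(n_subsample), function(r)
      conn1(expr[, sample(ncol(expr), n_min), drop = FALSE]), numeric(1)))
  }
  ce <- conn(ex)
  cl <- conn(lx)
  if (cl <= 0)
    return(list(mdc_value = Inf, pvalue = NA_real_, class = "gain",
                late_zero = TRUE))
  v <- log2(ce / cl)

  pooled <- cbind(ex, lx)
  np <- ncol(pooled)
  null_v <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(np)
    log2(conn1(pooled[, idx[seq_len(n_min)], drop = FALSE]) /
         conn1(pooled[, idx[n_min + seq_len(n_min)], drop = FALSE]))
  }, numeric(1))
  pvalue <- (1 + sum(abs(null_v) >= abs(v))) / (n_perm + 1)
  cls <- if (pvalue < alpha && v > tau) "gain"
         else if (pvalue < alpha && v < -tau) "loss"
         else "none"
  list(mdc_value = v, pvalue = pvalue, class = cls)
}

#' Co-expression modules with modular differential connectivity
#'
#' End-to-end module analysis of an expression dataset: optional covariate
#' residualisation, soft-power selection and TOM module detection on the
#' early stage, then per-module MDC between the early and late stages.
#'
#' @param ds An [expression_dataset()] (log2 scale recommended).
#' @param boundary_pcd Age boundary separating early from late samples.
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @param power Soft power; `NULL` (default) picks it with
#'   [pick_soft_power()].
#' @param tau MDC classification threshold.
#' @param covariates Metadata columns to residualise out first.
#' @return A `module_set` with an additional `module_mdc` element and the
#'   `soft_power` used.
#' @export
coexpression_modules <- function(ds, boundary_pcd, min_module_size = 30,
                                 cut_height = 0.99, power = NULL, tau = 0.1,
                                 covariates = character()) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds <- residualize_covariates(ds, covariates)
  stages <- split_by_age(ds, boundary_pcd)
  early <- stages$early$values
  late <- stages$late$values
  if (is.null(power)) power <- pick_soft_power(early)
  adj <- abs(stats::cor(t(early)))^as.integer(power)
  diag(adj) <- 0
  tom <- topological_overlap(adj)
  ms <- detect_modules(tom, min_module_size, cut_height)
  ms$soft_power <- as.integer(power)
  ms$module_mdc <- lapply(ms$modules, function(genes)
    mdc(genes, early, late, power = as.integer(power), tau = tau))
  ms
}

#' Mutual-information network of a gene module
#'
#' Pairwise mutual information is estimated with the rank-based
#' Gaussian-copula closed form `MI = -0.5 * log(1 - rho^2)`, where `rho` is
#' the Pearson-equivalent of the Spearman correlation
#' (`2 * sin(pi/6 * rho_s)`), a stable estimator at the small sample sizes
#' of stage-wise expression data. Edges must exceed a permutation-derived
#' significance threshold (pooled null MI from column-permuted data), and
#' indirect edges are pruned by the data processing inequality: in every
#' fully connected triangle the weakest edge is removed when it is weaker
#' than `(1 - dpi_tolerance)` times both others.
#'
#' @param expr Gene-by-sample matrix (>= 3 genes, >= 8 samples).
#' @param dpi_tolerance DPI tolerance (default 0.15).
#' @param alpha Edge significance level against the permutation null
#'   (default 0.01).
#' @param n_perm Number of column permutations pooled for the null
#'   (default 5).
#' @param hops,sd_mult Hub definition forwarded to [key_drivers()].
#' @return A list of class `mi_network` with `nodes`, `edges` (data frame
#'   `from`, `to`, `mi`), `mi_threshold` and `hubs`.
#' @export
mi_network <- function(expr, dpi_tolerance = 0.15, alpha = 0.01, n_perm = 5,
                       hops = 2, sd_mult = 1) {
  ng <- nrow(expr)
  if (ng < 3) stop("need at least 3 genes")
  if (ncol(expr) < 8) stop("need at least 8 samples")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ng))
  mi_of <- function(x) {
    rho_s <- stats::cor(t(x), method = "spearman")
    rho <- 2 * sin(pi / 6 * rho_s)
    rho <- pmin(pmax(rho, -0.999999), 0.999999)
    mi <- -0.5 * log(1 - rho^2)
    diag(mi) <- 0
    mi
  }
  mi <- mi_of(expr)
  null_mi <- unlist(lapply(seq_len(n_perm), function(p) {
    perm <- t(apply(expr, 1, sample))
    m <- mi_of(perm)
    m[upper.tri(m)]
  }))
  threshold <- stats::quantile(null_mi, 1 - alpha, names = FALSE)
  keep <- mi > threshold
  diag(keep) <- FALSE

  # DPI: mark, then remove, the weakest edge of each significant triangle
  drop_edge <- matrix(FALSE, ng, ng)
  for (i in seq_len(ng - 2)) {
    for (j in (i + 1):(ng - 1)) {
      if (!keep[i, j]) next
      for (k in (j + 1):ng) {
        if (!keep[i, k] || !keep[j, k]) next
        w <- c(mi[i, j], mi[i, k], mi[j, k])
        weakest <- which.min(w)
        if (w[weakest] < (1 - dpi_tolerance) * min(w[-weakest])) {
          if (weakest == 1) drop_edge[i, j] <- TRUE
          else if (weakest == 2) drop_edge[i, k] <- TRUE
          else drop_edge[j, k] <- TRUE
        }
      }
    }
  }
  keep <- keep & !(drop_edge | t(drop_edge))
  ut <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  edges <- data.frame(from = genes[ut[, 1L]], to = genes[ut[, 2L]],
                      mi = mi[ut], stringsAsFactors = FALSE)
  net <- structure(list(nodes = genes, edges = edges,
                        mi_threshold = threshold,
                        dpi_tolerance = dpi_tolerance),
                   class = "mi_network")
  net$hubs <- key_drivers(net, hops = hops, sd_mult = sd_mult)
  net
}

#' @export
print.mi_network <- function(x, ...) {
  cat("mi_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (MI threshold ", round(x$mi_threshold, 4), ")\n", sep = "")
  cat("  hubs: ", if (length(x$hubs)) paste(x$hubs, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Key-driver (hub) genes of an interaction network
#'
#' For every gene the size of its neighbourhood within `hops` steps is
#' computed; hubs are the genes whose neighbourhood size exceeds the mean by
#' more than `sd_mult` standard deviations.
#'
#' @param net An `mi_network` (or list with `nodes` and an `edges` data
#'   frame).
#' @param hops Neighbourhood radius in steps (default 2).
#' @param sd_mult Hub threshold in standard deviations above the mean
#'   (default 1).
#' @return Character vector of hub gene ids (possibly empty), with the
#'   per-gene neighbourhood sizes as attribute `neighborhood_size`.
#' @export
key_drivers <- function(net, hops = 2, sd_mult = 1) {
  if (length(net$nodes) == 0) stop("empty network")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  nb <- igraph::ego_size(g, order = hops, mindist = 1)
  names(nb) <- net$nodes
  s <- stats::sd(nb)
  hubs <- if (!is.finite(s) || s < 1e-12) character()
          else net$nodes[nb > mean(nb) + sd_mult * s]
  attr(hubs, "neighborhood_size") <- nb
  hubs
}

#' Hubs specific to the early-stage network
#'
#' @param early_net,late_net `mi_network`s over the same gene universe.
#' @return Hub genes of the early network that are not hubs of the late
#'   network.
#' @export
early_specific_hubs <- function(early_net, late_net) {
  setdiff(early_net$hubs, late_net$hubs)
}
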