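#' Developmental age grids
#'
#' Sampling grids (postconception days, PCD) mirroring the ages at which the
#' two species' brain transcriptomes are typically sampled: densely through
#' the prenatal period, then sparser postnatal ages. Postnatal ages are
#' converted to PCD with birth at 280 PCD (human) or 165 PCD (macaque),
#' 30.44 days per month and 365.25 days per year.
#'
#' @return Numeric vector of ages in PCD, sorted.
#' @export
human_age_grid <- function() {
  early <- c(56, 72, 84, 91, 112, 120, 133, 147, 168, 175)
  late <- c(182,
            280 + c(4, 10) * 30.44,
            280 + c(1, 2, 3, 4, 8, 13, 15, 18, 21, 23, 30, 36, 37, 40) * 365.25)
  c(early, late)
}

#' @rdname human_age_grid
#' @export
macaque_age_grid <- function() {
  early <- c(50, 70, 80, 90, 119)
  late <- 165 + c(0, 3, 12, 48) * 30.44
  c(early, late)
}

#' Geometrically spaced ages
#'
#' Convenience for building age grids that are evenly spaced on the log2-age
#' scale, the natural scale for developmental time.
#'
#' @param from,to Range in PCD.
#' @param n Number of ages.
#' @return Numeric vector of `n` ages.
#' @export
geometric_ages <- function(from, to, n) 2^seq(log2(from), log2(to), length.out = n)

#' Configuration for the two-species developmental expression simulator
#'
#' Returns the full set of generator parameters, with defaults defining the
#' simulated study conditions used throughout the package's validation suite:
#' Table-2-like age grids for both species, a planted state transition with a
#' correlated high-variance DNB gene group, heterochronic (time-shifted)
#' genes, stage-dependent co-expression module blocks with an observed
#' regulator gene each, and cell-type marker structure.
#'
#' @param n_genes Total number of genes.
#' @param ages_human,ages_macaque Sampling ages (PCD) per species.
#' @param replicates_per_age Samples per age per species.
#' @param transition_age_human,transition_age_macaque Planted transition ages
#'   (PCD); must be (close to) a grid age.
#' @param n_switch Number of genes whose mean jumps by `switch_delta` after
#'   the transition (half up, half down).
#' @param switch_delta Log2-scale mean offset of switch genes.
#' @param n_dnb Size of the planted DNB group.
#' @param dnb_sd_inflation Noise-SD multiplier for DNB genes inside the
#'   transition window (ages within one grid step of the transition).
#' @param dnb_intra_corr Pairwise noise correlation of DNB genes inside the
#'   transition window.
#' @param n_neoteny,n_acceleration Numbers of genes whose human trajectory is
#'   delayed (neoteny) or advanced (acceleration) by `shift_log2age`.
#' @param shift_log2age Planted time shift, in human log2-age units.
#' @param het_amplitude Curve amplitude (SD over registered time) of the
#'   heterochronic genes' transient expression programs.
#' @param n_modules,module_size Co-expression module count and size(s);
#'   `module_size` is recycled over modules.
#' @param module_corr_early,module_corr_late Within-module pairwise
#'   correlations per stage; vectors recycled over modules. Defaults plant a
#'   connectivity-gain, a connectivity-loss and an unchanged module.
#' @param n_celltypes,markers_per_type,marker_fold Cell-type mean-expression
#'   table structure: each marker gene is `marker_fold` times higher in its
#'   own type than in any other.
#' @param traj_amplitude Scale (half-normal SD) of the per-gene developmental
#'   trajectory amplitudes of non-heterochronic genes.
#' @param noise_sd Residual SD on the log2 scale.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   expression.
#' @param seed Integer seed; generation is bit-reproducible given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 450,
                       ages_human = human_age_grid(),
                       ages_macaque = macaque_age_grid(),
                       replicates_per_age = 3,
                       transition_age_human = 175,
                       transition_age_macaque = 119,
                       n_switch = 150,
                       switch_delta = 1.0,
                       n_dnb = 30,
                       dnb_sd_inflation = 3,
                       dnb_intra_corr = 0.9,
                       n_neoteny = 15,
                       n_acceleration = 15,
                       shift_log2age = 1.0,
                       het_amplitude = 1.0,
                       n_modules = 3,
                       module_size = 50,
                       module_corr_early = c(0.7, 0.3, 0.5),
                       module_corr_late = c(0.3, 0.7, 0.5),
                       n_celltypes = 5,
                       markers_per_type = 10,
                       marker_fold = 8,
                       traj_amplitude = 0.3,
                       noise_sd = 0.5,
                       baseline_mean = 6,
                       baseline_sd = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  module_sizes <- rep(cfg$module_size, length.out = cfg$n_modules)
  cfg$module_sizes <- module_sizes
  n_module_genes <- sum(module_sizes) + cfg$n_modules  # + 1 regulator each
  n_planted <- cfg$n_switch + cfg$n_dnb + cfg$n_neoteny + cfg$n_acceleration +
    n_module_genes
  if (n_planted > cfg$n_genes)
    stop("planted roles need ", n_planted, " genes but n_genes is ", cfg$n_genes)
  if (cfg$n_genes - n_planted < cfg$n_celltypes * cfg$markers_per_type)
    stop("not enough background genes left for cell-type markers")
  if (any(cfg$dnb_intra_corr < 0 | cfg$dnb_intra_corr >= 1) ||
      any(cfg$module_corr_early < 0 | cfg$module_corr_early >= 1) ||
      any(cfg$module_corr_late < 0 | cfg$module_corr_late >= 1))
    stop("correlations must lie in [0, 1)")
  if (cfg$dnb_sd_inflation < 1) stop("dnb_sd_inflation must be >= 1")
  if (cfg$marker_fold < 1) stop("marker_fold must be >= 1")
  if (any(cfg$ages_human <= 0) || any(cfg$ages_macaque <= 0))
    stop("ages must be positive")
  structure(cfg, class = "sim_config")
}

#' Null configuration: all planted effects removed
#'
#' Returns a copy of `config` with the stage offset, time shifts, DNB noise
#' structure, module connectivity difference and the trajectory amplitudes
#' all zeroed, so that genes are exchangeable noise around constant
#' baselines. Used for type-I-error calibration of the downstream tests.
#'
#' @param config A [sim_config()].
#' @return A `sim_config` describing pure-noise data.
#' @export
null_sim_config <- function(config = sim_config()) {
  config$switch_delta <- 0
  config$shift_log2age <- 0
  config$het_amplitude <- 0
  config$dnb_sd_inflation <- 1
  config$dnb_intra_corr <- 0
  config$module_corr_late <- config$module_corr_early
  config$traj_amplitude <- 0
  config$null <- TRUE
  config
}

# registered developmental time: each species' sampled log2-age span mapped
# to [0, 1]; trajectories are shared functions of this coordinate.
registered_time <- function(age_pcd, grid) {
  r <- range(log2(grid))
  (log2(age_pcd) - r[1]) / (r[2] - r[1])
}

# ages (sorted unique grid) within +-1 grid step of the transition age
transition_window_ages <- function(grid, transition_age) {
  grid <- sort(unique(grid))
  i <- which.min(abs(grid - transition_age))
  grid[seq(max(1L, i - 1L), min(length(grid), i + 1L))]
}

#' Generate a two-species developmental expression dataset with ground truth
#'
#' Simulates gene-by-sample log2-scale expression for two species over their
#' age grids and returns linear-scale datasets plus the planted truth. The
#' generative model: every gene has a baseline plus a smooth trajectory in
#' registered developmental time (the species' log2-age span mapped to
#' \[0,1\]) and Gaussian noise on the log2 scale. Planted structure:
#' \describe{
#'   \item{switch genes}{mean offset after the species' transition age, half
#'     up and half down - the two-stage structure.}
#'   \item{DNB genes}{inside a window of one grid step around the transition,
#'     noise is equicorrelated with inflated SD; independent elsewhere.}
#'   \item{heterochronic genes}{transient bump-shaped programs; the human
#'     trajectory is evaluated at registered time shifted by
#'     `shift_log2age / span` (delayed for neoteny, advanced for
#'     acceleration).}
#'   \item{module genes}{flat baselines with stage-wise equicorrelated noise
#'     around a per-module latent factor; the factor itself is emitted as an
#'     observed regulator gene.}
#'   \item{markers}{a cell-type-by-gene mean table in which each marker gene
#'     is `marker_fold` times higher in its own type.}
#' }
#'
#' @param config A [sim_config()].
#' @return A list of class `devtraj_sim` with elements `human` and `macaque`
#'   (linear-scale [expression_dataset()]s), `truth` (planted ground truth)
#'   and `celltype_means` (cell-type x gene matrix, linear scale).
#' @export
simulate_devexpr <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  cfg <- config
  ng <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))

  # --- gene roles, in fixed blocks -----------------------------------------
  pos <- 0L
  take <- function(n) {
    idx <- pos + seq_len(n)
    pos <<- pos + n
    idx
  }
  idx_switch <- take(cfg$n_switch)
  idx_dnb <- take(cfg$n_dnb)
  idx_neo <- take(cfg$n_neoteny)
  idx_acc <- take(cfg$n_acceleration)
  idx_modules <- lapply(seq_len(cfg$n_modules), function(m)
    take(cfg$module_sizes[m]))
  idx_regulators <- if (cfg$n_modules > 0) take(cfg$n_modules) else integer()
  idx_background <- if (pos < ng) (pos + 1L):ng else integer()
  idx_module_all <- c(unlist(idx_modules), idx_regulators)

  # --- shared trajectory shapes on registered time -------------------------
  ref <- seq(0, 1, length.out = 101)
  refB <- cbind(ref, ref^2, ref^3)
  shape_coef <- matrix(stats::rnorm(3 * ng), nrow = 3)
  ref_curves <- refB %*% shape_coef
  shape_mu <- colMeans(ref_curves)
  shape_sd <- apply(ref_curves, 2, stats::sd)
  shape_sd[shape_sd < 1e-12] <- 1
  amplitude <- abs(stats::rnorm(ng, 0, cfg$traj_amplitude))
  amplitude[idx_module_all] <- 0
  baseline <- stats::rnorm(ng, cfg$baseline_mean, cfg$baseline_sd)

  het_idx <- c(idx_neo, idx_acc)
  bump_center <- stats::runif(ng, 0.3, 0.55)
  bump_width <- stats::runif(ng, 0.13, 0.2)
  bump_sign <- sample(c(-1, 1), ng, replace = TRUE)
  is_het <- seq_len(ng) %in% het_idx
  amplitude[het_idx] <- cfg$het_amplitude

  shifts <- numeric(ng)
  shifts[idx_neo] <- cfg$shift_log2age
  shifts[idx_acc] <- -cfg$shift_log2age
  switch_sign <- numeric(ng)
  if (cfg$n_switch > 0)
    switch_sign[idx_switch] <- rep(c(1, -1), length.out = cfg$n_switch)

  # trajectory of gene g at registered time u (vectorised over u)
  traj <- function(g, u) {
    if (is_het[g]) {
      raw <- exp(-(u - bump_center[g])^2 / (2 * bump_width[g]^2))
      ref_raw <- exp(-(ref - bump_center[g])^2 / (2 * bump_width[g]^2))
      sdv <- stats::sd(ref_raw)
      if (sdv < 1e-12) sdv <- 1
      bump_sign[g] * amplitude[g] * (raw - mean(ref_raw)) / sdv
    } else {
      raw <- cbind(u, u^2, u^3) %*% shape_coef[, g]
      amplitude[g] * (raw - shape_mu[g]) / shape_sd[g]
    }
  }

  simulate_species <- function(species) {
    grid <- if (species == "human") cfg$ages_human else cfg$ages_macaque
    t_age <- if (species == "human") cfg$transition_age_human else cfg$transition_age_macaque
    age <- rep(sort(grid), each = cfg$replicates_per_age)
    ns <- length(age)
    u <- registered_time(age, grid)
    span <- diff(range(log2(grid)))

    signal <- matrix(0, ng, ns)
    for (g in seq_len(ng)) {
      ug <- if (species == "human" && shifts[g] != 0) u - shifts[g] / span else u
      signal[g, ] <- baseline[g] + traj(g, ug)
    }
    late <- age > t_age
    if (any(switch_sign != 0))
      signal[, late] <- signal[, late] + switch_sign %o% rep(cfg$switch_delta, sum(late))

    noise <- matrix(stats::rnorm(ng * ns, 0, cfg$noise_sd), ng, ns)

    # DNB window: equicorrelated, inflated noise for the DNB group
    if (cfg$n_dnb > 0 && (cfg$dnb_sd_inflation > 1 || cfg$dnb_intra_corr > 0)) {
      win_ages <- transition_window_ages(grid, t_age)
      win <- which(age %in% win_ages)
      rho <- cfg$dnb_intra_corr
      shared <- stats::rnorm(length(win))
      eps <- matrix(stats::rnorm(cfg$n_dnb * length(win)), cfg$n_dnb)
      corr_noise <- sqrt(rho) * rep(shared, each = cfg$n_dnb) + sqrt(1 - rho) * eps
      noise[idx_dnb, win] <- cfg$dnb_sd_inflation * cfg$noise_sd *
        matrix(corr_noise, cfg$n_dnb)
    }

    # module blocks: stage-wise equicorrelated noise around a latent factor
    if (cfg$n_modules > 0) {
      r_early <- rep(cfg$module_corr_early, length.out = cfg$n_modules)
      r_late <- rep(cfg$module_corr_late, length.out = cfg$n_modules)
      for (m in seq_len(cfg$n_modules)) {
        factor_m <- stats::rnorm(ns)
        r <- ifelse(late, r_late[m], r_early[m])
        k <- cfg$module_sizes[m]
        eps <- matrix(stats::rnorm(k * ns), k)
        noise[idx_modules[[m]], ] <- cfg$noise_sd *
          (rep(sqrt(r) * factor_m, each = k) + rep(sqrt(1 - r), each = k) * eps)
        # the regulator tracks the module factor in the early stage only:
        # an early-development regulator that disengages after the transition
        reg_eps <- stats::rnorm(ns)
        reg <- (factor_m + 0.3 * reg_eps) / sqrt(1.09)
        reg[late] <- stats::rnorm(sum(late))
        noise[idx_regulators[m], ] <- cfg$noise_sd * reg
      }
    }

    meta <- data.frame(
      sample_id = sprintf("%s_s%03d", substr(species, 1, 1), seq_len(ns)),
      species = species,
      region = "V1C",
      age_pcd = age,
      stage = ifelse(late, "late", "early"),
      stringsAsFactors = FALSE)
    expression_dataset(2^(signal + noise), gene_ids, meta, scale = "linear")
  }

  human <- simulate_species("human")
  macaque <- simulate_species("macaque")

  # --- cell-type mean table ------------------------------------------------
  means <- matrix(stats::runif(cfg$n_celltypes * ng, 0.5, 2),
                  nrow = cfg$n_celltypes, ncol = ng)
  dimnames(means) <- list(if (cfg$n_celltypes > 0)
    paste0("celltype", seq_len(cfg$n_celltypes)) else NULL, gene_ids)
  markers <- list()
  if (cfg$n_celltypes > 0 && cfg$markers_per_type > 0) {
    marker_pool <- idx_background[seq_len(cfg$n_celltypes * cfg$markers_per_type)]
    for (ct in seq_len(cfg$n_celltypes)) {
      mg <- marker_pool[(ct - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)]
      for (g in mg) means[ct, g] <- cfg$marker_fold * max(means[-ct, g])
      markers[[rownames(means)[ct]]] <- gene_ids[mg]
    }
  }

  is_null <- isTRUE(cfg$null)
  module_classes <- ifelse(
    rep(cfg$module_corr_early, length.out = cfg$n_modules) >
      rep(cfg$module_corr_late, length.out = cfg$n_modules), "gain",
    ifelse(rep(cfg$module_corr_early, length.out = cfg$n_modules) <
             rep(cfg$module_corr_late, length.out = cfg$n_modules), "loss", "none"))
  truth <- list(
    transition_age = list(human = cfg$transition_age_human,
                          macaque = cfg$transition_age_macaque),
    switch_genes = if (is_null) character() else gene_ids[idx_switch],
    dnb_genes = if (is_null) character() else gene_ids[idx_dnb],
    shifts = if (is_null) stats::setNames(numeric(0), character(0))
             else stats::setNames(shifts[het_idx], gene_ids[het_idx]),
    module_blocks = if (is_null) list() else stats::setNames(
      lapply(seq_len(cfg$n_modules), function(m)
        list(genes = gene_ids[idx_modules[[m]]], class = module_classes[m])),
      sprintf("module%d", seq_len(cfg$n_modules))),
    regulators = if (is_null) character() else
      stats::setNames(gene_ids[idx_regulators],
                      sprintf("module%d", seq_len(cfg$n_modules))),
    markers = if (is_null) list() else markers)

  structure(list(human = human, macaque = macaque, truth = truth,
                 celltype_means = means, config = cfg),
            class = "devtraj_sim")
}

#' Generate the matched null dataset
#'
#' Shorthand for `simulate_devexpr(null_sim_config(config))`: same layout and
#' sample structure, but all planted effects zeroed and empty truth lists.
#'
#' @param config A [sim_config()].
#' @return A `devtraj_sim` (see [simulate_devexpr()]).
#' @export
simulate_null <- function(config = sim_config()) {
  simulate_devexpr(null_sim_config(config))
}

#' @export
print.devtraj_sim <- function(x, ...) {
  cat("devtraj_sim (seed ", x$config$seed, ")\n", sep = "")
  cat("  human:   ", nrow(x$human$values), " genes x ", ncol(x$human$values),
      " samples\n", sep = "")
  cat("  macaque: ", nrow(x$macaque$values), " genes x ",
      ncol(x$macaque$values), " samples\n", sep = "")
  cat("  planted: ", length(x$truth$switch_genes), " switch, ",
      length(x$truth$dnb_genes), " DNB, ", length(x$truth$shifts),
      " heterochronic, ", length(x$truth$module_blocks), " modules\n", sep = "")
  invisible(x)
}
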