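#' Pipeline configuration
#'
#' Collects input paths, output directory, seed and every stage parameter
#' into one flat, auditable object. All thresholds of the analysis (the 0.8
#' expressed fraction, FDR 0.05, fold change 1.5, the p < 0.05 screens, the
#' 5-fold marker rule) appear here as named defaults.
#'
#' @param human_matrix,human_meta Paths to the human expression matrix and
#'   sample metadata TSVs (see [load_expression()]).
#' @param macaque_matrix,macaque_meta Optional macaque paths; heterochrony
#'   runs only when both species are present.
#' @param gene_sets Optional GMT path for enrichment.
#' @param celltype_means Optional TSV (cell types in rows, first column
#'   `celltype`, genes in columns) for marker derivation.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed governing every stochastic stage.
#' @param boundary_pcd Optional forced early/late boundary; by default the
#'   demarcation stage's estimate (its last early age) is used.
#' @param min_fraction,pseudocount Preprocessing parameters.
#' @param dnb_width,dnb_step,dnb_min_size,dnb_corr_cut,dnb_peak_factor DNB
#'   stage parameters (see [detect_transition()]).
#' @param fdr_cut,fc_cut Differential-expression decision rule.
#' @param marker_fold Cell-type marker fold rule (see [select_markers()]).
#' @param het_p_cut,het_sims,het_registration,het_statistic Heterochrony
#'   parameters (see [heterochrony_analysis()]).
#' @param min_module_size,cut_height,mdc_tau Network stage parameters.
#' @param covariates Metadata columns residualised out before networks.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(human_matrix, human_meta,
                            macaque_matrix = NULL, macaque_meta = NULL,
                            gene_sets = NULL, celltype_means = NULL,
                            out_dir = "devtraj_out", seed = 1,
                            boundary_pcd = NULL,
                            min_fraction = 0.8, pseudocount = 1,
                            dnb_width = 4, dnb_step = 1, dnb_min_size = 5,
                            dnb_corr_cut = 0.75, dnb_peak_factor = 2,
                            fdr_cut = 0.05, fc_cut = 1.5, marker_fold = 5,
                            het_p_cut = 0.05, het_sims = 200,
                            het_registration = "normalized",
                            het_statistic = "mean",
                            min_module_size = 30, cut_height = 0.99,
                            mdc_tau = 0.1, covariates = character()) {
  cfg <- as.list(environment())
  for (p in c("human_matrix", "human_meta"))
    if (!file.exists(cfg[[p]])) stop("input not found: ", cfg[[p]])
  for (p in c("macaque_matrix", "macaque_meta", "gene_sets", "celltype_means"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input not found: ", cfg[[p]])
  structure(cfg, class = "pipeline_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

strip_class <- function(x) {
  x <- unclass(x)
  lapply(x, function(e) if (is.list(e) && !is.data.frame(e)) strip_class(e) else e)
}

#' Run the full developmental trajectory pipeline
#'
#' Executes demarcation clustering, the age split (at the detected boundary
#' or a user-forced one), DNB transition detection, early/late differential
#' expression with enrichment and marker derivation, heterochrony (when
#' both species are supplied) and co-expression network analysis, writing
#' JSON/TSV outputs plus a reproducibility manifest (package version, seed,
#' parameters, input checksums) into the configured output directory. All
#' stochastic stages are governed by the config seed, so reruns of one
#' config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  set.seed(cfg$seed)
  results <- list()

  # --- load + preprocess ----------------------------------------------------
  human <- load_expression(cfg$human_matrix, cfg$human_meta)
  human <- filter_expressed(human, cfg$min_fraction)
  human_log2 <- log2_transform(human, cfg$pseudocount)
  human_z <- log2_z_transform(human, cfg$pseudocount)
  macaque <- NULL
  if (!is.null(cfg$macaque_matrix)) {
    macaque <- load_expression(cfg$macaque_matrix, cfg$macaque_meta)
    macaque <- filter_expressed(macaque, cfg$min_fraction)
  }

  # --- demarcation ----------------------------------------------------------
  dem <- demarcate(human_z)
  results$demarcation <- dem
  write_json_out(list(
    demarcation_interval = as.list(dem$demarcation_interval),
    purity = dem$purity, reliable = dem$reliable,
    consistent = dem$consistent,
    labels = as.list(dem$labels)), out("demarcation.json"))

  boundary <- if (!is.null(cfg$boundary_pcd)) cfg$boundary_pcd
              else unname(dem$demarcation_interval[1L])
  results$boundary_pcd <- boundary

  # --- DNB ------------------------------------------------------------------
  dnb <- detect_transition(human_z, width = cfg$dnb_width, step = cfg$dnb_step,
                           min_size = cfg$dnb_min_size,
                           corr_cut = cfg$dnb_corr_cut,
                           peak_factor = cfg$dnb_peak_factor)
  results$dnb <- dnb
  write_json_out(list(
    transition_age_pcd = dnb$transition_age_pcd,
    transition_called = dnb$transition_called,
    dnb_genes = dnb$dnb_genes,
    window_scores = lapply(dnb$window_scores, function(w)
      list(window_index = w$window_index, center_age_pcd = w$center_age_pcd,
           n_members = length(w$member_genes), SD_d = w$SD_d,
           PCC_d = w$PCC_d, PCC_o = w$PCC_o, CI = w$CI))),
    out("dnb.json"))

  # --- differential expression + enrichment ---------------------------------
  stages <- split_by_age(human_log2, boundary)
  degs <- differential_expression(stages$early, stages$late,
                                  cfg$fdr_cut, cfg$fc_cut)
  results$degs <- degs
  utils::write.table(degs, out("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sets <- NULL
  if (!is.null(cfg$gene_sets)) sets <- read_gmt(cfg$gene_sets)$sets
  if (!is.null(cfg$celltype_means)) {
    ctm <- utils::read.table(cfg$celltype_means, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    markers <- select_markers(as.matrix(ctm), fold = cfg$marker_fold)
    results$markers <- markers
    sets <- c(sets, stats::setNames(markers$sets,
                                    paste0("markers_", names(markers$sets))))
  }
  if (!is.null(sets)) {
    query <- degs$gene[degs$direction != "ns"]
    universe <- degs$gene
    if (length(query) > 0) {
      enr <- fisher_enrichment(query, sets, universe)
      results$enrichment <- enr
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # --- heterochrony ---------------------------------------------------------
  if (!is.null(macaque)) {
    het <- heterochrony_analysis(human_log2,
                                 log2_transform(macaque, cfg$pseudocount),
                                 p_cut = cfg$het_p_cut, n_sims = cfg$het_sims,
                                 registration = cfg$het_registration,
                                 statistic = cfg$het_statistic)
    results$heterochrony <- het
    utils::write.table(het, out("heterochrony.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- networks -------------------------------------------------------------
  modules <- coexpression_modules(human_log2, boundary,
                                  min_module_size = cfg$min_module_size,
                                  cut_height = cfg$cut_height,
                                  tau = cfg$mdc_tau,
                                  covariates = cfg$covariates)
  results$modules <- modules
  write_json_out(list(
    soft_power = modules$soft_power,
    assignment = as.list(modules$assignment),
    module_mdc = lapply(modules$module_mdc, function(m)
      list(mdc_value = m$mdc_value, class = m$class))), out("modules.json"))

  if (length(modules$modules) > 0) {
    stage_expr <- split_by_age(human_log2, boundary)
    m1 <- modules$modules[[1L]]
    early_net <- mi_network(stage_expr$early$values[m1, , drop = FALSE])
    late_net <- mi_network(stage_expr$late$values[m1, , drop = FALSE])
    results$early_net <- early_net
    results$late_net <- late_net
    results$early_specific_hubs <- early_specific_hubs(early_net, late_net)
    writeLines(early_net$hubs, out("hubs_module1.txt"))
    writeLines(results$early_specific_hubs, out("early_specific_hubs.txt"))
  }

  # --- manifest -------------------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   cfg[c("human_matrix", "human_meta", "macaque_matrix",
                         "macaque_meta", "gene_sets", "celltype_means")])
  params <- cfg[setdiff(names(cfg), c(names(inputs), "out_dir"))]
  manifest <- list(
    package = "devtraj",
    version = as.character(utils::packageVersion("devtraj")),
    seed = cfg$seed,
    boundary_pcd = boundary,
    parameters = params,
    input_checksums = as.list(tools::md5sum(unlist(inputs))))
  write_json_out(manifest, out("manifest.json"))
  results$out_dir <- cfg$out_dir
  invisible(results)
}

#' Write a complete synthetic demo bundle to disk
#'
#' Generates the default synthetic two-species dataset (see
#' [simulate_devexpr()]) and writes every input the pipeline consumes:
#' expression matrices and metadata for both species, the cell-type mean
#' table, a GMT of planted gene sets (markers, modules, switch genes) and
#' the ground-truth JSON.
#'
#' @param dir Output directory.
#' @param seed Simulation seed.
#' @param config Optional [sim_config()] overriding the defaults (its seed
#'   is replaced by `seed`).
#' @return Invisibly, a list with the written `paths`, the `truth` and the
#'   simulation object.
#' @export
make_demo <- function(dir = "devtraj_demo", seed = 1, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  else config$seed <- seed
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_devexpr(config)
  paths <- list(
    human_matrix = file.path(dir, "human_expr.tsv"),
    human_meta = file.path(dir, "human_meta.tsv"),
    macaque_matrix = file.path(dir, "macaque_expr.tsv"),
    macaque_meta = file.path(dir, "macaque_meta.tsv"),
    celltype_means = file.path(dir, "celltype_means.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json"))
  write_expression(sim$human, paths$human_matrix, paths$human_meta)
  write_expression(sim$macaque, paths$macaque_matrix, paths$macaque_meta)
  ctm <- data.frame(celltype = rownames(sim$celltype_means),
                    sim$celltype_means, check.names = FALSE)
  utils::write.table(ctm, paths$celltype_means, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets <- c(sim$truth$markers,
            lapply(sim$truth$module_blocks, `[[`, "genes"))
  sets$switch_genes <- sim$truth$switch_genes
  sets <- Filter(function(s) length(s) > 0, sets)
  if (length(sets) > 0) write_gmt(sets, paths$gene_sets)
  truth_json <- sim$truth
  truth_json$shifts <- as.list(truth_json$shifts)       # keep gene names in JSON
  truth_json$regulators <- as.list(truth_json$regulators)
  write_json_out(truth_json, paths$truth)
  invisible(list(paths = paths, truth = sim$truth, sim = sim))
}
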