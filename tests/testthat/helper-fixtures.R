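# small builders shared across the test files; all fixtures are generated in
# code, nothing is read from disk except files the tests write themselves

make_meta <- function(n, species = "human", ages = seq_len(n) * 10,
                      region = "V1C") {
  data.frame(sample_id = sprintf("%s_s%02d", substr(species, 1, 1), seq_len(n)),
             species = species, region = region, age_pcd = ages,
             stringsAsFactors = FALSE)
}

make_ds <- function(values, species = "human", ages = NULL, scale = "linear") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  meta <- make_meta(ncol(values), species,
                    ages = if (is.null(ages)) seq_len(ncol(values)) * 10 else ages)
  expression_dataset(values, rownames(values), meta, scale)
}

# two-species bump-trajectory gene on the early-development grids used by the
# heterochrony conditions; returns expression vectors with a planted shift
# (human delayed by `shift` log2-age units) in registered time
het_gene <- function(shift = 0, noise = 0.3, n = 20, center = 0.4,
                     width = 0.15, sign = 1) {
  ages_h <- geometric_ages(56, 1000, n)
  ages_m <- geometric_ages(50, 500, n)
  span_h <- diff(range(log2(ages_h)))
  u_h <- (log2(ages_h) - min(log2(ages_h))) / span_h
  u_m <- (log2(ages_m) - min(log2(ages_m))) / diff(range(log2(ages_m)))
  f <- function(u) sign * exp(-(u - center)^2 / (2 * width^2))
  amp <- 1 / stats::sd(f(seq(0, 1, length.out = 50)))
  list(expr_h = amp * f(u_h - shift / span_h) + stats::rnorm(n, 0, noise),
       expr_m = amp * f(u_m) + stats::rnorm(n, 0, noise),
       ages_h = ages_h, ages_m = ages_m, span_h = span_h)
}

# generator config scaled to one planted role, used by the focused tests
dnb_condition_config <- function(seed) {
  sim_config(n_genes = 150, n_switch = 40, n_dnb = 30, n_neoteny = 0,
             n_acceleration = 0, n_modules = 0, n_celltypes = 0,
             markers_per_type = 0, ages_human = macaque_age_grid(),
             transition_age_human = 119, replicates_per_age = 20, seed = seed)
}

de_power_config <- function(seed) {
  sim_config(n_genes = 200, n_switch = 60, noise_sd = 0.3, traj_amplitude = 0,
             n_dnb = 0, n_neoteny = 0, n_acceleration = 0, n_modules = 0,
             n_celltypes = 0, markers_per_type = 0,
             ages_human = geometric_ages(56, 1000, 10),
             transition_age_human = 230, replicates_per_age = 2, seed = seed)
}

module_condition_config <- function(seed, module_size = 50,
                                    corr_early = c(0.7, 0.3, 0.5),
                                    corr_late = c(0.3, 0.7, 0.5),
                                    n_modules = 3, replicates = 5) {
  sim_config(n_genes = 50 + n_modules + sum(rep(module_size, length.out = n_modules)),
             n_switch = 0, n_dnb = 0, n_neoteny = 0, n_acceleration = 0,
             n_modules = n_modules, module_size = module_size,
             module_corr_early = corr_early, module_corr_late = corr_late,
             n_celltypes = 0, markers_per_type = 0,
             ages_human = geometric_ages(56, 1000, 10),
             transition_age_human = 230, replicates_per_age = replicates,
             seed = seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
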