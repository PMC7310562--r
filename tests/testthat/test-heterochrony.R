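test_that("log2_age transforms and validates ages", {
  expect_equal(log2_age(56), 5.807, tolerance = 1e-3)
  expect_equal(log2_age(1), 0)
  expect_equal(log2_age(128), 7)
  expect_equal(log2_age(data.frame(age_pcd = c(2, 4))), c(1, 2))
  expect_error(log2_age(c(10, 0)), "nonpositive")
})

test_that("age_related_test finds the generating degree and calibrates on noise", {
  ages <- geometric_ages(56, 1000, 20)
  l2 <- log2_age(ages)
  # exact quadratic: degree 2 wins with essentially zero p
  y <- 2 + 0.5 * l2 - 0.3 * l2^2
  r <- suppressWarnings(age_related_test(y, l2))
  expect_equal(r$best_degree, 2)
  expect_lt(r$pvalue, 1e-10)
  expect_gt(r$adj_r2, 0.999)

  # linear + small noise: the adjusted-R2 penalty prefers degree 1
  set.seed(1)
  deg1 <- vapply(1:40, function(i)
    age_related_test(1 + 0.8 * l2 + rnorm(20, 0, 0.2), l2)$best_degree,
    numeric(1))
  expect_gt(mean(deg1 == 1), 0.5)

  # pure noise: p-values roughly uniform
  set.seed(2)
  pv <- vapply(1:400, function(i)
    age_related_test(rnorm(20), l2)$pvalue, numeric(1))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
  expect_gt(mean(pv > 0.5), 0.25)

  expect_warning(age_related_test(rnorm(4), log2_age(c(1, 2, 4, 8))), "capped")
})

test_that("species divergence ANCOVA reacts to offsets and time shifts", {
  set.seed(3)
  ages <- geometric_ages(56, 1000, 20)
  l2 <- log2_age(ages)
  shared <- 1 + 0.5 * l2 - 0.05 * l2^2

  # identical trajectories: no divergence
  p_same <- species_divergence_test(shared + rnorm(20, 0, 0.3), ages,
                                    shared + rnorm(20, 0, 0.3), ages, 2)
  expect_gt(p_same, 0.05)

  # constant vertical offset: main effect detected
  p_off <- species_divergence_test(shared + 1 + rnorm(20, 0, 0.2), ages,
                                   shared + rnorm(20, 0, 0.2), ages, 2)
  expect_lt(p_off, 1e-4)

  # time-shifted copy of the same curve: power >= 0.8 by Monte Carlo
  hits <- 0
  for (i in 1:25) {
    g <- het_gene(shift = 1, noise = 0.3)
    p <- species_divergence_test(g$expr_h, g$ages_h, g$expr_m, g$ages_m, 3)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 25, 0.8)
})

test_that("dtw_shift is zero for identical curves and recovers displacement", {
  set.seed(4)
  g <- het_gene(shift = 0, noise = 0)
  s0 <- dtw_shift(g$expr_h, g$ages_h, g$expr_h, g$ages_h, degree = 3)
  expect_equal(s0$shift_log2age, 0)

  # exact discrete displacement: curve b is curve a moved right by 10 grid
  # cells (constant tails), so the path's max displacement must be 10 cells
  # (a pinned-endpoint path bounds the MEAN displacement below the true lag,
  # so the max variant is the sharp one)
  G <- 60
  u <- seq(0, 1, length.out = G)
  base <- exp(-(u - 0.35)^2 / (2 * 0.12^2))
  shifted <- c(rep(base[1], 10), base[1:(G - 10)])
  al <- devtraj:::.dtw_align_cpp(as.numeric(scale(shifted)),
                                 as.numeric(scale(base)))
  expect_equal(al$max_displacement, 10 / (G - 1), tolerance = 1 / (G - 1))

  # end to end through the polynomial fits: planted +0.25 normalized
  # displacement recovered (fit ringing adds a little distortion)
  f <- function(v) exp(-(v - 0.35)^2 / (2 * 0.15^2))
  ages <- geometric_ages(56, 1000, 50)
  span <- diff(range(log2(ages)))
  uu <- (log2(ages) - min(log2(ages))) / span
  sh <- dtw_shift(f(uu - 0.25), ages, f(uu), ages, degree = 3,
                  statistic = "max")
  expect_lt(abs(sh$shift_log2age / span - 0.25), 0.15)

  # flat curve: shift undefined
  flat <- dtw_shift(rep(1, 20), g$ages_h, g$expr_m, g$ages_m, degree = 1)
  expect_true(is.na(flat$shift_log2age))
})

test_that("planted shifts are recovered with the right sign and magnitude", {
  set.seed(5)
  errs <- vapply(1:30, function(i) {
    g <- het_gene(shift = 1, noise = 0.3,
                  center = runif(1, 0.3, 0.55), width = runif(1, 0.13, 0.2),
                  sign = sample(c(-1, 1), 1))
    dtw_shift(g$expr_h, g$ages_h, g$expr_m, g$ages_m, degree = 3)$shift_log2age - 1
  }, numeric(1))
  expect_gt(mean(errs + 1 > 0), 0.93)          # sign recovery
  expect_lte(median(abs(errs)), 0.3)           # magnitude
})

test_that("swapping the species negates the shift on matched grids", {
  set.seed(6)
  ages <- geometric_ages(56, 1000, 20)
  span <- diff(range(log2(ages)))
  u <- (log2(ages) - min(log2(ages))) / span
  f <- function(v) exp(-(v - 0.4)^2 / (2 * 0.15^2))
  a <- 3 * f(u - 0.2) + rnorm(20, 0, 0.1)
  b <- 3 * f(u) + rnorm(20, 0, 0.1)
  s1 <- dtw_shift(a, ages, b, ages, degree = 3)$shift_log2age
  s2 <- dtw_shift(b, ages, a, ages, degree = 3)$shift_log2age
  expect_gt(s1, 0)
  expect_equal(s1, -s2, tolerance = 2 * span / 49)
})

test_that("bootstrap significance is powered on shifts and calibrated on nulls", {
  set.seed(7)
  hits <- 0
  for (i in 1:10) {
    g <- het_gene(shift = 1, noise = 0.3)
    s <- shift_significance(g$expr_h, g$ages_h, g$expr_m, g$ages_m,
                            degree = 3, n_sims = 200)
    hits <- hits + (s$pvalue < 0.05)
  }
  expect_gte(hits / 10, 0.8)

  set.seed(8)
  pv <- vapply(1:60, function(i) {
    g <- het_gene(shift = 0, noise = 0.3, center = runif(1, 0.3, 0.55))
    shift_significance(g$expr_h, g$ages_h, g$expr_m, g$ages_m,
                       degree = 3, n_sims = 200)$pvalue
  }, numeric(1))
  expect_lte(mean(pv < 0.05), 0.15)
  expect_gte(mean(pv > 0.3), 0.4)

  g <- het_gene(shift = 0, noise = 0)
  s0 <- shift_significance(g$expr_h, g$ages_h, g$expr_h, g$ages_h,
                           degree = 3, n_sims = 100)
  expect_gt(s0$pvalue, 0.9)  # zero observed shift cannot beat the null
  expect_error(shift_significance(g$expr_h, g$ages_h, g$expr_m, g$ages_m,
                                  n_sims = 50), "at least 100")
})

test_that("classification follows the sign/significance rule exactly", {
  expect_equal(classify_heterochrony(0.8, 0.01), "neoteny")
  expect_equal(classify_heterochrony(-0.8, 0.01), "acceleration")
  expect_equal(classify_heterochrony(0.8, 0.2), "none")
  expect_equal(classify_heterochrony(NA, 0.01), "none")
  expect_equal(classify_heterochrony(0, 0.001), "none")
})

test_that("the screen's pass flag is a pure function of its two p-values", {
  sim <- simulate_devexpr(sim_config(
    seed = 9, n_genes = 80, n_switch = 10, n_dnb = 0, n_neoteny = 5,
    n_acceleration = 5, n_modules = 0, n_celltypes = 0, markers_per_type = 0,
    ages_human = geometric_ages(56, 1000, 15),
    ages_macaque = geometric_ages(50, 500, 15),
    transition_age_human = 230, transition_age_macaque = 210,
    replicates_per_age = 1, noise_sd = 0.3))
  sc <- heterochrony_screen(log2_transform(sim$human),
                            log2_transform(sim$macaque))
  expect_identical(sc$passes, sc$age_pvalue < 0.05 & sc$species_pvalue < 0.05)
  # planted heterochronic genes are age-related by construction; the pooled
  # screen sees their bumps at species-offset positions, which dilutes but
  # does not erase the age signal
  expect_gt(mean(sc$age_pvalue[sc$gene %in% names(sim$truth$shifts)] < 0.05),
            0.6)
})

test_that("the full analysis classifies planted neoteny and acceleration", {
  sim <- simulate_devexpr(sim_config(
    seed = 10, n_genes = 60, n_switch = 0, n_dnb = 0, n_neoteny = 10,
    n_acceleration = 10, n_modules = 0, n_celltypes = 0, markers_per_type = 0,
    ages_human = geometric_ages(56, 1000, 20),
    ages_macaque = geometric_ages(50, 500, 20),
    transition_age_human = 230, transition_age_macaque = 210,
    replicates_per_age = 1, noise_sd = 0.3))
  res <- heterochrony_analysis(log2_transform(sim$human),
                               log2_transform(sim$macaque),
                               genes = names(sim$truth$shifts), n_sims = 200)
  calls <- setNames(res$class, res$gene)
  truth <- sim$truth$shifts
  sig <- calls != "none"
  expect_gt(sum(sig), 10)
  agree <- (calls[sig] == "neoteny") == (truth[names(calls[sig])] > 0)
  expect_gt(mean(agree), 0.9)
})
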