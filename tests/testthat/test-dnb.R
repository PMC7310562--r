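# independent double-loop oracle for the composite index
naive_ci <- function(x, group) {
  others <- setdiff(rownames(x), group)
  sds <- vapply(group, function(g) stats::sd(x[g, ]), numeric(1))
  pd <- c()
  for (i in seq_along(group)) for (j in seq_along(group)) if (i < j)
    pd <- c(pd, abs(cor(x[group[i], ], x[group[j], ])))
  po <- c()
  for (g in group) for (o in others)
    po <- c(po, abs(cor(x[g, ], x[o, ])))
  list(SD_d = mean(sds), PCC_d = mean(pd), PCC_o = mean(po),
       CI = mean(sds) * mean(pd) / mean(po))
}

test_that("sliding windows cover the series with the expected count", {
  meta <- make_meta(9, ages = seq_len(9) * 10)
  w <- sliding_windows(meta, width = 3, step = 1)
  expect_length(w, 7)  # n - width + 1
  expect_equal(w[[1]]$index, 1:3)
  expect_equal(w[[7]]$index, 7:9)
  expect_equal(w[[1]]$center_age_pcd, 20)
  expect_length(sliding_windows(meta, width = 9), 1)
  # trailing window is kept when the step would skip past it
  w2 <- sliding_windows(meta, width = 4, step = 4)
  expect_equal(w2[[length(w2)]]$index, 6:9)
  meta_bad <- meta; meta_bad$age_pcd <- rev(meta_bad$age_pcd)
  expect_error(sliding_windows(meta_bad, 3), "sorted")
  expect_error(sliding_windows(meta, width = 10), "width exceeds")
})

test_that("candidate groups recover planted correlated triplets", {
  set.seed(1)
  base1 <- rnorm(30); base2 <- rnorm(30)
  x <- rbind(A = base1 + rnorm(30, 0, 0.1),
             B = base1 + rnorm(30, 0, 0.1),
             C = -base1 + rnorm(30, 0, 0.1),  # |r| clustering catches the sign flip
             D = rnorm(30), E = rnorm(30))
  g <- candidate_groups(x, min_size = 3, corr_cut = 0.8)
  expect_length(g, 1)
  expect_setequal(g[[1]], c("A", "B", "C"))

  # two disjoint triplets
  x2 <- rbind(A = base1, B = base1 + rnorm(30, 0, 0.1), C = base1 + rnorm(30, 0, 0.1),
              D = base2, E = base2 + rnorm(30, 0, 0.1), F = base2 + rnorm(30, 0, 0.1))
  g2 <- candidate_groups(x2, min_size = 3, corr_cut = 0.8)
  expect_length(g2, 2)
  expect_setequal(lapply(g2, sort), list(c("A", "B", "C"), c("D", "E", "F")))

  # uncorrelated noise yields no group
  set.seed(2)
  x3 <- matrix(rnorm(5 * 200), 5, dimnames = list(LETTERS[1:5], NULL))
  expect_length(candidate_groups(x3, min_size = 3, corr_cut = 0.8), 0)
})

test_that("composite_index equals the naive double-loop oracle", {
  set.seed(3)
  for (rep in 1:20) {
    x <- matrix(rnorm(80), 10, 8, dimnames = list(sprintf("g%02d", 1:10), NULL))
    group <- sample(rownames(x), 4)
    got <- composite_index(x, group)
    want <- naive_ci(x, group)
    expect_equal(got$SD_d, want$SD_d, tolerance = 1e-12)
    expect_equal(got$PCC_d, want$PCC_d, tolerance = 1e-12)
    expect_equal(got$PCC_o, want$PCC_o, tolerance = 1e-12)
    expect_equal(got$CI, want$CI, tolerance = 1e-12)
  }
})

test_that("CI follows the defining arithmetic and its invariances", {
  set.seed(4)
  x <- matrix(rnorm(60), 6, 10, dimnames = list(letters[1:6], NULL))
  sc <- composite_index(x, c("a", "b", "c"))
  expect_equal(sc$CI, sc$SD_d * sc$PCC_d / sc$PCC_o, tolerance = 1e-12)
  expect_gte(sc$CI, 0)

  # scaling all expressions by c > 0 scales SD_d and CI, leaves PCCs alone
  sc3 <- composite_index(3 * x, c("a", "b", "c"))
  expect_equal(sc3$SD_d, 3 * sc$SD_d, tolerance = 1e-12)
  expect_equal(sc3$PCC_d, sc$PCC_d, tolerance = 1e-12)
  expect_equal(sc3$PCC_o, sc$PCC_o, tolerance = 1e-12)
  expect_equal(sc3$CI, 3 * sc$CI, tolerance = 1e-12)

  # duplicated gene pair: PCC_d is exactly 1
  y <- rbind(g1 = rnorm(12), g2 = 0, out = rnorm(12))
  y["g2", ] <- y["g1", ]
  dup <- composite_index(y, c("g1", "g2"))
  expect_equal(dup$PCC_d, 1, tolerance = 1e-12)
  expect_equal(dup$CI, dup$SD_d / dup$PCC_o, tolerance = 1e-12)

  # a large group of independent z-scored noise has PCC_d near 0
  set.seed(5)
  big <- matrix(rnorm(12 * 500), 12, 500,
                dimnames = list(sprintf("g%02d", 1:12), NULL))
  noise <- composite_index(big, sprintf("g%02d", 1:8))
  expect_lt(noise$PCC_d, 0.1)
})

test_that("degenerate composite_index inputs are handled explicitly", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), out = c(1, 1, 2, 1))
  expect_error(composite_index(x, "g1"), "at least 2")
  expect_error(composite_index(x[1:2, ], c("g1", "g2")), "non-group")
  xc <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(0, 1, 0, 2),
              out = c(1, 3, 2, 1))
  expect_warning(sc <- composite_index(xc, c("g1", "g2", "g3")), "constant")
  expect_true(is.finite(sc$CI))
})

test_that("an SD-only perturbation moves the CI peak to the perturbed window", {
  # one correlated group present everywhere, but its noise SD inflated only
  # around the transition age: the peak must come from the SD_d term
  set.seed(6)
  n_age <- 9; reps <- 6
  ages <- rep(seq_len(n_age) * 30, each = reps)
  n <- length(ages)
  factor_col <- rnorm(n)
  sd_vec <- ifelse(ages == 150, 3, 1)
  grp <- t(sapply(1:6, function(i)
    (sqrt(0.8) * factor_col + sqrt(0.2) * rnorm(n)) * sd_vec))
  others <- matrix(rnorm(30 * n), 30, n)
  vals <- rbind(grp, others)
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  ds <- make_ds(vals, ages = ages, scale = "linear"); ds$scale <- "log2"
  ds <- log2_z_transform(ds, log = FALSE)
  r <- detect_transition(ds, width = 6, min_size = 4)
  expect_equal(r$transition_age_pcd, 150, tolerance = 31)
  expect_true(r$transition_called)
  expect_gte(length(intersect(r$dnb_genes, sprintf("g%02d", 1:6))), 4)
})

test_that("null data does not call a transition", {
  sim <- simulate_null(dnb_condition_config(seed = 21))
  hz <- log2_z_transform(filter_expressed(sim$human))
  r <- detect_transition(hz)
  expect_false(r$transition_called)
})

test_that("planted DNB structure is recovered from simulated data", {
  sim <- simulate_devexpr(dnb_condition_config(seed = 31))
  hz <- log2_z_transform(filter_expressed(sim$human))
  r <- detect_transition(hz)
  expect_true(r$transition_called)
  expect_gte(r$transition_age_pcd, 90)
  expect_lte(r$transition_age_pcd, 165)
  expect_gte(jaccard(r$dnb_genes, sim$truth$dnb_genes), 0.6)
})
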