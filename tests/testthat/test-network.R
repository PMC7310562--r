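# brute-force TOM oracle
naive_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
    num <- num - 2 * a[i, i] * a[i, j]  # a has zero diagonal anyway
    out[i, j] <- (sum(a[i, ] * a[, j]) + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive BFS neighbourhood-size oracle
bfs_sizes <- function(nodes, edges, hops) {
  adj <- lapply(setNames(nodes, nodes), function(n)
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n])))
  vapply(nodes, function(start) {
    seen <- start
    frontier <- start
    for (h in seq_len(hops)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
    }
    length(seen) - 1L
  }, integer(1))
}

test_that("topological overlap matches hand values and the brute-force oracle", {
  a3 <- matrix(1, 3, 3) - diag(3)
  t3 <- topological_overlap(a3)
  expect_equal(t3, matrix(1, 3, 3))  # fully connected triangle overlaps fully

  z <- matrix(0, 4, 4)
  tz <- topological_overlap(z)
  expect_equal(tz, diag(4))

  set.seed(1)
  for (i in 1:10) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    got <- topological_overlap(a)
    expect_equal(got, naive_tom(a), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
    expect_equal(got, t(got), tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3)), "symmetric")
  bad <- matrix(0.5, 3, 3)
  expect_error(topological_overlap(bad), "diagonal")
})

test_that("soft power selection is deterministic and fits modular data", {
  sim <- simulate_devexpr(sim_config(
    seed = 2, n_genes = 300, n_switch = 0, n_dnb = 0, n_neoteny = 0,
    n_acceleration = 0, n_modules = 3, module_size = c(60, 40, 20),
    module_corr_early = c(0.75, 0.65, 0.55),
    module_corr_late = c(0.75, 0.65, 0.55),
    n_celltypes = 0, markers_per_type = 0,
    ages_human = geometric_ages(56, 1000, 10), transition_age_human = 230,
    replicates_per_age = 5))
  x <- split_by_age(log2_transform(sim$human), 230)$early$values
  p1 <- pick_soft_power(x)
  p2 <- pick_soft_power(x)
  expect_identical(as.integer(p1), as.integer(p2))
  expect_gte(attr(p1, "fit_r2"), 0.8)

  # exactly uncorrelated genes (orthogonal centred Helmert rows): degenerate
  # degree distribution falls back with a warning
  flat <- t(stats::contr.helmert(25))[1:24, ]
  expect_warning(pick_soft_power(flat), "best fit")
})

test_that("planted correlation blocks are recovered as modules", {
  skip_if_not_installed("mclust")
  cfg <- module_condition_config(seed = 4, module_size = 50,
                                 corr_early = 0.7, corr_late = 0.7,
                                 n_modules = 2)
  sim <- simulate_devexpr(cfg)
  x <- split_by_age(log2_transform(sim$human), 230)$early$values
  adj <- abs(cor(t(x)))^6; diag(adj) <- 0
  ms <- detect_modules(topological_overlap(adj))
  expect_length(ms$modules, 2)
  tg <- unlist(lapply(sim$truth$module_blocks, `[[`, "genes"))
  ari <- mclust::adjustedRandIndex(ms$assignment[tg], rep(1:2, each = 50))
  expect_gte(ari, 0.9)

  # pure noise dissolves into module 0
  set.seed(5)
  noise <- matrix(rnorm(60 * 40), 60, 40)
  adj0 <- abs(cor(t(noise)))^6; diag(adj0) <- 0
  ms0 <- detect_modules(topological_overlap(adj0))
  expect_length(ms0$modules, 0)
  expect_true(all(ms0$assignment == 0))
})

test_that("the minimum size filter drops small planted blocks", {
  cfg <- module_condition_config(seed = 6, module_size = c(60, 40, 20),
                                 corr_early = 0.7, corr_late = 0.7,
                                 n_modules = 3, replicates = 6)
  sim <- simulate_devexpr(cfg)
  x <- split_by_age(log2_transform(sim$human), 230)$early$values
  adj <- abs(cor(t(x)))^6; diag(adj) <- 0
  ms <- detect_modules(topological_overlap(adj), min_module_size = 30)
  expect_length(ms$modules, 2)
  sizes <- sort(vapply(ms$modules, length, 1L), decreasing = TRUE)
  expect_true(all(sizes >= 30))
  small <- sim$truth$module_blocks[[3]]$genes
  expect_true(all(ms$assignment[small] == 0))
})

test_that("mdc matches an independent connectivity computation and is antisymmetric", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:10)
  e <- matrix(rnorm(100), 10, 10, dimnames = list(genes, NULL))
  l <- matrix(rnorm(100), 10, 10, dimnames = list(genes, NULL))
  r <- mdc(genes, e, l, n_perm = 20)
  conn <- function(x, p = 6) {
    vals <- c()
    for (i in 1:9) for (j in (i + 1):10)
      vals <- c(vals, abs(cor(x[i, ], x[j, ]))^p)
    mean(vals)
  }
  expect_equal(r$mdc_value, log2(conn(e) / conn(l)), tolerance = 1e-12)

  # swapping the stages negates the value exactly (equal sample counts)
  r2 <- mdc(genes, l, e, n_perm = 20)
  expect_equal(r$mdc_value, -r2$mdc_value, tolerance = 1e-12)

  # identical stages: value exactly 0, class none
  r0 <- mdc(genes, e, e, n_perm = 20)
  expect_equal(r0$mdc_value, 0)
  expect_equal(r0$class, "none")
  expect_error(mdc(genes[1:2], e, l), "at least 3")
})

test_that("planted connectivity gain and loss are classified correctly", {
  sim <- simulate_devexpr(sim_config(seed = 8))
  st <- split_by_age(log2_transform(sim$human), 175)
  set.seed(8)
  classes <- vapply(sim$truth$module_blocks, function(b)
    mdc(b$genes, st$early$values, st$late$values)$class, "")
  expect_equal(unname(classes), c("gain", "loss", "none"))
})

test_that("DPI prunes the indirect edge of a noisy chain", {
  set.seed(9)
  n <- 100
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.5)
  z <- y + rnorm(n, 0, 0.5)
  expr <- rbind(X = x, Y = y, Z = z)
  net <- mi_network(expr, n_perm = 10)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_true("X Y" %in% pairs)
  expect_true("Y Z" %in% pairs)
  expect_false("X Z" %in% pairs)

  # independent genes: no significant edges
  set.seed(10)
  ind <- matrix(rnorm(8 * 60), 8, 60,
                dimnames = list(paste0("g", 1:8), NULL))
  net0 <- mi_network(ind, alpha = 0.001, n_perm = 20)
  expect_lte(nrow(net0$edges), 1)
})

test_that("the copula MI estimator tracks the Gaussian closed form", {
  set.seed(11)
  for (rho in c(0.3, 0.6, 0.9)) {
    x <- rnorm(500)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(500)
    rs <- 2 * sin(pi / 6 * cor(x, y, method = "spearman"))
    mi_hat <- -0.5 * log(1 - rs^2)
    expect_lt(abs(mi_hat - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("key drivers: star centre is the unique hub, rings have none", {
  star <- list(nodes = c("hub", paste0("leaf", 1:10)),
               edges = data.frame(from = "hub", to = paste0("leaf", 1:10),
                                  stringsAsFactors = FALSE))
  h <- key_drivers(star, hops = 1)
  expect_equal(as.character(h), "hub")
  expect_equal(unname(attr(h, "neighborhood_size")),
               unname(bfs_sizes(star$nodes, star$edges, 1)))

  ring <- list(nodes = paste0("n", 1:8),
               edges = data.frame(from = paste0("n", 1:8),
                                  to = paste0("n", c(2:8, 1)),
                                  stringsAsFactors = FALSE))
  expect_length(key_drivers(ring, hops = 2), 0)
  expect_equal(unname(attr(key_drivers(ring, hops = 2), "neighborhood_size")),
               unname(bfs_sizes(ring$nodes, ring$edges, 2)))
})

test_that("the planted early-stage regulator is an early-specific hub", {
  sim <- simulate_devexpr(sim_config(seed = 12))
  st <- split_by_age(log2_transform(sim$human), 175)
  b <- sim$truth$module_blocks[[3]]
  reg <- sim$truth$regulators[["module3"]]
  genes <- c(b$genes, reg)
  set.seed(12)
  enet <- mi_network(st$early$values[genes, ])
  lnet <- mi_network(st$late$values[genes, ])
  nb <- attr(key_drivers(enet), "neighborhood_size")
  expect_lte(rank(-nb)[reg], ceiling(0.05 * length(genes)))
  expect_true(reg %in% early_specific_hubs(enet, lnet))
  expect_length(early_specific_hubs(enet, enet), 0)
})

test_that("coexpression_modules assembles detection and MDC end to end", {
  cfg <- module_condition_config(seed = 13, module_size = 40,
                                 corr_early = c(0.7, 0.7),
                                 corr_late = c(0.2, 0.7), n_modules = 2,
                                 replicates = 6)
  sim <- simulate_devexpr(cfg)
  set.seed(13)
  ms <- coexpression_modules(log2_transform(sim$human), 230)
  expect_gte(length(ms$modules), 1)
  expect_named(ms$module_mdc, names(ms$modules))
  gain_block <- sim$truth$module_blocks[[1]]$genes
  hit <- which.max(vapply(ms$modules, function(g)
    length(intersect(g, gain_block)), 1L))
  expect_equal(ms$module_mdc[[hit]]$class, "gain")
})
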