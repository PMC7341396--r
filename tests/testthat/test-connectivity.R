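test_that("correlation matrix matches a direct covariance computation", {
  set.seed(1)
  x <- matrix(rnorm(50 * 4), 50, 4)
  C <- correlation_matrix(x)
  expect_equal(diag(C), rep(0, 4), ignore_attr = TRUE)
  expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  ## independent formula: cov / (sd_i sd_j)
  for (i in 1:3) for (j in (i + 1):4) {
    r <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j]))) /
      ((nrow(x) - 1) * sd(x[, i]) * sd(x[, j]))
    expect_equal(C[i, j], r, tolerance = 1e-12)
  }

  ## identical and negated columns
  y <- cbind(x[, 1], x[, 1], -x[, 1], x[, 2])
  Cy <- correlation_matrix(y)
  expect_equal(Cy[1, 2], 1)
  expect_equal(Cy[1, 3], -1)

  ## affine invariance per column
  z <- sweep(sweep(x, 2, c(2, 3, 0.5, 10), "*"), 2, c(1, 0, -5, 2), "+")
  expect_equal(unclass(correlation_matrix(z)), unclass(C), tolerance = 1e-12)

  xc <- x; xc[, 3] <- 7
  expect_error(correlation_matrix(xc), "constant ROI column\\(s\\): 3")
  expect_error(correlation_matrix(x[1:2, ]), "at least 3")
})

test_that("binarization keeps exactly the k strongest edges", {
  v <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  C <- matrix(0, 4, 4)
  C[upper.tri(C)] <- v
  C <- C + t(C)
  g <- binarize_at_sparsity(C, 0.5)
  expect_equal(g$n_edges, 3L)
  kept <- which(g$adjacency[upper.tri(C)] == 1)
  expect_setequal(C[upper.tri(C)][kept], c(0.9, 0.8, 0.7))

  ## complete graph when the budget covers all edges
  gfull <- binarize_at_sparsity(C, 0.999)
  expect_equal(sum(gfull$adjacency) / 2, 6)

  ## ties: edge count still k, resolved deterministically
  Ct <- matrix(0.5, 4, 4); diag(Ct) <- 0
  g1 <- binarize_at_sparsity(Ct, 0.5)
  g2 <- binarize_at_sparsity(Ct, 0.5)
  expect_equal(sum(g1$adjacency) / 2, 3)
  expect_identical(g1$adjacency, g2$adjacency)
  ## documented tie rule: lexicographically first (i, j) pairs win
  expect_equal(g1$adjacency[1, 2], 1)
  expect_equal(g1$adjacency[1, 3], 1)
  expect_equal(g1$adjacency[1, 4], 1)

  ## tiny S: empty graph with a warning flag, not an error
  expect_warning(ge <- binarize_at_sparsity(C, 0.01), "empty")
  expect_true(ge$empty)
  expect_equal(sum(ge$adjacency), 0)

  ## absolute ranking can pick strong negatives
  Cn <- matrix(0, 4, 4)
  Cn[upper.tri(Cn)] <- c(-0.95, 0.8, 0.1, 0.05, 0.02, 0.01)
  Cn <- Cn + t(Cn)
  gs <- binarize_at_sparsity(Cn, 1 / 6)
  ga <- binarize_at_sparsity(Cn, 1 / 6, rank = "absolute")
  expect_equal(gs$adjacency[1, 3], 1)  # signed: +0.8 wins
  expect_equal(ga$adjacency[1, 2], 1)  # absolute: -0.95 wins
})

test_that("binarization is monotone in sparsity with exact densities", {
  set.seed(2)
  C <- correlation_matrix(matrix(rnorm(60 * 12), 60, 12))
  m <- 12 * 11 / 2
  prev <- matrix(0, 12, 12)
  for (S in seq(0.05, 0.95, by = 0.1)) {
    g <- binarize_at_sparsity(C, S)
    expect_equal(sum(g$adjacency) / 2, floor(S * m + 0.5))  # exact density
    expect_true(all(g$adjacency >= prev))                   # nested edge sets
    expect_identical(g$adjacency, t(g$adjacency))
    prev <- g$adjacency
  }
})

test_that("the study sparsity grid enumerates 45 densities", {
  g <- sparsity_grid(0.08, 0.52, 0.01)
  expect_length(g$grid, 45L)
  expect_equal(g$grid[1], 0.08)
  expect_equal(g$grid[45], 0.52)
})

test_that("degree criterion bound matches the closed form", {
  expect_equal(degree_criterion_bound(90), 2 * log(90) / 89,
               tolerance = 1e-13)
  expect_equal(degree_criterion_bound(90, log_base = "log10"),
               2 * log10(90) / 89, tolerance = 1e-13)
})

test_that("sparsity-range selection applies both criteria", {
  set.seed(3)
  ## correlated control matrices so small-worldness is well defined
  mats <- lapply(1:4, function(i)
    correlation_matrix(equicorr_ts(120, 30, 0.3)))

  ## both criteria disabled -> full candidate grid returned
  full <- select_sparsity_range(mats, step = 0.05, degree_factor = 0,
                                sw_floor = 0,
                                candidates = sparsity_grid(0.05, 0.5, 0.05))
  expect_equal(full$grid, sparsity_grid(0.05, 0.5, 0.05)$grid)

  ## degree criterion alone: lower cut at the closed-form bound
  dg <- select_sparsity_range(mats, step = 0.01, degree_factor = 2,
                              sw_floor = 0,
                              candidates = sparsity_grid(0.01, 0.5, 0.01))
  n <- 30
  ks <- floor(sparsity_grid(0.01, 0.5, 0.01)$grid * n * (n - 1) / 2 + 0.5)
  expected_min <- sparsity_grid(0.01, 0.5, 0.01)$grid[
    which(2 * ks / n >= 2 * log(n))[1]]
  expect_equal(dg$s_min, expected_min)
  expect_equal(dg$s_max, 0.5)

  ## impossible floor -> informative error
  expect_error(
    select_sparsity_range(mats, sw_floor = 50,
                          candidates = sparsity_grid(0.2, 0.4, 0.05),
                          n_random = 10),
    "small-world criterion")
})
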