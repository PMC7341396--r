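complete_graph <- function(n) { A <- matrix(1, n, n); diag(A) <- 0; A }
path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}
star_graph <- function(n) {
  A <- matrix(0, n, n); A[1, 2:n] <- A[2:n, 1] <- 1; A
}
ring_graph <- function(n, k = 2) {  # ring lattice, each node tied to k nearest
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k)) {
    j <- ((i + d - 1) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  A
}

test_that("metrics agree with closed forms on canonical graphs", {
  K4 <- complete_graph(4)
  expect_equal(as.numeric(char_path_length(K4)), 1)
  expect_true(attr(char_path_length(K4), "connected"))
  expect_equal(global_efficiency(K4), 1)
  expect_equal(clustering_coef(K4), 1)
  expect_equal(transitivity_coef(K4), 1)

  P3 <- path_graph(3)
  expect_equal(as.numeric(char_path_length(P3)), 4 / 3)
  expect_equal(global_efficiency(P3), 5 / 6)

  S4 <- star_graph(4)
  expect_equal(clustering_coef(S4), 0)
  expect_equal(transitivity_coef(S4), 0)

  ## two disjoint K2: mean over the 2 reachable pairs, flagged disconnected
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  cp <- char_path_length(A)
  expect_equal(as.numeric(cp), 1)
  expect_false(attr(cp, "connected"))

  ## empty graph: efficiency 0, path length undefined
  E4 <- matrix(0, 4, 4)
  expect_equal(global_efficiency(E4), 0)
  expect_error(char_path_length(E4), "no reachable pairs")

  ## triangle plus pendant: brute-force clustering
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1
  A[3, 4] <- A[4, 3] <- 1
  expect_equal(clustering_coef(A), bf_clustering(A), tolerance = 1e-12)

  ## no connected triples: transitivity defined as 0 with a warning
  expect_warning(tr <- transitivity_coef(matrix(0, 3, 3)), "no connected triples")
  expect_equal(as.numeric(tr), 0)
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    m <- n * (n - 1) / 2
    k <- sample.int(m, 1)
    A <- rand_graph(n, k)
    expect_equal(global_efficiency(A), bf_efficiency(A), tolerance = 1e-10)
    expect_equal(clustering_coef(A), bf_clustering(A), tolerance = 1e-10)
    expect_equal(suppressWarnings(as.numeric(transitivity_coef(A))),
                 bf_transitivity(A), tolerance = 1e-10)
    D <- bf_distances(A)
    if (any(is.finite(D[upper.tri(D)])))
      expect_equal(as.numeric(char_path_length(A)), bf_char_path(A),
                   tolerance = 1e-10)
    expect_equal(graph_distances(A), D)
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    A <- rand_graph(n, sample.int(n * (n - 1) / 2, 1))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(clustering_coef(A),
                 mean(igraph::transitivity(g, type = "localundirected",
                                           isolates = "zero")),
                 tolerance = 1e-10)
    tr <- igraph::transitivity(g, type = "global")
    if (!is.nan(tr))
      expect_equal(transitivity_coef(A), tr, tolerance = 1e-10)
    if (igraph::is_connected(g))
      expect_equal(as.numeric(char_path_length(A)),
                   igraph::mean_distance(g), tolerance = 1e-10)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(13)
  A <- rand_graph(10, 20)
  p <- sample(10)
  B <- A[p, p]
  expect_equal(clustering_coef(B), clustering_coef(A), tolerance = 1e-12)
  expect_equal(transitivity_coef(B), transitivity_coef(A), tolerance = 1e-12)
  expect_equal(global_efficiency(B), global_efficiency(A), tolerance = 1e-12)
  expect_equal(as.numeric(char_path_length(B)),
               as.numeric(char_path_length(A)), tolerance = 1e-12)
})

test_that("efficiency and path length respond correctly to edge additions", {
  set.seed(14)
  A <- rand_graph(9, 12)
  lin <- which(upper.tri(A) & A == 0)
  eff0 <- global_efficiency(A)
  cp0 <- char_path_length(A)
  for (e in lin[seq_len(min(5, length(lin)))]) {
    B <- A
    B[e] <- 1
    B[arrayInd(e, dim(A))[, c(2, 1), drop = FALSE]] <- 1
    expect_gte(global_efficiency(B), eff0 - 1e-12)
    if (attr(cp0, "connected"))
      expect_lte(as.numeric(char_path_length(B)), as.numeric(cp0) + 1e-12)
  }
  ## harmonic-arithmetic inequality on a connected graph
  Ac <- ring_graph(10, 2)
  expect_gte(global_efficiency(Ac), 1 / as.numeric(char_path_length(Ac)))
})

test_that("random reference is deterministic and matches ER expectations", {
  r1 <- random_reference(20, 60, n_random = 10, seed = 5)
  r2 <- random_reference(20, 60, n_random = 10, seed = 5)
  expect_identical(r1$c0, r2$c0)
  expect_identical(r1$l0, r2$l0)
  r3 <- random_reference(20, 60, n_random = 10, seed = 6)
  expect_false(identical(r1$c0, r3$c0))

  ## full density -> complete reference
  rfull <- random_reference(6, 15, n_random = 3, seed = 1)
  expect_equal(rfull$c0, 1)
  expect_equal(rfull$l0, 1)

  ## ER expected clustering ~ density
  p <- 0.3
  k <- round(p * 90 * 89 / 2)
  rer <- random_reference(90, k, n_random = 30, seed = 2)
  expect_lt(abs(rer$c0 - p), 0.02)
})

test_that("small-worldness normalizes clustering and path length", {
  ## direct substitution: C = 2 C0, L = L0 -> SW = 2
  A <- ring_graph(12, 2)
  cl <- clustering_coef(A)
  cp <- as.numeric(char_path_length(A))
  ref <- structure(list(c0 = cl / 2, l0 = cp, n_nodes = 12L, n_edges = 24L,
                        n_random = 1L, seed = 1L),
                   class = "random_reference")
  expect_equal(small_worldness(A, ref), 2)

  ## ring lattice vs matched random references: SW > 1
  L <- ring_graph(30, 3)
  refL <- random_reference(30, sum(L) / 2, n_random = 20, seed = 3)
  expect_gt(small_worldness(L, refL), 1)

  ## zero clustering -> 0 with warning; degenerate reference -> error
  P <- path_graph(5)
  refP <- random_reference(5, 4, n_random = 10, seed = 4)
  if (refP$c0 > 0)
    expect_warning(expect_equal(small_worldness(P, refP), 0), "zero clustering")
  bad <- structure(list(c0 = 0, l0 = 1), class = "random_reference")
  expect_error(small_worldness(L, bad), "C0 must be")
})

test_that("AUC matches closed forms and an independent re-summation", {
  g <- sparsity_grid(0.08, 0.52, 0.01)
  expect_equal(metric_auc(rep(1, 45), g), 0.44, tolerance = 1e-12)
  expect_equal(metric_auc(rep(2.5, 45), g), 1.1, tolerance = 1e-12)
  x <- c(0, 0.5, 1)
  expect_equal(metric_auc(x, x), 0.5, tolerance = 1e-12)
  set.seed(15)
  y <- rnorm(45)
  expect_equal(metric_auc(y, g), bf_trapz(g$grid, y), tolerance = 1e-12)
  expect_error(metric_auc(1:3, g), "lengths differ")
  ## NA points are dropped; fewer than 2 finite values -> NA
  y2 <- y; y2[c(1, 10)] <- NA
  keep <- is.finite(y2)
  expect_equal(metric_auc(y2, g), bf_trapz(g$grid[keep], y2[keep]),
               tolerance = 1e-12)
  expect_true(is.na(metric_auc(c(NA, NA, 1), c(0.1, 0.2, 0.3))))
})

test_that("metric sweep matches pointwise binarize-and-measure", {
  set.seed(16)
  C <- correlation_matrix(equicorr_ts(80, 15, 0.3))
  g <- sparsity_grid(0.1, 0.5, 0.1)
  sw <- metric_sweep(C, g, n_random = 10, seed = 2)
  expect_equal(nrow(sw), 5L)
  for (r in seq_len(nrow(sw))) {
    gb <- binarize_at_sparsity(C, sw$sparsity[r])
    expect_equal(sw$char[r], as.numeric(char_path_length(gb)))
    expect_equal(sw$clus[r], clustering_coef(gb))
    expect_equal(sw$tran[r], transitivity_coef(gb))
    expect_equal(sw$effi[r], global_efficiency(gb))
  }
  aucs <- sweep_auc(sw)
  expect_equal(aucs[["clus"]], metric_auc(sw$clus, sw$sparsity))
  expect_named(aucs, c("char", "effi", "clus", "tran", "sw"))
})
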