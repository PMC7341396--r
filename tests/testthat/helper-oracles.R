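## Independent brute-force oracles for graph metrics, kept deliberately
## naive (Floyd-Warshall distances, explicit triple/triangle enumeration)
## and separate from the package's implementations.

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_char_path <- function(A) {
  D <- bf_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

bf_efficiency <- function(A) {
  D <- bf_distances(A)
  mean(1 / D[upper.tri(D)])
}

bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    t <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] > 0) t <- t + 1
    ci[i] <- t / (k * (k - 1) / 2)
  }
  mean(ci)
}

bf_transitivity <- function(A) {
  n <- nrow(A)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    for (a in seq_len(k - 1))
      for (b in (a + 1):k) {
        triples <- triples + 1
        if (A[nb[a], nb[b]] > 0) triangles <- triangles + 1
      }
  }
  if (triples == 0) return(0)
  triangles / triples  # = 3 * n_triangles / n_connected_triples
}

## uniform random graph with exactly k edges
rand_graph <- function(n, k) {
  lin <- which(upper.tri(matrix(0, n, n)))
  A <- matrix(0, n, n)
  if (k > 0) {
    A[sample(lin, k)] <- 1
    A <- A + t(A)
  }
  A
}

## brute-force Benjamini-Hochberg step-up q-values
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

## independent trapezoid re-summation
bf_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

## T x n time series whose population correlation is rho within one block
equicorr_ts <- function(T, n, rho) {
  sigma <- matrix(rho, n, n)
  diag(sigma) <- 1
  matrix(rnorm(T * n), T, n) %*% chol(sigma)
}

## small two-network partition for cheap cohort configs
tiny_partition <- function(n_per = 3L) {
  rsn_partition(rep(c("A", "B"), each = n_per))
}

tiny_cohort_config <- function(n_per = 3L, T = 40L,
                               sizes = c(NC = 2L, EMCI = 2L, LMCI = 2L, AD = 2L),
                               seed = 1L, ...) {
  w <- rbind(A = c(0.30, 0.45, 0.35, 0.20), B = c(0.45, 0.38, 0.30, 0.22))
  colnames(w) <- ad_stages()
  cohort_config(n_rois = 2L * n_per, n_timepoints = T, group_sizes = sizes,
                partition = tiny_partition(n_per), within_r = w,
                network_pattern = c(A = "inversion", B = "decline"),
                seed = seed, ...)
}
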