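as_adjacency <- function(G) {
  A <- if (inherits(G, "binary_graph")) G$adjacency else unclass(as.matrix(G))
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  A
}

#' Shortest-path hop distances of an unweighted graph
#'
#' All-pairs breadth-first distances computed by repeated boolean matrix
#' products; unreachable pairs are `Inf`.
#'
#' @param G A `binary_graph` or 0/1 adjacency matrix.
#' @return N x N matrix of hop counts (0 on the diagonal).
#' @export
graph_distances <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n < 2L || sum(A) == 0) return(D)
  D[A > 0] <- 1
  reach <- A
  d <- 1L
  repeat {
    d <- d + 1L
    if (d > n) break
    reach <- (reach %*% A) > 0
    new <- reach & !is.finite(D)
    diag(new) <- FALSE
    if (!any(new)) break
    D[new] <- d
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over unordered node pairs.  The plain formula
#' is infinite for disconnected graphs, which occur at low sparsity; the mean
#' is therefore restricted to reachable pairs and the result carries a
#' `"connected"` attribute so disconnection is never silent.
#'
#' @param G A `binary_graph` or adjacency matrix with >= 2 nodes.
#' @return Positive scalar (hops) with logical attribute `"connected"`.
#' @export
char_path_length <- function(G) {
  A <- as_adjacency(G)
  if (nrow(A) < 2L) stop("need at least 2 nodes")
  D <- graph_distances(A)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  if (!any(fin)) stop("graph has no reachable pairs (no edges)")
  structure(mean(d[fin]), connected = all(fin))
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' `1/Inf = 0` for unreachable pairs — no special-casing of disconnected
#' graphs is needed.
#'
#' @inheritParams char_path_length
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(G) {
  A <- as_adjacency(G)
  if (nrow(A) < 2L) stop("need at least 2 nodes")
  D <- graph_distances(A)
  mean(1 / D[upper.tri(D)])
}

## per-node degree and triangle counts (t_i = edges among neighbors of i)
node_triangles <- function(A) {
  k <- rowSums(A)
  t3 <- diag(A %*% A %*% A) / 2
  list(k = k, t = t3)
}

#' Clustering coefficient
#'
#' Mean over nodes of `C_i = t_i / (k_i (k_i - 1) / 2)`, the fraction of a
#' node's neighbor pairs that are themselves connected; `C_i = 0` for nodes
#' of degree < 2 (the standard convention).
#'
#' @inheritParams char_path_length
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coef <- function(G) {
  A <- as_adjacency(G)
  nt <- node_triangles(A)
  ci <- ifelse(nt$k < 2, 0, nt$t / (nt$k * (nt$k - 1) / 2))
  mean(ci)
}

#' Transitivity
#'
#' Graph-level triangle density `sum(2 t_i) / sum(k_i (k_i - 1))`.  When no
#' node has degree >= 2 the denominator is zero and the value is defined as 0
#' with a `"degenerate"` attribute and a warning.
#'
#' @inheritParams char_path_length
#' @return Scalar in `[0, 1]`.
#' @export
transitivity_coef <- function(G) {
  A <- as_adjacency(G)
  nt <- node_triangles(A)
  den <- sum(nt$k * (nt$k - 1))
  if (den == 0) {
    warning("no connected triples; transitivity defined as 0")
    return(structure(0, degenerate = TRUE))
  }
  sum(2 * nt$t) / den
}

#' Random-network reference for small-worldness
#'
#' Ensemble of uniform random graphs with the same node count and edge count
#' (density) as the target graph; returns the ensemble means of the
#' clustering coefficient (C0) and characteristic path length (L0).
#' Reproducible under `seed`, which is applied locally.
#'
#' @param n_nodes,n_edges Size and edge count to match.
#' @param n_random Ensemble size (default 100).
#' @param seed Integer seed.
#' @return Object of class `random_reference` with fields `c0`, `l0`,
#'   `n_nodes`, `n_edges`, `n_random`, `seed`.
#' @export
random_reference <- function(n_nodes, n_edges, n_random = 100L, seed = 1L) {
  stopifnot(n_random >= 1L, n_nodes >= 2L)
  m <- n_nodes * (n_nodes - 1) / 2
  stopifnot(n_edges >= 0, n_edges <= m)
  lin <- which(upper.tri(matrix(0, n_nodes, n_nodes)))
  res <- with_local_seed(seed, {
    cs <- ls <- numeric(n_random)
    for (r in seq_len(n_random)) {
      A <- matrix(0, n_nodes, n_nodes)
      if (n_edges > 0) {
        A[sample(lin, n_edges)] <- 1
        A <- A + t(A)
      }
      nt <- node_triangles(A)
      cs[r] <- mean(ifelse(nt$k < 2, 0, nt$t / (nt$k * (nt$k - 1) / 2)))
      D <- graph_distances(A)
      d <- D[upper.tri(D)]
      fin <- is.finite(d)
      ls[r] <- if (any(fin)) mean(d[fin]) else NA_real_
    }
    c(mean(cs), mean(ls, na.rm = TRUE))
  })
  structure(list(c0 = res[1], l0 = res[2], n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges), n_random = as.integer(n_random),
                 seed = as.integer(seed)),
            class = "random_reference")
}

## memoized reference ensembles; the ensemble seed is derived from
## (n_nodes, n_edges, base seed) so results never depend on evaluation order
cached_reference <- function(n_nodes, n_edges, n_random = 100L, base_seed = 1L) {
  key <- paste(n_nodes, n_edges, n_random, base_seed, sep = ":")
  cache <- .stagenet_env$ref_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  ref <- random_reference(n_nodes, n_edges, n_random,
                          seed = derive_seed(base_seed, n_nodes * 1000 + n_edges))
  cache[[key]] <- ref
  ref
}

#' Empty the memoized random-reference cache
#' @return Invisibly `NULL`.
#' @export
clear_reference_cache <- function() {
  .stagenet_env$ref_cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

#' Small-worldness
#'
#' `SW = (C / C0) / (L / L0)`: clustering and characteristic path length
#' normalized by a size- and density-matched random reference.  Values above
#' 1 indicate small-world organization.
#'
#' @param G A `binary_graph` or adjacency matrix.
#' @param ref A [random_reference()] (or [cached_reference] result).
#' @return Nonnegative scalar; 0 with a warning when the graph has zero
#'   clustering.
#' @export
small_worldness <- function(G, ref) {
  stopifnot(inherits(ref, "random_reference"))
  if (is.na(ref$c0) || ref$c0 <= 0) stop("reference clustering C0 must be > 0")
  if (is.na(ref$l0) || ref$l0 <= 0) stop("reference path length L0 must be > 0")
  cl <- clustering_coef(G)
  if (cl == 0) {
    warning("graph has zero clustering; small-worldness set to 0")
    return(0)
  }
  L <- as.numeric(char_path_length(G))
  (cl / ref$c0) / (L / ref$l0)
}

#' All five global metrics of one binary graph
#'
#' @param G A `binary_graph` or adjacency matrix.
#' @param ref Optional [random_reference()]; built on the fly (memoized) when
#'   `NULL`.
#' @param n_random,seed Reference settings used when `ref` is `NULL`.
#' @return Named list `char`, `effi`, `clus`, `tran`, `sw`, plus `connected`.
#' @export
global_metrics <- function(G, ref = NULL, n_random = 100L, seed = 1L) {
  A <- as_adjacency(G)
  n <- nrow(A)
  D <- graph_distances(A)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  cha <- if (any(fin)) mean(d[fin]) else NA_real_
  eff <- mean(1 / d)
  nt <- node_triangles(A)
  clu <- mean(ifelse(nt$k < 2, 0, nt$t / (nt$k * (nt$k - 1) / 2)))
  den <- sum(nt$k * (nt$k - 1))
  tra <- if (den > 0) sum(2 * nt$t) / den else 0
  if (is.null(ref)) ref <- cached_reference(n, sum(A) / 2, n_random, seed)
  sw <- if (!is.na(cha) && clu > 0 && !is.na(ref$c0) && ref$c0 > 0 &&
            !is.na(ref$l0) && ref$l0 > 0)
    (clu / ref$c0) / (cha / ref$l0) else NA_real_
  list(char = cha, effi = eff, clus = clu, tran = tra, sw = sw,
       connected = all(fin))
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of metric values against sparsity.  `NA` values
#' (e.g. grid points where a small subnetwork has no edges) are dropped and
#' the integral taken over the remaining contiguous grid; at least two finite
#' points are required.
#'
#' @param values Numeric vector, one value per grid point.
#' @param grid A [sparsity_grid()] or numeric vector of the same length.
#' @return Scalar AUC (metric units x density), or `NA` if fewer than two
#'   finite values remain.
#' @examples
#' metric_auc(rep(1, 45), sparsity_grid(0.08, 0.52, 0.01))  # 0.44
#' @export
metric_auc <- function(values, grid) {
  x <- as_grid(grid)
  if (length(x) != length(values)) stop("values and grid lengths differ")
  if (length(x) < 2L) stop("grid needs at least 2 points")
  ok <- is.finite(values)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- values[ok]
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Metric curves of one subject over the sparsity sweep
#'
#' Binarizes a connectivity matrix at every grid sparsity and evaluates the
#' five global metrics, with the small-world reference matched to the graph's
#' size and edge count (memoized across calls).
#'
#' @param C A [correlation_matrix()].
#' @param grid A [sparsity_grid()].
#' @param rank Edge ranking, see [binarize_at_sparsity()].
#' @param n_random,seed Random-reference settings.
#' @return `data.frame` with columns `sparsity`, `char`, `effi`, `clus`,
#'   `tran`, `sw`, `connected`, `empty`.
#' @export
metric_sweep <- function(C, grid, rank = "signed", n_random = 100L, seed = 1L) {
  C <- as_connectivity(C)
  s <- as_grid(grid)
  n <- nrow(C)
  ei <- edge_index(n)
  v <- C[ei$lin]
  score <- v
  ord <- order(-score, ei$i, ei$j)
  m <- length(v)
  if (identical(rank, "absolute")) ord <- order(-abs(v), ei$i, ei$j)
  A <- matrix(0, n, n)
  kprev <- 0L
  out <- vector("list", length(s))
  for (gi in seq_along(s)) {
    k <- as.integer(floor(s[gi] * m + 0.5))
    if (k > kprev) {        # monotone fill: lower-S edge sets are subsets
      sel <- ord[(kprev + 1L):k]
      A[ei$lin[sel]] <- 1
      A[(ei$i[sel] - 1L) * n + ei$j[sel]] <- 1
      kprev <- k
    }
    if (k == 0L) {
      out[[gi]] <- data.frame(sparsity = s[gi], char = NA_real_, effi = 0,
                              clus = 0, tran = 0, sw = NA_real_,
                              connected = FALSE, empty = TRUE)
      next
    }
    ref <- cached_reference(n, k, n_random, seed)
    gm <- global_metrics(A, ref)
    out[[gi]] <- data.frame(sparsity = s[gi], char = gm$char, effi = gm$effi,
                            clus = gm$clus, tran = gm$tran, sw = gm$sw,
                            connected = gm$connected, empty = FALSE)
  }
  do.call(rbind, out)
}

#' AUC summary of a metric sweep
#'
#' @param sweep Output of [metric_sweep()].
#' @return Named numeric vector with the AUC of `char`, `effi`, `clus`,
#'   `tran`, `sw` over the sweep grid.
#' @export
sweep_auc <- function(sweep) {
  metrics <- c("char", "effi", "clus", "tran", "sw")
  vapply(metrics, function(m) metric_auc(sweep[[m]], sweep$sparsity), 0)
}
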