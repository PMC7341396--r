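#' Pearson correlation matrix of an ROI time series
#'
#' Entry (i, j) is the Pearson correlation of ROI columns i and j; the
#' diagonal (self-correlation) is set to 0.  Invariant to per-column affine
#' rescaling of the time series.
#'
#' @param ts A [roi_timeseries()] or a plain T x N numeric matrix with
#'   T >= 3 and no constant column.
#' @return N x N symmetric matrix of class `connectivity_matrix`, zero
#'   diagonal, off-diagonal entries in `[-1, 1]`.
#' @export
correlation_matrix <- function(ts) {
  x <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  if (nrow(x) < 3L) stop("need at least 3 time points")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("constant ROI column(s): ", paste(which(v == 0), collapse = ", "))
  C <- stats::cor(x)
  diag(C) <- 0
  structure(unname(C), class = c("connectivity_matrix", "matrix", "array"))
}

as_connectivity <- function(C) {
  C <- unclass(C)
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("connectivity matrix must be square")
  if (max(abs(C - t(C))) > 1e-8) stop("connectivity matrix must be symmetric")
  C
}

## upper-triangle (i, j) index pairs, i < j, in lexicographic (i, j) order
edge_index <- function(n) {
  i <- sequence(seq_len(n - 1L))                    # column-major upper tri
  j <- rep.int(2:n, 1:(n - 1L))
  o <- order(i, j)
  list(i = i[o], j = j[o], lin = (j[o] - 1L) * n + i[o])
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Retains the `k = round(S * N(N-1)/2)` strongest edges (round-half-up).
#' Edges are ranked by signed correlation, strongest positive first, the
#' common convention in sparsity-threshold connectome studies; set
#' `rank = "absolute"` to rank by magnitude.  Ties at the cutoff are broken
#' deterministically by lexicographic (i, j) position, so binarization is
#' monotone in S: the edge set at a lower sparsity is always a subset of the
#' edge set at a higher one.
#'
#' @param C A [correlation_matrix()] (or symmetric numeric matrix).
#' @param S Sparsity (edge density) in (0, 1).
#' @param rank `"signed"` (default) or `"absolute"` edge ranking.
#' @return Object of class `binary_graph`: fields `adjacency` (N x N 0/1,
#'   symmetric, zero diagonal), `sparsity`, `n_edges`, and `empty` (flag set
#'   with a warning when the edge budget rounds to zero).
#' @export
binarize_at_sparsity <- function(C, S, rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  C <- as_connectivity(C)
  if (S <= 0 || S >= 1) stop("sparsity S must be in (0, 1)")
  n <- nrow(C)
  ei <- edge_index(n)
  m <- length(ei$lin)
  k <- floor(S * m + 0.5)
  A <- matrix(0, n, n)
  if (k > 0) {
    v <- C[ei$lin]
    score <- if (rank == "absolute") abs(v) else v
    sel <- order(-score, ei$i, ei$j)[seq_len(k)]
    A[ei$lin[sel]] <- 1
    A <- A + t(A)
  } else {
    warning("edge budget rounds to zero at S = ", S, "; empty graph returned")
  }
  structure(list(adjacency = A, sparsity = S, n_edges = as.integer(k),
                 empty = k == 0L),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (S = %.3f)%s\n",
              nrow(x$adjacency), x$n_edges, x$sparsity,
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Arithmetic sparsity grid
#'
#' @param s_min,s_max Grid end points in (0, 1), `s_min <= s_max`.
#' @param step Grid step (> 0).
#' @return Object of class `sparsity_range` with fields `s_min`, `s_max`,
#'   `step` and the ordered `grid`.
#' @examples
#' length(sparsity_grid(0.08, 0.52, 0.01)$grid)  # 45
#' @export
sparsity_grid <- function(s_min, s_max, step = 0.01) {
  stopifnot(step > 0, s_min > 0, s_max < 1, s_min <= s_max)
  grid <- round(seq(s_min, s_max, by = step), 10)
  structure(list(s_min = s_min, s_max = s_max, step = step, grid = grid),
            class = "sparsity_range")
}

as_grid <- function(grid) {
  if (inherits(grid, "sparsity_range")) grid$grid else as.numeric(grid)
}

#' Select the sparsity sweep range from the control group
#'
#' Scans a candidate grid and keeps the maximal contiguous run of sparsities
#' satisfying both criteria used to bound fake edges: (a) the mean degree of
#' every binarized control-group network is at least
#' `degree_factor * log(N)`, and (b) the control-group mean small-worldness
#' is at least `sw_floor`.  With equal edge budgets the mean degree
#' `2k/N` is the same for every subject, so (a) reduces to a closed-form
#' bound: it first holds near `S >= degree_factor * log(N) / (N - 1)`
#' (about 0.101 for N = 90 with the natural log).
#'
#' @param nc_matrices Nonempty list of control-group connectivity matrices.
#' @param step Candidate grid step.
#' @param degree_factor Multiplier of `log(N)` in criterion (a); default 2.
#' @param sw_floor Small-worldness floor in criterion (b); default 1.1.
#' @param log_base `"natural"` (default) or `"log10"`.
#' @param candidates Optional candidate grid (a [sparsity_grid()] or numeric
#'   vector); defaults to `sparsity_grid(step, 0.6, step)` — denser graphs
#'   are never small-world at the default floor.
#' @param n_random,seed Random-reference ensemble settings for criterion (b).
#' @param rank Edge ranking passed to [binarize_at_sparsity()].
#' @return A [sparsity_grid()] over the selected contiguous range.
#' @export
select_sparsity_range <- function(nc_matrices, step = 0.01, degree_factor = 2,
                                  sw_floor = 1.1,
                                  log_base = c("natural", "log10"),
                                  candidates = NULL, n_random = 100L,
                                  seed = 1L, rank = "signed") {
  log_base <- match.arg(log_base)
  if (length(nc_matrices) < 1L) stop("need at least one control matrix")
  if (is.null(candidates)) candidates <- sparsity_grid(step, 0.6, step)
  s <- as_grid(candidates)
  n <- nrow(as_connectivity(nc_matrices[[1L]]))
  logN <- if (log_base == "natural") log(n) else log10(n)
  m <- n * (n - 1) / 2
  ok_a <- ok_b <- logical(length(s))
  for (gi in seq_along(s)) {
    k <- floor(s[gi] * m + 0.5)
    ok_a[gi] <- (2 * k / n) >= degree_factor * logN
    if (sw_floor <= 0) { ok_b[gi] <- TRUE; next }
    if (!ok_a[gi] && degree_factor > 0) { ok_b[gi] <- NA; next } # skip work
    sw <- vapply(nc_matrices, function(C) {
      g <- suppressWarnings(binarize_at_sparsity(C, s[gi], rank = rank))
      if (g$empty) return(NA_real_)
      ref <- cached_reference(n, g$n_edges, n_random, seed)
      suppressWarnings(small_worldness(g, ref))
    }, 0)
    ok_b[gi] <- mean(sw, na.rm = TRUE) >= sw_floor
  }
  ok <- ok_a & !is.na(ok_b) & ok_b
  if (!any(ok)) {
    span <- function(flag) {
      if (!any(flag, na.rm = TRUE)) return("nowhere on the candidate grid")
      paste0("on [", paste(range(s[which(!is.na(flag) & flag)]),
                           collapse = ", "), "]")
    }
    stop("no sparsity satisfies both criteria: degree criterion holds ",
         span(ok_a), "; small-world criterion holds ", span(ok_b))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which(r$values)[which.max(r$lengths[r$values])]
  sel <- s[starts[best]:ends[best]]
  sparsity_grid(min(sel), max(sel), step)
}

#' Closed-form lower sparsity bound of the degree criterion
#'
#' In the continuous approximation the mean degree of a graph binarized at
#' sparsity S is `S (N - 1)`, so the criterion "mean degree at least
#' `degree_factor * log(N)`" first holds at
#' `S = degree_factor * log(N) / (N - 1)` — about 0.101 for N = 90 with the
#' natural log, matching the adopted lower end of the sweep.
#'
#' @param n_nodes Number of nodes N.
#' @param degree_factor Multiplier of `log(N)` (default 2).
#' @param log_base `"natural"` or `"log10"`.
#' @return The bound as a scalar sparsity.
#' @export
degree_criterion_bound <- function(n_nodes, degree_factor = 2,
                                   log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  logN <- if (log_base == "natural") log(n_nodes) else log10(n_nodes)
  degree_factor * logN / (n_nodes - 1)
}
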