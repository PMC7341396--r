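#' Intra-network connectivity submatrix
#'
#' Principal submatrix of a connectivity matrix restricted to the ROIs of one
#' subnetwork, preserving ROI order.
#'
#' @param C A [correlation_matrix()].
#' @param partition An [rsn_partition()].
#' @param name Network name; the network must have at least 3 ROIs for graph
#'   metrics to be meaningful.
#' @return A `connectivity_matrix` of the network's ROIs.
#' @export
extract_intra_network <- function(C, partition, name) {
  C <- as_connectivity(C)
  idx <- network_indices(partition, name)
  if (length(idx) < 3L)
    stop("network ", name, " has fewer than 3 ROIs")
  structure(C[idx, idx], class = c("connectivity_matrix", "matrix", "array"))
}

#' Mean inter-network functional connectivity
#'
#' Arithmetic mean of the correlation entries over all region pairs with one
#' ROI in each of two distinct subnetworks; symmetric in the pair order.
#'
#' @inheritParams extract_intra_network
#' @param n,m Distinct network names.
#' @return Scalar mean correlation in `[-1, 1]`.
#' @export
inter_network_fc <- function(C, partition, n, m) {
  C <- as_connectivity(C)
  if (identical(n, m))
    stop("n and m must differ; use extract_intra_network for within-network")
  mean(C[network_indices(partition, n), network_indices(partition, m)])
}

#' All pairwise inter-network mean FC values
#'
#' @inheritParams extract_intra_network
#' @return `data.frame` with columns `network_a`, `network_b`, `fc`, one row
#'   per unordered network pair.
#' @export
inter_network_fc_table <- function(C, partition) {
  nets <- partition$networks
  pairs <- utils::combn(nets, 2L)
  data.frame(
    network_a = pairs[1L, ], network_b = pairs[2L, ],
    fc = apply(pairs, 2L, function(p)
      inter_network_fc(C, partition, p[1L], p[2L])))
}

#' Subnetwork metric curves and AUCs over the sparsity sweep
#'
#' For every subnetwork and grid sparsity, evaluates the five global metrics
#' on the subnetwork's binary graph and summarizes each curve by its AUC.
#'
#' Two binarization modes are available.  The default, `"global_restrict"`,
#' thresholds the whole-brain matrix at each sweep sparsity and restricts the
#' resulting binary graph to the subnetwork's ROIs, so a subnetwork's edge
#' count reflects how strongly its regions couple relative to the rest of the
#' brain.  `"own_budget"` instead thresholds each subnetwork's own
#' correlation block with its own edge budget `round(S |n|(|n|-1)/2)`, fixing
#' every subnetwork's density to the sweep value.
#'
#' The small-world reference is matched to the subnetwork's node count at the
#' nominal sweep density by default (`sw_ref = "sweep"`), keeping the
#' reference a fixed function of the grid; `"realized"` matches the
#' subgraph's realized edge count instead, which normalizes density
#' differences away (see the package vignette for the trade-off).
#'
#' Grid points where a small subnetwork has no edges are flagged and excluded
#' from that curve's AUC segment, so the AUC is taken over the valid
#' sub-grid.
#'
#' @inheritParams extract_intra_network
#' @param grid A [sparsity_grid()].
#' @param mode `"global_restrict"` (default) or `"own_budget"`.
#' @param sw_ref `"sweep"` (default) or `"realized"` reference matching.
#' @param rank Edge ranking, see [binarize_at_sparsity()].
#' @param n_random,seed Random-reference ensemble settings.
#' @return List with `curves` (long `data.frame`: `network`, `sparsity`, the
#'   five metric columns, `empty`) and `auc` (`data.frame`: `network`,
#'   `metric`, `auc`).
#' @export
subnetwork_metric_sweep <- function(C, partition, grid,
                                    mode = c("global_restrict", "own_budget"),
                                    sw_ref = c("sweep", "realized"),
                                    rank = "signed",
                                    n_random = 100L, seed = 1L) {
  mode <- match.arg(mode)
  sw_ref <- match.arg(sw_ref)
  C <- as_connectivity(C)
  s <- as_grid(grid)
  nets <- partition$networks
  idxs <- lapply(nets, function(nm) network_indices(partition, nm))
  names(idxs) <- nets
  if (any(lengths(idxs) < 3L))
    stop("every network needs at least 3 ROIs: ",
         paste(nets[lengths(idxs) < 3L], collapse = ", "))
  n <- nrow(C)
  metrics <- c("char", "effi", "clus", "tran", "sw")

  sub_eval <- function(B, nn, S) {
    kb <- sum(B) / 2
    if (kb == 0)  # flagged-empty: excluded from every metric's AUC segment
      return(data.frame(char = NA_real_, effi = NA_real_, clus = NA_real_,
                        tran = NA_real_, sw = NA_real_, empty = TRUE))
    mm <- nn * (nn - 1) / 2
    kref <- if (sw_ref == "sweep") max(1L, floor(S * mm + 0.5)) else kb
    ref <- cached_reference(nn, kref, n_random, seed)
    gm <- global_metrics(B, ref)
    data.frame(char = gm$char, effi = gm$effi, clus = gm$clus, tran = gm$tran,
               sw = gm$sw, empty = FALSE)
  }

  rows <- vector("list", length(nets) * length(s))
  ri <- 0L
  if (mode == "global_restrict") {
    ei <- edge_index(n)
    v <- C[ei$lin]
    ord <- if (identical(rank, "absolute")) order(-abs(v), ei$i, ei$j)
           else order(-v, ei$i, ei$j)
    m <- length(v)
    A <- matrix(0, n, n)
    kprev <- 0L
    for (gi in seq_along(s)) {
      k <- as.integer(floor(s[gi] * m + 0.5))
      if (k > kprev) {
        sel <- ord[(kprev + 1L):k]
        A[ei$lin[sel]] <- 1
        A[(ei$i[sel] - 1L) * n + ei$j[sel]] <- 1
        kprev <- k
      }
      for (nm in nets) {
        B <- A[idxs[[nm]], idxs[[nm]]]
        ri <- ri + 1L
        rows[[ri]] <- cbind(network = nm, sparsity = s[gi],
                            sub_eval(B, length(idxs[[nm]]), s[gi]))
      }
    }
  } else {
    for (nm in nets) {
      Cn <- C[idxs[[nm]], idxs[[nm]]]
      for (gi in seq_along(s)) {
        g <- suppressWarnings(binarize_at_sparsity(
          structure(Cn, class = c("connectivity_matrix", "matrix", "array")),
          s[gi], rank = rank))
        ri <- ri + 1L
        rows[[ri]] <- cbind(network = nm, sparsity = s[gi],
                            sub_eval(g$adjacency, nrow(Cn), s[gi]))
      }
    }
  }
  curves <- do.call(rbind, rows)
  auc <- do.call(rbind, lapply(nets, function(nm) {
    cv <- curves[curves$network == nm, ]
    cv <- cv[order(cv$sparsity), ]
    data.frame(network = nm, metric = metrics,
               auc = vapply(metrics, function(mt)
                 metric_auc(cv[[mt]], cv$sparsity), 0))
  }))
  rownames(auc) <- NULL
  list(curves = curves, auc = auc)
}
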