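#' ROI-to-subnetwork partition
#'
#' A resting-state-network (RSN) partition assigns every ROI index to exactly
#' one named subnetwork.  The conventional six networks are the default mode
#' (DMN), attention (ATT), subcortical (SUB), auditory (AUD), visual (VIS) and
#' sensorimotor (SEN) networks.
#'
#' @param assignment Character vector of length `n_rois`; element `i` is the
#'   network name of ROI `i` (1-based ROI indices).
#' @param networks Optional character vector fixing the network order; defaults
#'   to the order of first appearance in `assignment`.
#' @return An object of class `rsn_partition` with fields `networks`,
#'   `assignment` and `n_rois`.
#' @examples
#' p <- rsn_partition(rep(c("DMN", "VIS"), each = 5))
#' network_indices(p, "VIS")
#' @export
rsn_partition <- function(assignment, networks = NULL) {
  assignment <- as.character(assignment)
  if (length(assignment) < 1L || anyNA(assignment))
    stop("every ROI must be assigned to a network")
  if (is.null(networks)) networks <- unique(assignment)
  if (!setequal(networks, unique(assignment)))
    stop("'networks' must list exactly the networks present in 'assignment'")
  sizes <- table(assignment)
  if (any(sizes < 1L)) stop("every network must be nonempty")
  structure(
    list(networks = as.character(networks), assignment = assignment,
         n_rois = length(assignment)),
    class = "rsn_partition")
}

#' @export
print.rsn_partition <- function(x, ...) {
  cat("RSN partition:", x$n_rois, "ROIs in", length(x$networks), "networks\n")
  sz <- vapply(x$networks, function(n) sum(x$assignment == n), 0L)
  print(sz)
  invisible(x)
}

#' ROI indices belonging to one network
#'
#' @param partition An [rsn_partition()].
#' @param name Network name.
#' @return Integer vector of 1-based ROI indices.
#' @export
network_indices <- function(partition, name) {
  stopifnot(inherits(partition, "rsn_partition"))
  if (!name %in% partition$networks)
    stop("unknown network: ", name)
  which(partition$assignment == name)
}

#' Default six-network partition
#'
#' Contiguous index blocks with sizes mirroring typical AAL-90 RSN
#' assignments: DMN 22, ATT 14, SUB 12, AUD 8, VIS 14, SEN 20 for 90 ROIs
#' (other ROI counts are split proportionally, each network at least 3 ROIs).
#' This is a synthetic stand-in for a real atlas-to-network mapping, which
#' must be supplied for real data; the same assignment ships as
#' `extdata/synthetic_rsn_partition_90.tsv`.
#'
#' @param n_rois Number of ROIs (default 90).
#' @return An [rsn_partition()].
#' @export
default_rsn_partition <- function(n_rois = 90L) {
  base <- c(DMN = 22L, ATT = 14L, SUB = 12L, AUD = 8L, VIS = 14L, SEN = 20L)
  if (n_rois == 90L) {
    sizes <- base
  } else {
    if (n_rois < 6L * 3L)
      stop("n_rois must be at least 18 for the six-network default partition")
    sizes <- floor(base / 90 * n_rois)  # names kept from `base`
    sizes[sizes < 3L] <- 3L
    i <- 1L
    while (sum(sizes) != n_rois) {  # distribute the rounding remainder
      j <- ((i - 1L) %% 6L) + 1L
      d <- sign(n_rois - sum(sizes))
      if (d > 0L || sizes[j] > 3L) sizes[j] <- sizes[j] + d
      i <- i + 1L
    }
  }
  rsn_partition(rep(names(sizes), times = sizes), networks = names(sizes))
}

#' Read / write a partition file
#'
#' Tab-separated with header `roi_index`, `roi_name`, `network`; `roi_index`
#' is 1-based and must cover `1..N` exactly once.
#'
#' @param path File path.
#' @return `read_rsn_partition` returns an [rsn_partition()];
#'   `write_rsn_partition` returns `path` invisibly.
#' @export
read_rsn_partition <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_index", "roi_name", "network")
  if (!all(need %in% names(d)))
    stop("partition file must have columns: ", paste(need, collapse = ", "))
  idx <- as.integer(d$roi_index)
  if (!setequal(idx, seq_len(nrow(d))) || anyDuplicated(idx))
    stop("roi_index must cover 1..N exactly once")
  rsn_partition(d$network[order(idx)])
}

#' @param partition An [rsn_partition()].
#' @rdname read_rsn_partition
#' @export
write_rsn_partition <- function(partition, path) {
  stopifnot(inherits(partition, "rsn_partition"))
  d <- data.frame(
    roi_index = seq_len(partition$n_rois),
    roi_name = sprintf("ROI%03d", seq_len(partition$n_rois)),
    network = partition$assignment)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
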