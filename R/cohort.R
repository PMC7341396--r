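#' Configuration for the synthetic four-stage cohort generator
#'
#' The generator draws each subject's ROI time series as zero-mean
#' multivariate-Gaussian samples with a stage-dependent block covariance:
#' ROIs sharing a subnetwork correlate at `within_r[network, stage]`, ROIs in
#' different subnetworks at `between_r`.  Across the ordered stages, networks
#' tagged `"inversion"` follow a rise-then-fall (peak at EMCI) within-network
#' correlation trajectory and networks tagged `"decline"` a strictly
#' decreasing one — the two trajectory shapes whose recovery the downstream
#' analysis is designed to test.  MMSE scores are Gaussian per stage, rounded
#' and clipped to `[0, 30]`.
#'
#' Defaults encode the study conditions: 90 ROIs, 130 retained volumes
#' (140 acquired minus 10 discarded), group sizes NC 35 / EMCI 37 / LMCI 33 /
#' AD 25, MMSE means and SDs per stage, inversion trajectories
#' `(0.30, 0.45, 0.35, 0.20)` for AUD/DMN/VIS/SUB and decline trajectories
#' `(0.45, 0.38, 0.30, 0.22)` for SEN/ATT.
#'
#' @param n_rois Number of ROIs (columns).
#' @param n_timepoints Time points per subject (rows); minimum 30.
#' @param group_sizes Named integer vector over [ad_stages()].
#' @param partition An [rsn_partition()] over `n_rois` ROIs.
#' @param within_r Numeric matrix, networks x stages, of target within-network
#'   correlations in `[0, 1)`.
#' @param between_r Baseline between-network correlation in `[0, 1)`.
#' @param network_pattern Named character vector tagging each network
#'   `"inversion"`, `"decline"` or `"none"`; used to validate the `within_r`
#'   trajectory shapes (`"none"` imposes no shape, e.g. for null cohorts with
#'   stage-constant connectivity).
#' @param mmse_params 2-column matrix (mean, sd) with one row per stage.
#' @param ar1 Optional AR(1) coefficient for temporal autocorrelation of the
#'   innovations; default 0 (off) so the correlation targets are exact.
#' @param seed Integer seed making [generate_cohort()] reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_rois = 90L,
                          n_timepoints = 130L,
                          group_sizes = c(NC = 35L, EMCI = 37L, LMCI = 33L, AD = 25L),
                          partition = default_rsn_partition(n_rois),
                          within_r = default_within_r(),
                          between_r = 0.10,
                          network_pattern = default_network_pattern(),
                          mmse_params = default_mmse_params(),
                          ar1 = 0,
                          seed = 1L) {
  stages <- ad_stages()
  stopifnot(n_rois >= 1L, n_timepoints >= 30L)
  if (!all(stages %in% names(group_sizes)))
    stop("group_sizes must be named over ", paste(stages, collapse = ", "))
  group_sizes <- group_sizes[stages]
  if (any(group_sizes < 0L)) stop("group sizes must be nonnegative")
  stopifnot(inherits(partition, "rsn_partition"))
  if (partition$n_rois != n_rois)
    stop("partition covers ", partition$n_rois, " ROIs but n_rois = ", n_rois)
  if (!is.matrix(within_r) || !all(stages %in% colnames(within_r)))
    stop("within_r must be a matrix with stage columns ",
         paste(stages, collapse = ", "))
  if (!all(partition$networks %in% rownames(within_r)))
    stop("within_r must have a row per network of the partition")
  within_r <- within_r[partition$networks, stages, drop = FALSE]
  if (any(within_r < 0 | within_r >= 1)) stop("within_r values must be in [0, 1)")
  if (between_r < 0 || between_r >= 1) stop("between_r must be in [0, 1)")
  if (!all(partition$networks %in% names(network_pattern)))
    stop("network_pattern must tag every network")
  if (!all(network_pattern %in% c("inversion", "decline", "none")))
    stop("network_pattern tags must be 'inversion', 'decline' or 'none'")
  for (net in partition$networks) {
    r <- within_r[net, ]
    if (network_pattern[[net]] == "none") {
      next  # untagged networks (e.g. null cohorts) carry no shape constraint
    } else if (network_pattern[[net]] == "inversion") {
      ok <- r[2] > r[1] && r[2] > r[3] && r[3] > r[4]
      if (!ok) stop("within_r trajectory for inversion network ", net,
                    " must rise to a peak at EMCI then fall")
    } else {
      if (!all(diff(r) < 0))
        stop("within_r trajectory for decline network ", net,
             " must be strictly decreasing")
    }
  }
  if (!is.matrix(mmse_params) || !all(stages %in% rownames(mmse_params)) ||
      ncol(mmse_params) < 2L)
    stop("mmse_params must be a (stage x c(mean, sd)) matrix")
  mmse_params <- mmse_params[stages, 1:2, drop = FALSE]
  colnames(mmse_params) <- c("mean", "sd")
  if (any(mmse_params[, "sd"] < 0)) stop("MMSE sd must be nonnegative")
  stopifnot(ar1 >= 0, ar1 < 1)
  structure(
    list(n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
         group_sizes = group_sizes, partition = partition,
         within_r = within_r, between_r = between_r,
         network_pattern = network_pattern[partition$networks],
         mmse_params = mmse_params, ar1 = ar1, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_within_r <- function() {
  inv <- c(0.30, 0.45, 0.35, 0.20)
  dec <- c(0.45, 0.38, 0.30, 0.22)
  m <- rbind(DMN = inv, ATT = dec, SUB = inv, AUD = inv, VIS = inv, SEN = dec)
  colnames(m) <- ad_stages()
  m
}

#' @rdname cohort_config
#' @export
default_network_pattern <- function() {
  c(DMN = "inversion", ATT = "decline", SUB = "inversion",
    AUD = "inversion", VIS = "inversion", SEN = "decline")
}

#' @rdname cohort_config
#' @export
default_mmse_params <- function() {
  m <- rbind(NC = c(28.89, 1.21), EMCI = c(28.08, 1.74),
             LMCI = c(27.85, 1.64), AD = c(22.72, 2.41))
  colnames(m) <- c("mean", "sd")
  m
}

#' Stage covariance matrix implied by a cohort configuration
#'
#' Entry (i, j) is `within_r[network(i), stage]` when ROIs i and j share a
#' network and `between_r` otherwise, with unit diagonal.  The matrix is
#' checked for positive definiteness; a non-PD matrix is repaired with
#' [Matrix::nearPD()] (flagged via the `"repaired"` attribute and a warning),
#' and a hard error naming the offending network blocks is raised if repair
#' fails.
#'
#' @param config A [cohort_config()].
#' @param stage One of [ad_stages()].
#' @return N x N positive-definite covariance matrix with unit diagonal.
#' @export
build_stage_covariance <- function(config, stage) {
  stopifnot(inherits(config, "cohort_config"))
  stage <- match.arg(stage, ad_stages())
  n <- config$n_rois
  sigma <- matrix(config$between_r, n, n)
  for (net in config$partition$networks) {
    idx <- network_indices(config$partition, net)
    sigma[idx, idx] <- config$within_r[net, stage]
  }
  diag(sigma) <- 1
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    rep <- try(as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat), silent = TRUE)
    if (inherits(rep, "try-error") ||
        min(eigen(rep, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      stop("stage covariance for ", stage, " is not positive definite; ",
           "offending blocks: ",
           paste(sprintf("%s(r=%.3f)", config$partition$networks,
                         config$within_r[, stage]), collapse = ", "))
    }
    warning("stage covariance for ", stage,
            " repaired to nearest positive-definite matrix")
    attr(rep, "repaired") <- TRUE
    dimnames(rep) <- NULL
    return(rep)
  }
  attr(sigma, "repaired") <- FALSE
  sigma
}

#' One subject's ROI time series
#'
#' @param subject_id Character id.
#' @param stage One of [ad_stages()].
#' @param mmse Integer MMSE score in `[0, 30]`.
#' @param data T x N numeric matrix (time points x ROIs), no missing values,
#'   every column with nonzero variance, T >= 30.
#' @param min_timepoints Minimum T accepted (correlations need a reasonable
#'   sample).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, stage, mmse, data, min_timepoints = 30L) {
  stage <- match.arg(stage, ad_stages())
  data <- as.matrix(data)
  if (anyNA(data)) stop("time series contains missing values")
  if (nrow(data) < min_timepoints)
    stop("need at least ", min_timepoints, " time points, got ", nrow(data))
  v <- apply(data, 2L, stats::var)
  if (any(v == 0))
    stop("ROI(s) with zero variance: ", paste(which(v == 0), collapse = ", "))
  mmse <- as.integer(round(mmse))
  if (mmse < 0L || mmse > 30L) stop("MMSE must be in [0, 30]")
  structure(list(subject_id = as.character(subject_id), stage = stage,
                 mmse = mmse, data = unname(data)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s  stage=%s  MMSE=%d  %d x %d\n",
              x$subject_id, x$stage, x$mmse, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `group_sizes[stage]` subjects per stage: each subject is
#' `n_timepoints` rows sampled from the zero-mean Gaussian with the stage
#' covariance of [build_stage_covariance()] (via its Cholesky factor), plus a
#' rounded, clipped Gaussian MMSE score.  Fully reproducible under the
#' configuration seed, which is applied locally without disturbing the
#' caller's RNG state.
#'
#' @param config A [cohort_config()].
#' @return List of [roi_timeseries()] objects (class `stage_cohort`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  stages <- ad_stages()
  chols <- lapply(stages, function(st)
    chol(build_stage_covariance(config, st)))
  names(chols) <- stages
  Tn <- config$n_timepoints
  N <- config$n_rois
  phi <- config$ar1
  out <- with_local_seed(config$seed, {
    res <- list()
    for (st in stages) {
      for (i in seq_len(config$group_sizes[[st]])) {
        z <- matrix(stats::rnorm(Tn * N), Tn, N)
        if (phi > 0) {  # AR(1) innovations; unit marginal variance preserved
          z <- apply(z, 2L, function(col)
            as.numeric(stats::filter(col * sqrt(1 - phi^2), phi,
                                     method = "recursive")))
        }
        x <- z %*% chols[[st]]
        m <- config$mmse_params[st, ]
        mmse <- min(30L, max(0L, as.integer(round(stats::rnorm(1, m["mean"], m["sd"])))))
        res[[length(res) + 1L]] <- roi_timeseries(
          sprintf("%s_%03d", st, i), st, mmse, x)
      }
    }
    res
  })
  structure(out, class = c("stage_cohort", "list"))
}

#' @export
print.stage_cohort <- function(x, ...) {
  st <- vapply(x, function(s) s$stage, "")
  cat("<stage_cohort>", length(x), "subjects:",
      paste(sprintf("%s=%d", ad_stages(), table(factor(st, ad_stages()))),
            collapse = " "), "\n")
  invisible(x)
}

#' Write / read a cohort as plain text
#'
#' Each subject becomes one header-less TSV of T rows x N columns (full
#' `%.17g` precision, so matrices round-trip to numerical equality), plus a
#' manifest TSV with columns `subject_id`, `stage`, `mmse`, `path` (relative
#' to the manifest).
#'
#' @param cohort List of [roi_timeseries()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the manifest path invisibly; `read_cohort`
#'   returns a `stage_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  ids <- vapply(cohort, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    paths[i] <- paste0(s$subject_id, ".tsv")
    lines <- apply(s$data, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, file.path(dir, paths[i]))
  }
  man <- data.frame(
    subject_id = ids,
    stage = vapply(cohort, function(s) s$stage, ""),
    mmse = vapply(cohort, function(s) s$mmse, 0L),
    path = paths)
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @param manifest Path to a manifest written by [write_cohort()].
#' @rdname write_cohort
#' @export
read_cohort <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character"))
  base <- dirname(manifest)
  out <- lapply(seq_len(nrow(man)), function(i) {
    x <- as.matrix(utils::read.table(file.path(base, man$path[i]), sep = "\t"))
    roi_timeseries(man$subject_id[i], man$stage[i], man$mmse[i], x)
  })
  structure(out, class = c("stage_cohort", "list"))
}
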