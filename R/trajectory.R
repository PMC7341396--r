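#' Metric orientation for trajectory classification
#'
#' Characteristic path length is a cost metric: it falls as connectivity
#' strengthens, so its raw trajectory mirrors that of the cohesion metrics.
#' Trajectory classification multiplies each metric by its orientation so one
#' pattern vocabulary (inversion / decline) applies to all five.
#'
#' @return Named vector of +1/-1 per metric.
#' @export
metric_orientation <- function() {
  c(char = -1, effi = 1, clus = 1, tran = 1, sw = 1)
}

#' Classify a four-stage trajectory into an evolving pattern
#'
#' Given group means at the ordered stages NC, EMCI, LMCI, AD, assigns one of
#' four labels:
#' * `TEMPERATURE_INVERSION` — rises from NC beyond `tol`, peaks at EMCI,
#'   then declines through LMCI to AD (each downward step allowed to reverse
#'   by at most `tol`);
#' * `MONOTONOUS_DECLINE` — every step downward within `tol` slack and a net
#'   NC-to-AD fall beyond `tol`;
#' * `U_SHAPED` — interior minimum (EMCI or LMCI) with falls into and rises
#'   out of it beyond `tol`;
#' * `OTHER` — anything else (including flat trajectories).
#'
#' The default tolerance is noise-scaled: `tol_factor` (0.25) times the
#' pooled standard error of the four stage means, making the visual
#' classification rule quantitative and testable; pass `tol` directly for an
#' absolute tolerance.
#'
#' @param values Four finite stage means (NC, EMCI, LMCI, AD order).
#' @param dispersion Optional four standard errors of the stage means, used
#'   for the default tolerance.
#' @param tol Absolute tolerance; overrides the noise-scaled default.
#' @param tol_factor Multiplier of the pooled SE (default 0.25).
#' @return List of class `pattern_label` with `label`, `peak_stage` (the
#'   stage name for inversion patterns, otherwise `NA`), and `tol`.
#' @examples
#' classify_pattern(c(1.0, 1.5, 1.2, 0.8))$label  # TEMPERATURE_INVERSION
#' classify_pattern(c(4, 3, 2, 1))$label          # MONOTONOUS_DECLINE
#' @export
classify_pattern <- function(values, dispersion = NULL, tol = NULL,
                             tol_factor = 0.25) {
  if (length(values) != 4L || !all(is.finite(values)))
    stop("need 4 finite stage values")
  if (is.null(tol)) {
    tol <- if (is.null(dispersion)) 0
           else tol_factor * sqrt(mean(dispersion^2))
  }
  if (tol < 0) stop("tol must be nonnegative")
  v <- as.numeric(values)
  label <- "OTHER"
  peak <- NA_character_
  if (v[2] - v[1] > tol && which.max(v) == 2L &&
      v[2] - v[3] > -tol && v[3] - v[4] > -tol) {
    label <- "TEMPERATURE_INVERSION"
    peak <- "EMCI"
  } else if (v[1] - v[2] > -tol && v[2] - v[3] > -tol && v[3] - v[4] > -tol &&
             v[1] - v[4] > tol) {
    label <- "MONOTONOUS_DECLINE"
  } else {
    am <- which.min(v)
    if (am %in% c(2L, 3L) && v[4] - v[am] > tol && v[1] - v[am] > tol)
      label <- "U_SHAPED"
  }
  structure(list(label = label, peak_stage = peak, tol = tol),
            class = "pattern_label")
}

#' Stage trajectories and pattern labels for subnetwork metric AUCs
#'
#' Aggregates a long per-subject AUC table into per-(network, metric) stage
#' means and standard errors, applies the metric orientation of
#' [metric_orientation()], and classifies each trajectory with
#' [classify_pattern()].
#'
#' @param auc_table `data.frame` with columns `subject_id`, `stage`,
#'   `network`, `metric`, `auc`.
#' @param tol,tol_factor Passed to [classify_pattern()].
#' @return `data.frame` with one row per (network, metric): stage means and
#'   SEs, `label`, `peak_stage`.
#' @export
trajectory_table <- function(auc_table, tol = NULL, tol_factor = 0.25) {
  stages <- ad_stages()
  orient <- metric_orientation()
  need <- c("subject_id", "stage", "network", "metric", "auc")
  if (!all(need %in% names(auc_table)))
    stop("auc_table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (net in unique(auc_table$network)) {
    for (mt in unique(auc_table$metric)) {
      d <- auc_table[auc_table$network == net & auc_table$metric == mt, ]
      mu <- se <- stats::setNames(numeric(4L), stages)
      for (st in stages) {
        x <- d$auc[d$stage == st]
        x <- x[is.finite(x)]
        mu[st] <- if (length(x)) mean(x) else NA_real_
        se[st] <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                  else NA_real_
      }
      o <- if (mt %in% names(orient)) orient[[mt]] else 1
      cl <- if (all(is.finite(mu))) {
        disp <- se
        disp[!is.finite(disp)] <- 0  # singleton stages contribute no noise
        classify_pattern(o * mu, dispersion = disp, tol = tol,
                         tol_factor = tol_factor)
      } else {  # a stage without usable data cannot be classified
        list(label = "OTHER", peak_stage = NA_character_, tol = NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        network = net, metric = mt,
        mean_NC = mu[1L], mean_EMCI = mu[2L], mean_LMCI = mu[3L],
        mean_AD = mu[4L],
        se_NC = se[1L], se_EMCI = se[2L], se_LMCI = se[3L], se_AD = se[4L],
        label = cl$label, peak_stage = cl$peak_stage, tol = cl$tol)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group subnetworks by their majority evolving pattern
#'
#' Each network's pattern is the majority label across its five metric
#' trajectories; ties yield `OTHER`.  Networks sharing a pattern form one
#' "homogeneous evolving" group.
#'
#' @param trajectories Output of [trajectory_table()] (or any `data.frame`
#'   with `network`, `metric`, `label`).
#' @return List with `network_label` (named vector: majority label per
#'   network), `groups` (list label -> networks) and `labels` (the input
#'   label matrix, networks x metrics).
#' @export
group_homogeneous <- function(trajectories) {
  nets <- unique(trajectories$network)
  mets <- unique(trajectories$metric)
  lab <- matrix(NA_character_, length(nets), length(mets),
                dimnames = list(nets, mets))
  for (r in seq_len(nrow(trajectories)))
    lab[trajectories$network[r], trajectories$metric[r]] <-
      trajectories$label[r]
  if (anyNA(lab)) stop("missing metric labels for some network")
  majority <- function(l) {
    tb <- table(l)
    top <- names(tb)[tb == max(tb)]
    if (length(top) > 1L) "OTHER" else top
  }
  nl <- apply(lab, 1L, majority)
  groups <- split(names(nl), nl)
  list(network_label = nl, groups = groups, labels = lab)
}
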