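#' Nonparametric permutation test on a group difference in means
#'
#' The statistic is `mean(a) - mean(b)`.  The null distribution is built by
#' randomly reallocating all values into two groups of the original sizes.
#' The default two-tailed mode counts `|null| >= |observed|`; the one-tailed
#' mode is directional on the sign of the observed difference, counting null
#' draws at least as extreme on the observed side — note that choosing the
#' direction from the data doubles the effective type-I rate, so the
#' directional mode is only calibrated when the direction is prespecified.
#' Both use the add-one correction `(1 + count) / (B + 1)`, so p is never
#' exactly zero.  Reproducible under `seed` (applied locally).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param n_permutations Number of random relabelings (default 10000).
#' @param tail `"two_tailed"` (default) or `"one_tailed"` (directional).
#' @param seed Optional integer seed.
#' @return List with `observed_diff`, `p_value`, `n_permutations`, `tail`.
#' @export
permutation_test <- function(a, b, n_permutations = 10000L,
                             tail = c("two_tailed", "one_tailed"),
                             seed = NULL) {
  tail <- match.arg(tail)
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 values")
  stopifnot(n_permutations >= 100L)
  obs <- mean(a) - mean(b)
  null <- permutation_null(rbind(c(a, b)), length(a), n_permutations, seed)[1L, ]
  p <- perm_pvalue(obs, null, tail)
  list(observed_diff = obs, p_value = p,
       n_permutations = as.integer(n_permutations), tail = tail)
}

## shared null machinery: X is features x subjects (group A columns first);
## returns features x B matrix of null mean differences.  One permutation
## matrix serves every feature of a family, as the relabeling is of subjects.
permutation_null <- function(X, n_a, B, seed = NULL) {
  n <- ncol(X)
  n_b <- n - n_a
  W <- with_local_seed(seed, {
    W <- matrix(-1 / n_b, n, B)
    for (b in seq_len(B)) W[sample.int(n, n_a), b] <- 1 / n_a
    W
  })
  X %*% W
}

perm_pvalue <- function(obs, null, tail) {
  if (tail == "two_tailed") {
    (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)
  } else if (obs >= 0) {
    (1 + sum(null >= obs)) / (length(null) + 1)
  } else {
    (1 + sum(null <= obs)) / (length(null) + 1)
  }
}

#' Permutation tests for many features of one family
#'
#' Applies [permutation_test()]'s statistic to every row of a feature matrix,
#' sharing one set of subject relabelings across the family (the relabeling
#' permutes subjects, not features), then corrects with [bh_fdr()].
#'
#' @param X Numeric matrix, features x subjects.
#' @param n_a Number of leading columns belonging to group A.
#' @param n_permutations,tail,seed As in [permutation_test()].
#' @param alpha FDR level.
#' @return `data.frame` with `observed_diff`, `p`, `q`, `reject` per row of
#'   `X`.
#' @export
permutation_test_many <- function(X, n_a, n_permutations = 10000L,
                                  tail = "two_tailed", seed = NULL,
                                  alpha = 0.05) {
  X <- rbind(X)
  obs <- rowMeans(X[, seq_len(n_a), drop = FALSE]) -
    rowMeans(X[, -seq_len(n_a), drop = FALSE])
  null <- permutation_null(X, n_a, n_permutations, seed)
  p <- vapply(seq_along(obs), function(i)
    perm_pvalue(obs[i], null[i, ], tail), 0)
  fdr <- bh_fdr(p, alpha)
  data.frame(observed_diff = obs, p = p, q = fdr$q, reject = fdr$reject)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values `q_(i) = min_{j >= i} m p_(j) / j` (capped at 1) and
#' rejection flags `q <= alpha`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return List with `q` and logical `reject`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so perfect correlations stay
#' finite.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

## vectorized Welch two-sample t-test; returns t, df, two-sided p
welch_t <- function(xbar, ybar, vx, vy, nx, ny) {
  se2 <- vx / nx + vy / ny
  t <- (xbar - ybar) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Edge-wise two-sample comparison of functional connectivity
#'
#' For every unordered ROI pair, compares the (optionally Fisher
#' z-transformed) correlations between two groups with a Welch two-sample
#' t-test, then corrects all edges as one BH-FDR family.  Edges with zero
#' variance in both groups are flagged and assigned `p = 1`.
#'
#' @param group_a,group_b Lists of connectivity matrices (one per subject),
#'   at least 2 subjects each.
#' @param fisher_z Transform correlations before testing (default `TRUE`).
#' @param alpha FDR level.
#' @return `data.frame` with columns `i`, `j`, `observed_diff` (group A minus
#'   group B mean on the tested scale), `t`, `df`, `p`, `q`, `reject`,
#'   `degenerate`.
#' @export
edge_t_test <- function(group_a, group_b, fisher_z = TRUE, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 subjects per group")
  n <- nrow(as_connectivity(group_a[[1L]]))
  ei <- edge_index(n)
  pull <- function(lst) vapply(lst, function(C) as_connectivity(C)[ei$lin],
                               numeric(length(ei$lin)))
  XA <- pull(group_a)
  XB <- pull(group_b)
  if (fisher_z) { XA <- fisher_z(XA); XB <- fisher_z(XB) }
  ma <- rowMeans(XA); mb <- rowMeans(XB)
  va <- apply(XA, 1L, stats::var); vb <- apply(XB, 1L, stats::var)
  degen <- va == 0 & vb == 0
  wt <- welch_t(ma, mb, pmax(va, 1e-300), pmax(vb, 1e-300),
                ncol(XA), ncol(XB))
  p <- wt$p
  t <- wt$t
  t[degen] <- 0
  p[degen] <- 1
  fdr <- bh_fdr(p, alpha)
  data.frame(i = ei$i, j = ei$j, observed_diff = ma - mb, t = t, df = wt$df,
             p = p, q = fdr$q, reject = fdr$reject, degenerate = degen)
}

#' Pearson correlation between a property and MMSE scores
#'
#' @param values Per-subject property values (>= 4 paired observations).
#' @param mmse Per-subject MMSE scores.
#' @return List with `r`, `p` (two-sided, t-distribution with n-2 df) and
#'   `n`.
#' @export
mmse_correlation <- function(values, mmse) {
  ok <- is.finite(values) & is.finite(mmse)
  values <- values[ok]; mmse <- mmse[ok]
  if (length(values) < 4L) stop("need at least 4 paired observations")
  if (stats::var(values) == 0 || stats::var(mmse) == 0)
    stop("inputs must be nonconstant")
  ct <- stats::cor.test(values, mmse, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}
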