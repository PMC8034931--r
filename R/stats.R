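#' Subsampled Mann-Whitney test with Fisher combination
#'
#' Compares two groups with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test, capping each group at `cap` samples per test and repeating over
#' `n_resamples` random subsamples; the per-resample p-values are combined
#' with Fisher's method (`X = -2 sum ln p_i` referred to chi-square with
#' `2 n_resamples` degrees of freedom). Capping keeps p-values comparable
#' across comparisons of very different sizes.
#'
#' When both groups already fit under the cap every resample is the full
#' group, all p-values coincide and the combination is degenerate; the
#' result is still reported (that is how the procedure is defined) with
#' `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric samples for the two groups.
#' @param cap Maximum subsample size per group per test (default 500).
#' @param n_resamples Number of random subsamples (default 100).
#' @param seed Integer seed for the resampling.
#' @return A `group_comparison` list: `p_combined`, `p_values` (per
#'   resample), `statistic` (the chi-square statistic X), `df`, `n_a`,
#'   `n_b`, `cap`, `n_resamples`, `degenerate`, `seed`.
#' @export
mannwhitney_fisher <- function(values_a, values_b, cap = 500,
                               n_resamples = 100, seed = 1L) {
  if (length(values_a) < 1 || length(values_b) < 1) {
    stop("both groups must be non-empty")
  }
  set.seed(seed)
  na <- length(values_a); nb <- length(values_b)
  ka <- min(na, cap); kb <- min(nb, cap)
  degenerate <- na <= cap && nb <= cap
  use_exact <- ka <= 20 && kb <= 20
  pvals <- vapply(seq_len(n_resamples), function(i) {
    a <- if (na > cap) values_a[sample.int(na, ka)] else values_a
    b <- if (nb > cap) values_b[sample.int(nb, kb)] else values_b
    suppressWarnings(stats::wilcox.test(
      a, b, alternative = "two.sided",
      exact = use_exact, correct = TRUE
    )$p.value)
  }, numeric(1))
  X <- -2 * sum(log(pvals))
  df <- 2L * n_resamples
  p_comb <- stats::pchisq(X, df = df, lower.tail = FALSE)
  if (degenerate && n_resamples > 1) {
    warning("both groups are at or below the cap: the ", n_resamples,
            " resamples are identical and the Fisher combination is degenerate")
  }
  structure(list(p_combined = p_comb, p_values = pvals, statistic = X,
                 df = df, n_a = na, n_b = nb, cap = cap,
                 n_resamples = n_resamples, degenerate = degenerate,
                 seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> n = %d vs %d (cap %d, %d resamples)\n  Fisher X = %.2f on %d df, p_combined = %.3g%s\n",
    x$n_a, x$n_b, x$cap, x$n_resamples, x$statistic, x$df, x$p_combined,
    if (x$degenerate) " [degenerate: groups under cap]" else ""))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from midranks (tie-corrected), i.e.
#' the Mann-Whitney U statistic scaled by `n1 * n0`: the probability that a
#' random positive scores above a random negative (ties counting half).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 is the positive
#'   class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(scores)   # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation with guard rails
#'
#' Standard product-moment correlation; errors on degenerate input rather
#' than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}
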