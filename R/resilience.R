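#' Autocorrelation function of a daily BAA track
#'
#' Biased normalised estimator
#' `C(k) = sum (x_t - xbar)(x_{t+k} - xbar) / sum (x_t - xbar)^2`,
#' with both the mean and the denominator taken over valid days and lag-k
#' products restricted to pairs of valid days. `C(0) = 1` by construction.
#'
#' @param track A `baa_track` (or plain numeric vector).
#' @param max_lag Largest lag in days.
#' @return An `acf_estimate` list: `lags` (0..max_lag), `values`,
#'   `n_pairs` per lag.
#' @export
baa_autocorrelation <- function(track, max_lag = 28) {
  if (is.numeric(track)) track <- baa_track(track)
  x <- track$baa
  valid <- track$valid
  if (sum(valid) < 30) stop("need at least 30 valid days, got ", sum(valid))
  xm <- mean(x[valid])
  xc <- ifelse(valid, x - xm, 0)
  denom <- sum(xc[valid]^2)
  if (denom == 0) stop("constant track: zero variance")
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  vals <- numeric(max_lag + 1L)
  npairs <- integer(max_lag + 1L)
  for (k in 0:max_lag) {
    i <- seq_len(n - k)
    pair_ok <- valid[i] & valid[i + k]
    vals[k + 1L] <- sum(xc[i][pair_ok] * xc[i + k][pair_ok]) / denom
    npairs[k + 1L] <- sum(pair_ok)
  }
  vals[1L] <- 1
  structure(list(lags = 0:max_lag, values = vals, n_pairs = npairs),
            class = "acf_estimate")
}

#' Fit a relaxation time to an autocorrelation function
#'
#' Fits `C(k) = exp(-k/tau)` by least squares of `ln C(k)` on `k` through
#' the origin (the model forces `C(0) = 1`), using the initial run of
#' strictly positive ACF values inside `fit_range` (the fit stops at the
#' first zero crossing, where the log is undefined and the exponential
#' model has no support). The recovery rate is `1/tau` expressed per week.
#'
#' @param acf An `acf_estimate` from [baa_autocorrelation()].
#' @param fit_range Lags (days) eligible for the fit; default 1-28.
#' @param cutoff_days Resilience cutoff: recovery time above this flags the
#'   subject non-resilient. Default 21 days (3 weeks).
#' @param r2_threshold Fit quality below which the estimate is flagged
#'   unreliable.
#' @return A `resilience_estimate` list: `tau` (days), `rate` (1/week),
#'   `fit_r2`, `n_days_used`, `resilient`, `reliable`.
#' @export
fit_relaxation_time <- function(acf, fit_range = 1:28, cutoff_days = 21,
                                r2_threshold = 0.3) {
  in_range <- which(acf$lags %in% fit_range & acf$lags > 0)
  in_range <- in_range[order(acf$lags[in_range])]
  npos <- match(TRUE, acf$values[in_range] <= 0, nomatch = length(in_range) + 1L) - 1L
  sel <- in_range[seq_len(npos)]
  if (length(sel) < 3) {
    stop("tau unresolved (fast decay): fewer than 3 positive ACF values ",
         "before the first zero crossing")
  }
  k <- acf$lags[sel]
  y <- log(acf$values[sel])
  slope <- sum(k * y) / sum(k^2)          # through-origin least squares
  ss_res <- sum((y - slope * k)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  if (slope >= 0) {
    tau <- Inf
  } else {
    tau <- -1 / slope
  }
  structure(list(
    tau = tau,
    rate = 7 / tau,                       # per week
    fit_r2 = r2,
    n_days_used = length(k),
    resilient = is.finite(tau) && tau <= cutoff_days,
    reliable = r2 >= r2_threshold && is.finite(tau)
  ), class = "resilience_estimate")
}

#' Estimate a relaxation time directly from a BAA track
#'
#' Convenience composition of [baa_autocorrelation()] and
#' [fit_relaxation_time()].
#'
#' @inheritParams baa_autocorrelation
#' @inheritParams fit_relaxation_time
#' @return A `resilience_estimate`.
#' @export
estimate_resilience <- function(track, max_lag = 28, fit_range = 1:28,
                                cutoff_days = 21) {
  fit_relaxation_time(baa_autocorrelation(track, max_lag),
                      fit_range = fit_range, cutoff_days = cutoff_days)
}

bin_ages <- function(ages, width) {
  lo <- floor(min(ages) / width) * width
  centers <- lo + width * (floor((ages - lo) / width)) + width / 2
  centers
}

#' Cohort trend of recovery rate versus age
#'
#' Averages individual recovery rates within age bins, regresses the bin
#' mean rate on bin-centre age (weighted by bin size), and extrapolates the
#' declining trend to its zero crossing — the age at which the population
#' mean resilience would vanish. A bootstrap over individuals provides a
#' confidence interval for the zero-crossing age.
#'
#' @param estimates Data.frame with columns `age` and `rate` (1/week), one
#'   row per subject (e.g. built from [estimate_resilience()] results).
#' @param bin_width Age bin width, years (default 5).
#' @param min_per_bin Bins with fewer subjects are dropped from the trend.
#' @param n_boot Bootstrap replicates for the confidence band (0 disables).
#' @return A list: `bins` (data.frame age, mean_rate, n), `slope`,
#'   `intercept`, `zero_crossing_age` (NA with `zero_defined = FALSE` when
#'   the slope is not negative), and `zero_ci` when bootstrapped.
#' @export
cohort_recovery_trend <- function(estimates, bin_width = 5, min_per_bin = 20,
                                  n_boot = 200) {
  stopifnot(all(c("age", "rate") %in% names(estimates)))
  trend <- function(df) {
    centers <- bin_ages(df$age, bin_width)
    agg <- stats::aggregate(df$rate, by = list(age = centers),
                            function(v) c(mean = mean(v), n = length(v)))
    bins <- data.frame(age = agg$age, mean_rate = agg$x[, "mean"],
                       n = agg$x[, "n"])
    bins <- bins[bins$n >= min_per_bin, , drop = FALSE]
    if (nrow(bins) < 3) return(NULL)
    fit <- stats::lm(mean_rate ~ age, data = bins, weights = bins$n)
    co <- stats::coef(fit)
    list(bins = bins, slope = unname(co["age"]), intercept = unname(co["(Intercept)"]))
  }
  main <- trend(estimates)
  if (is.null(main)) stop("need at least 3 age bins with >= ", min_per_bin, " estimates")
  zero_defined <- main$slope < 0
  zero <- if (zero_defined) -main$intercept / main$slope else NA_real_
  zero_ci <- NULL
  if (n_boot > 0) {
    zs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(estimates), replace = TRUE)
      tr <- trend(estimates[idx, , drop = FALSE])
      if (is.null(tr) || tr$slope >= 0) return(NA_real_)
      -tr$intercept / tr$slope
    }, numeric(1))
    zs <- zs[is.finite(zs)]
    if (length(zs) >= 20) {
      zero_ci <- unname(stats::quantile(zs, c(0.025, 0.975)))
    }
  }
  list(bins = main$bins, slope = main$slope, intercept = main$intercept,
       zero_crossing_age = zero, zero_defined = zero_defined,
       zero_ci = zero_ci)
}

#' Non-resilient fraction by age and its exponential growth rate
#'
#' Computes per age bin the fraction of subjects whose recovery time exceeds
#' the cutoff (default 3 weeks), then fits `ln(fraction)` against age by
#' least squares over bins with non-zero fractions. The growth rate `alpha`
#' (1/year) and doubling time `ln 2 / alpha` (years) summarise how fast the
#' loss of resilience spreads through the population. Subjects whose tau
#' was unresolved because the ACF decays faster than one day are counted as
#' resilient (their recovery time is below the lag resolution) and reported
#' separately.
#'
#' @param estimates Data.frame with columns `age`, `tau` (days); may contain
#'   `unresolved` (logical) for fast-decay cases.
#' @param cutoff_days Non-resilience cutoff, days (default 21).
#' @param bin_width Age bin width, years.
#' @param min_per_bin Minimum subjects per bin.
#' @return A list: `bins` (age, fraction, n), `alpha` (1/year),
#'   `doubling_time` (years; `Inf` when `alpha <= 0`), `n_unresolved`.
#' @export
nonresilient_fraction <- function(estimates, cutoff_days = 21, bin_width = 5,
                                  min_per_bin = 20) {
  stopifnot(all(c("age", "tau") %in% names(estimates)))
  unresolved <- if ("unresolved" %in% names(estimates)) estimates$unresolved else rep(FALSE, nrow(estimates))
  nonres <- !unresolved & estimates$tau > cutoff_days
  centers <- bin_ages(estimates$age, bin_width)
  agg <- stats::aggregate(nonres, by = list(age = centers),
                          function(v) c(frac = mean(v), n = length(v)))
  bins <- data.frame(age = agg$age, fraction = agg$x[, "frac"], n = agg$x[, "n"])
  bins <- bins[bins$n >= min_per_bin, , drop = FALSE]
  if (all(bins$fraction == 0)) stop("no non-resilient individuals in any bin")
  pos <- bins[bins$fraction > 0, , drop = FALSE]
  if (nrow(pos) < 3) stop("need at least 3 age bins with non-zero fractions")
  fit <- stats::lm(log(fraction) ~ age, data = pos)
  alpha <- unname(stats::coef(fit)["age"])
  list(bins = bins, alpha = alpha,
       doubling_time = if (alpha > 0) log(2) / alpha else Inf,
       n_unresolved = sum(unresolved))
}
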