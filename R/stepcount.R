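#' Detect candidate step peaks in an acceleration trace
#'
#' Finds strict local maxima of the acceleration magnitude that exceed a
#' threshold. At rest a wrist-worn accelerometer reads about 1 g (gravity),
#' so the default 1.3 g threshold selects impacts well above baseline.
#'
#' @param trace An `accel_trace` object (see [accel_trace()]).
#' @param threshold Magnitude threshold in g; peaks must strictly exceed it.
#' @return A data.frame with columns `index` (1-based sample index),
#'   `time` (seconds from trace start) and `magnitude` (g), sorted by time.
#' @seealso [select_peaks_windowed()], [count_steps_per_minute()]
#' @export
detect_candidate_peaks <- function(trace, threshold = 1.3) {
  trace <- as_accel_trace(trace)
  stopifnot(threshold > 0)
  x <- trace$magnitudes
  n <- length(x)
  if (n < 3L) {
    stop("trace too short for peak detection: need at least 3 samples, got ", n)
  }
  mid <- 2:(n - 1L)
  is_peak <- x[mid] > x[mid - 1L] & x[mid] > x[mid + 1L] & x[mid] > threshold
  idx <- mid[is_peak]
  data.frame(
    index = idx,
    time = (idx - 1L) / trace$sampling_rate,
    magnitude = x[idx]
  )
}

#' Select counted steps from candidate peaks with a sliding window
#'
#' De-noises candidate peaks with a sliding window: only the highest peak in
#' each window may be counted, so a candidate that is out-magnituded in any
#' window containing it is discarded. With the default 480 ms window sliding
#' by 160 ms, surviving peaks are necessarily more than 320 ms apart, hence
#' at most 3 steps can be registered during any 960 ms interval.
#'
#' Window grid starts at the trace start (time 0) and advances by `stride_ms`;
#' windows are half-open `[s, s + window)`. Ties in magnitude are broken in
#' favour of the earlier peak.
#'
#' @param peaks data.frame with `time` (s) and `magnitude` columns, as
#'   returned by [detect_candidate_peaks()].
#' @param window_ms Window length, ms.
#' @param stride_ms Window step, ms. `window_ms` must be a multiple of it.
#' @return The subset of `peaks` that are counted as steps, sorted by time.
#' @export
select_peaks_windowed <- function(peaks, window_ms = 480, stride_ms = 160) {
  stopifnot(window_ms > 0, stride_ms > 0, window_ms %% stride_ms == 0)
  if (nrow(peaks) == 0L) return(peaks)
  ord <- order(peaks$time)
  peaks <- peaks[ord, , drop = FALSE]
  t_ms <- peaks$time * 1000
  mag <- peaks$magnitude
  n <- nrow(peaks)
  counted <- rep(TRUE, n)
  # a peak is counted iff it is the highest in every window containing it:
  # whenever two peaks share a window the lesser one is discarded (tie broken
  # toward the earlier peak), regardless of whether the greater survives
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && t_ms[j] - t_ms[i] < window_ms) {
      if (share_window(t_ms[i], t_ms[j], window_ms, stride_ms)) {
        if (mag[j] > mag[i]) counted[i] <- FALSE else counted[j] <- FALSE
      }
      j <- j + 1L
    }
  }
  peaks[counted, , drop = FALSE]
}

# do two event times (ms) fall inside a common sliding window?
share_window <- function(t1, t2, window_ms, stride_ms) {
  lo <- max(t1, t2) - window_ms    # window starts s in (lo, hi] contain both
  hi <- min(t1, t2)
  if (hi < 0) return(FALSE)
  # smallest multiple of stride that is > lo and <= hi
  s <- stride_ms * ceiling((lo + 1e-9) / stride_ms)
  if (s <= lo) s <- s + stride_ms
  s <= hi
}

#' Group steps into walking bouts and drop short bouts
#'
#' Steps closer than `gap_s` to their predecessor belong to the same walking
#' bout; bouts totalling fewer than `min_steps` steps are discarded entirely.
#'
#' @param step_times Sorted numeric vector of step times in seconds.
#' @param gap_s Maximum inter-step gap within a bout, seconds.
#' @param min_steps Minimum steps for a bout to be retained.
#' @return Numeric vector of retained step times.
#' @export
aggregate_bouts <- function(step_times, gap_s = 90, min_steps = 5) {
  stopifnot(gap_s > 0, min_steps >= 1)
  if (length(step_times) == 0L) return(step_times)
  if (is.unsorted(step_times)) stop("step_times must be sorted")
  bout <- cumsum(c(1, diff(step_times) >= gap_s))
  sizes <- tabulate(bout)
  step_times[sizes[bout] >= min_steps]
}

#' Convert a raw acceleration trace to per-minute step counts
#'
#' The full step-counting chain: threshold peak detection, sliding-window
#' selection, walking-bout filtering, then bucketing retained steps into
#' whole minutes from the trace start. A trailing partial minute is dropped.
#'
#' @param trace An `accel_trace`.
#' @param threshold Peak threshold in g.
#' @param window_ms,stride_ms Sliding-window parameters, ms.
#' @param bout_gap_s,bout_min_steps Walking-bout parameters.
#' @return A `step_series` object (see [step_series()]) with one count per
#'   whole minute.
#' @export
count_steps_per_minute <- function(trace, threshold = 1.3,
                                   window_ms = 480, stride_ms = 160,
                                   bout_gap_s = 90, bout_min_steps = 5) {
  trace <- as_accel_trace(trace)
  dur <- length(trace$magnitudes) / trace$sampling_rate
  n_min <- floor(dur / 60)
  if (n_min < 1L) stop("trace shorter than one minute (", round(dur, 1), " s)")
  peaks <- detect_candidate_peaks(trace, threshold)
  sel <- select_peaks_windowed(peaks, window_ms, stride_ms)
  kept <- aggregate_bouts(sel$time, bout_gap_s, bout_min_steps)
  minute <- floor(kept / 60)
  minute <- minute[minute < n_min]
  counts <- tabulate(minute + 1L, nbins = n_min)
  step_series(counts, start_time = trace$start_time)
}
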