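#' Acceleration-magnitude trace
#'
#' A uniformly sampled acceleration magnitude signal (Euclidean norm of the
#' three axes, so about 1 g at rest), the input to the step counter.
#'
#' @param magnitudes Numeric vector of magnitudes in g; finite, non-negative.
#' @param sampling_rate Samples per second (Hz).
#' @param start_time POSIXct start of the recording.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(magnitudes, sampling_rate = 100,
                        start_time = as.POSIXct("2020-01-06 00:00:00", tz = "UTC")) {
  stopifnot(is.numeric(magnitudes), sampling_rate > 0)
  if (anyNA(magnitudes) || any(!is.finite(magnitudes)) || any(magnitudes < 0)) {
    stop("magnitudes must be finite and non-negative")
  }
  structure(
    list(magnitudes = as.numeric(magnitudes),
         sampling_rate = sampling_rate,
         start_time = start_time),
    class = "accel_trace"
  )
}

as_accel_trace <- function(x) {
  if (inherits(x, "accel_trace")) return(x)
  stop("expected an accel_trace object")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$magnitudes), x$sampling_rate,
              length(x$magnitudes) / x$sampling_rate))
  invisible(x)
}

#' Per-minute step-count series
#'
#' Minute-resolution non-negative integer step counts covering whole days
#' (when `n_days`-aligned), with device and season tags and a per-day
#' missing mask. Missing days are zero-imputed and flagged, following the
#' convention that absent recording days are stored as zeros.
#'
#' @param counts Integer vector of per-minute step counts.
#' @param start_time POSIXct start (UTC); minutes are half-open intervals
#'   labelled by their start.
#' @param device Device tag, e.g. "wrist_research", "phone", "watch".
#' @param season Season tag, "summer" or "winter".
#' @param missing_mask Logical per-day vector; `TRUE` marks a zero-imputed
#'   missing day. Defaults to all-`FALSE` when the series spans whole days.
#' @param subject_id Optional subject identifier.
#' @return An object of class `step_series`.
#' @export
step_series <- function(counts, start_time = as.POSIXct("2020-01-06 00:00:00", tz = "UTC"),
                        device = "wrist_research", season = "summer",
                        missing_mask = NULL, subject_id = NA_character_) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  counts <- as.integer(counts)
  n_days <- length(counts) / 1440
  if (is.null(missing_mask)) {
    missing_mask <- rep(FALSE, floor(n_days))
  }
  if (n_days == floor(n_days) && length(missing_mask) != n_days) {
    stop("missing_mask must have one entry per day")
  }
  if (length(missing_mask) > 0 && any(missing_mask)) {
    for (d in which(missing_mask)) {
      idx <- ((d - 1L) * 1440L + 1L):(d * 1440L)
      if (any(counts[idx] != 0L)) stop("counts within missing days must be zero")
    }
  }
  structure(
    list(counts = counts, start_time = start_time, device = device,
         season = season, missing_mask = missing_mask, subject_id = subject_id),
    class = "step_series"
  )
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("<step_series> %s: %.1f days, device=%s, season=%s, %d missing day(s)\n",
              x$subject_id, length(x$counts) / 1440, x$device, x$season,
              sum(x$missing_mask)))
  invisible(x)
}

#' Number of whole days in a step series
#' @param series A `step_series`.
#' @return Integer day count.
#' @export
n_days <- function(series) length(series$counts) %/% 1440L

#' Daily BAA track
#'
#' Daily biological-age-acceleration values in years. The first 6 days of a
#' track are invalid because the model needs a full trailing 7-day window.
#'
#' @param baa Numeric vector, one BAA value (years) per day.
#' @param valid Logical vector, same length; which days carry a usable value.
#' @param subject_id Optional identifier.
#' @return An object of class `baa_track`.
#' @export
baa_track <- function(baa, valid = NULL, subject_id = NA_character_) {
  if (is.null(valid)) valid <- rep(TRUE, length(baa))
  stopifnot(length(valid) == length(baa))
  if (any(!is.finite(baa[valid]))) stop("BAA must be finite on valid days")
  structure(list(baa = as.numeric(baa), valid = as.logical(valid),
                 subject_id = subject_id, day_index = seq_along(baa)),
            class = "baa_track")
}

#' @export
print.baa_track <- function(x, ...) {
  cat(sprintf("<baa_track> %s: %d days (%d valid), mean BAA %.2f y\n",
              x$subject_id, length(x$baa), sum(x$valid),
              mean(x$baa[x$valid])))
  invisible(x)
}
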