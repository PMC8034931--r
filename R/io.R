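# CSV interchange formats. Step series are stored sparse (one row per
# minute with non-zero steps, plus an anchoring first row), timestamps
# ISO-8601 UTC labelling half-open minute intervals by their start.

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso8601 <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# write a file atomically: temp file in the same directory, then rename
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write step series to a sparse CSV
#'
#' Columns `subject_id`, `timestamp` (ISO-8601 UTC), `steps`. Minutes with
#' zero steps are omitted except the first minute of each subject, which is
#' always written so the series extent is recoverable; a `span_days` column
#' records each subject's day count. Missing days are stored as zeros
#' (omitted rows) and re-flagged on read.
#'
#' @param series_list Named list of `step_series`.
#' @param path Output CSV path; written atomically.
#' @return The path, invisibly.
#' @export
write_step_series <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    nz <- which(s$counts > 0L)
    keep <- sort(unique(c(1L, nz)))
    data.frame(
      subject_id = s$subject_id,
      timestamp = iso8601(s$start_time + 60 * (keep - 1L)),
      steps = s$counts[keep],
      span_days = n_days(s),
      device = s$device,
      season = s$season,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  atomic_write(function(p) utils::write.csv(df, p, row.names = FALSE), path)
}

#' Read step series from CSV
#'
#' Accepts the sparse format written by [write_step_series()]: absent
#' minutes are zero, and days with no recorded minutes at all are flagged
#' missing (zero-imputed). Malformed rows (unparseable timestamps, negative
#' or non-integer steps) and duplicate minutes abort with the offending line
#' numbers.
#'
#' @param path CSV with header `subject_id,timestamp,steps` (optional
#'   `span_days`, `device`, `season`).
#' @return Named list of `step_series`.
#' @export
read_step_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "steps")
  if (!all(need %in% names(df))) {
    stop("step-series CSV must have columns: ", paste(need, collapse = ", "))
  }
  ts <- parse_iso8601(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop("unparseable timestamps at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  bad <- which(df$steps < 0 | df$steps != round(df$steps))
  if (length(bad) > 0) {
    stop("negative or non-integer steps at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  out <- list()
  for (id in unique(df$subject_id)) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    t0 <- min(ts[df$subject_id == id])
    t0 <- trunc(t0, "days")
    minute <- as.integer(round(as.numeric(difftime(ts[df$subject_id == id],
                                                   t0, units = "mins"))))
    if (anyDuplicated(minute)) {
      dup <- minute[duplicated(minute)][1]
      stop("duplicate minute rows for subject ", id, " (minute offset ", dup, ")")
    }
    nd <- if ("span_days" %in% names(sub)) max(sub$span_days) else
      ceiling((max(minute) + 1) / 1440)
    counts <- integer(nd * 1440L)
    counts[minute + 1L] <- as.integer(sub$steps)
    day_of <- rep(seq_len(nd), each = 1440L)
    present <- tabulate(day_of[minute + 1L], nbins = nd) > 0L
    out[[id]] <- step_series(
      counts, start_time = t0,
      device = if ("device" %in% names(sub)) sub$device[1] else "wrist_research",
      season = if ("season" %in% names(sub)) sub$season[1] else "summer",
      missing_mask = !present, subject_id = id)
  }
  out
}

#' Write a cohort table to CSV
#' @param cohort Cohort data.frame ([simulate_cohort()]).
#' @param path Output path; written atomically.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  atomic_write(function(p) utils::write.csv(cohort, p, row.names = FALSE), path)
}

#' Read a cohort table from CSV
#' @param path CSV written by [write_cohort()].
#' @return Data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("dead" %in% names(df)) df$dead <- as.logical(df$dead)
  if ("morbid" %in% names(df)) df$morbid <- as.logical(df$morbid)
  df
}

#' Write a pipeline configuration as YAML
#' @param config A list (e.g. [pipeline_config()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  atomic_write(function(p) yaml::write_yaml(unclass(config), p), path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return A list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
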