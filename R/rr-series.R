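#' R-R interval series
#'
#' Container for an ordered sequence of heartbeat (R-R) intervals together
#' with the cumulative onset time of each beat. This is the raw physiological
#' input of the pipeline: everything downstream (range filtering, resampling,
#' spectral analysis) consumes an `rr_series`.
#'
#' @param rr_ms Numeric vector of R-R intervals in milliseconds; all positive,
#'   length at least 2.
#' @param t_ms Optional numeric vector of beat times in milliseconds, strictly
#'   increasing and the same length as `rr_ms`. When omitted, times are
#'   reconstructed cumulatively as `cumsum(rr_ms)`, i.e. each beat is stamped
#'   at the end of the interval it terminates.
#' @param schedule Optional [condition_schedule()] attached to the recording.
#'
#' @return An object of class `rr_series`: a data frame with columns `t_ms`
#'   and `rr_ms`, and a `schedule` attribute when one was supplied.
#' @export
#' @examples
#' rr <- rr_series(c(800, 810, 790, 805))
#' rr$t_ms
rr_series <- function(rr_ms, t_ms = NULL, schedule = NULL) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 2L) {
    stop("rr_ms: an R-R series needs at least 2 intervals", call. = FALSE)
  }
  if (anyNA(rr_ms) || any(rr_ms <= 0)) {
    stop("rr_ms: intervals must be positive and non-missing", call. = FALSE)
  }
  if (is.null(t_ms)) {
    t_ms <- cumsum(rr_ms)
  } else {
    t_ms <- as.numeric(t_ms)
    if (length(t_ms) != length(rr_ms)) {
      stop("t_ms: must match rr_ms in length", call. = FALSE)
    }
    if (anyNA(t_ms) || any(diff(t_ms) <= 0)) {
      stop("t_ms: beat times must be strictly increasing", call. = FALSE)
    }
  }
  out <- data.frame(t_ms = t_ms, rr_ms = rr_ms)
  class(out) <- c("rr_series", "data.frame")
  if (!is.null(schedule)) {
    attr(out, "schedule") <- as_condition_schedule(schedule)
  }
  out
}

#' @export
print.rr_series <- function(x, ...) {
  dur <- (x$t_ms[nrow(x)] - x$t_ms[1L]) / 1000
  cat(sprintf("<rr_series> %d beats, %.1f s, mean RR %.1f ms\n",
              nrow(x), dur, mean(x$rr_ms)))
  sch <- attr(x, "schedule")
  if (!is.null(sch)) {
    cat("  schedule:", paste(sprintf("%s[%gs+%gs]", sch$label, sch$onset_s,
                                     sch$duration_s), collapse = " "), "\n")
  }
  invisible(x)
}

#' Behavioral-condition schedule
#'
#' The paradigm timeline: an ordered set of contiguous, non-overlapping
#' conditions. The default is the three-behavioral-state layout used
#' throughout the package: roughly 60 s of initial rest (`Rest`), a 100-s
#' random-number-generation task (`Task`), and 60 s of post-task rest
#' (`After`). Each condition must last longer than 30 s so that the
#' within-condition averaging window (which skips the first 30 s) is
#' non-empty.
#'
#' @param label Character vector of condition names.
#' @param onset_s Numeric vector of condition onsets in seconds.
#' @param duration_s Numeric vector of condition durations in seconds.
#'
#' @return A `condition_schedule` data frame with columns `label`, `onset_s`,
#'   `duration_s`.
#' @export
#' @examples
#' condition_schedule()  # the default Rest/Task/After layout
condition_schedule <- function(label = c("Rest", "Task", "After"),
                               onset_s = c(0, 60, 160),
                               duration_s = c(60, 100, 60)) {
  label <- as.character(label)
  onset_s <- as.numeric(onset_s)
  duration_s <- as.numeric(duration_s)
  n <- length(label)
  if (n < 1L || length(onset_s) != n || length(duration_s) != n) {
    stop("schedule: label, onset_s and duration_s must have equal length",
         call. = FALSE)
  }
  if (any(duration_s <= 30)) {
    stop("schedule: every condition must exceed 30 s (averaging skips the ",
         "first 30 s of each condition)", call. = FALSE)
  }
  if (n > 1L) {
    ends <- onset_s + duration_s
    if (any(abs(onset_s[-1L] - ends[-n]) > 1e-9)) {
      stop("schedule: conditions must be contiguous and non-overlapping",
           call. = FALSE)
    }
  }
  out <- data.frame(label = label, onset_s = onset_s, duration_s = duration_s)
  class(out) <- c("condition_schedule", "data.frame")
  out
}

as_condition_schedule <- function(x) {
  if (inherits(x, "condition_schedule")) return(x)
  condition_schedule(x$label, x$onset_s, x$duration_s)
}

#' Read and write R-R series as CSV
#'
#' The on-disk format is a two-column CSV with header `t_ms,rr_ms`. A bare
#' interval list (one millisecond value per line, no header) is also accepted
#' on read; beat times are then reconstructed cumulatively. An optional JSON
#' sidecar carries the condition schedule.
#'
#' @param path Path of the CSV (or bare-interval text) file.
#' @param schedule_path Optional path of a JSON schedule sidecar (an array of
#'   objects with fields `label`, `onset_s`, `duration_s`).
#' @return `read_rr_csv()` returns an [rr_series()].
#' @export
read_rr_csv <- function(path, schedule_path = NULL) {
  first <- readLines(path, n = 1L)
  sched <- if (!is.null(schedule_path)) {
    df <- jsonlite::fromJSON(schedule_path)
    condition_schedule(df$label, df$onset_s, df$duration_s)
  }
  if (grepl("t_ms", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    rr_series(df$rr_ms, df$t_ms, schedule = sched)
  } else {
    rr <- as.numeric(readLines(path))
    rr_series(rr[!is.na(rr)], schedule = sched)
  }
}

#' @rdname read_rr_csv
#' @param rr An [rr_series()].
#' @export
write_rr_csv <- function(rr, path, schedule_path = NULL) {
  utils::write.csv(as.data.frame(rr)[, c("t_ms", "rr_ms")], path,
                   row.names = FALSE, quote = FALSE)
  sch <- attr(rr, "schedule")
  if (!is.null(schedule_path) && !is.null(sch)) {
    jsonlite::write_json(as.data.frame(sch), schedule_path,
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}
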