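#' Range-filter an R-R series
#'
#' Intervals outside the physiological range (default 273-1500 ms, i.e. heart
#' rates of roughly 40-220 beats/min) are treated as paroxysmal beats or
#' detection artifacts and replaced by the average of the nearest in-range
#' interval on each side. An edge beat with only one in-range neighbor copies
#' that neighbor. Runs of consecutive out-of-range beats are replaced
#' left-to-right using the nearest originally-valid values on each side, so
#' the result does not depend on processing order. Beat times are rebuilt
#' cumulatively from the repaired intervals.
#'
#' @param rr An [rr_series()].
#' @param lo_ms,hi_ms Acceptance range in milliseconds.
#' @return The repaired [rr_series()] with attribute `n_replaced`, the number
#'   of intervals that were replaced.
#' @export
#' @examples
#' rr <- rr_series(c(800, 2000, 820))
#' filter_rr_range(rr)$rr_ms  # 800 810 820
filter_rr_range <- function(rr, lo_ms = 273, hi_ms = 1500) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  n <- length(x)
  if (n < 3L) {
    stop("filter_rr_range: need at least 3 beats for neighbor replacement",
         call. = FALSE)
  }
  bad <- x < lo_ms | x > hi_ms
  if (mean(bad) > 0.5) {
    stop("quality error: more than 50% of beats outside [", lo_ms, ", ",
         hi_ms, "] ms; recording unusable", call. = FALSE)
  }
  if (any(bad)) {
    good_idx <- which(!bad)
    for (i in which(bad)) {
      left <- good_idx[good_idx < i]
      right <- good_idx[good_idx > i]
      if (length(left) && length(right)) {
        x[i] <- (x[max(left)] + x[min(right)]) / 2
      } else if (length(right)) {
        x[i] <- x[min(right)]
      } else {
        x[i] <- x[max(left)]
      }
    }
  }
  t0 <- rr$t_ms[1L] - rr$rr_ms[1L]
  out <- rr_series(x, t0 + cumsum(x), schedule = attr(rr, "schedule"))
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Resample an R-R series on a uniform grid
#'
#' Spectral estimation needs evenly spaced samples; the beat-stamped
#' tachogram is interpolated onto a uniform grid whose rate is the mean heart
#' rate (fs = 1 / mean RR). The grid starts at the first beat time and
#' includes both ends of the recording. Cubic-spline interpolation is the
#' default; linear interpolation is exact for piecewise-linear test signals.
#'
#' @param rr A (filtered) [rr_series()].
#' @param method `"spline"` or `"linear"`.
#' @return A `uniform_series` list: `values_ms` (resampled intervals),
#'   `fs_hz` (sampling rate), `t0_ms` (time of the first sample), `t_s`
#'   (absolute sample times, seconds) and `schedule` carried over.
#' @export
#' @examples
#' u <- resample_uniform(rr_series(rep(800, 75)))
#' u$fs_hz  # 1.25
resample_uniform <- function(rr, method = c("spline", "linear")) {
  stopifnot(inherits(rr, "rr_series"))
  method <- match.arg(method)
  fs <- 1000 / mean(rr$rr_ms)           # Hz
  dur_s <- (rr$t_ms[nrow(rr)] - rr$t_ms[1L]) / 1000
  if (dur_s + rr$rr_ms[1L] / 1000 < 30) {
    stop("resample_uniform: recording shorter than 30 s; no spectral window ",
         "can be formed", call. = FALSE)
  }
  n <- floor(dur_s * fs) + 1L
  t_grid_ms <- rr$t_ms[1L] + (seq_len(n) - 1L) * 1000 / fs
  vals <- if (method == "spline") {
    stats::spline(rr$t_ms, rr$rr_ms, xout = t_grid_ms, method = "fmm")$y
  } else {
    stats::approx(rr$t_ms, rr$rr_ms, xout = t_grid_ms, rule = 2)$y
  }
  structure(list(values_ms = vals, fs_hz = fs, t0_ms = t_grid_ms[1L],
                 t_s = t_grid_ms / 1000, schedule = attr(rr, "schedule")),
            class = "uniform_series")
}

#' Per-beat heart rate trend
#'
#' Converts each R-R interval to an instantaneous heart rate,
#' HR = 60000 / RR(ms), in beats per minute.
#'
#' @param rr An [rr_series()].
#' @return Numeric vector of heart rates (beats/min), one per beat.
#' @export
#' @examples
#' hr_trend(rr_series(c(800, 1000, 600)))  # 75 60 100
hr_trend <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  60000 / rr$rr_ms
}
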