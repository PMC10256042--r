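#' Per-condition period means of a spectral trend
#'
#' Averages the spectral-trend estimates within each scheduled condition,
#' skipping the first `skip_s` seconds after each condition onset (default
#' 30 s). The skip serves two purposes: it discards the autonomic carry-over
#' from the previous condition, and — because each trend estimate summarises
#' the trailing 30 s — it guarantees that no averaged estimate's window
#' reaches back across the condition boundary.
#'
#' @param trend A `spectral_trend` from [spectral_trend()].
#' @param schedule A [condition_schedule()]; defaults to the one attached to
#'   the trend.
#' @param skip_s Seconds skipped after each condition onset.
#' @return A `period_summary` data frame, one row per condition: `label`,
#'   `lf_ms2`, `hf_ms2`, `lfhf_sum_ms2`, `lfhf_ratio`, `hr_bpm`, `n_est`.
#' @export
period_means <- function(trend, schedule = NULL, skip_s = 30) {
  stopifnot(inherits(trend, "spectral_trend"))
  if (is.null(schedule)) schedule <- attr(trend, "schedule")
  if (is.null(schedule)) {
    stop("period_means: no schedule supplied or attached to the trend",
         call. = FALSE)
  }
  schedule <- as_condition_schedule(schedule)
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    lo <- schedule$onset_s[i] + skip_s
    hi <- schedule$onset_s[i] + schedule$duration_s[i]
    sel <- trend$t_s >= lo - 1e-9 & trend$t_s <= hi + 1e-9
    if (!any(sel)) {
      stop("period_means: no spectral estimates inside condition '",
           schedule$label[i], "' (averaging interval [", lo, ", ", hi, "] s)",
           call. = FALSE)
    }
    data.frame(label = schedule$label[i],
               lf_ms2 = mean(trend$lf_ms2[sel]),
               hf_ms2 = mean(trend$hf_ms2[sel]),
               lfhf_sum_ms2 = mean(trend$lfhf_sum_ms2[sel]),
               lfhf_ratio = mean(trend$lfhf_ratio[sel]),
               hr_bpm = mean(trend$hr_bpm[sel]),
               n_est = sum(sel))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("period_summary", "data.frame")
  out
}

#' Nine-feature vector for the discriminant equation
#'
#' Builds the predictors of the discriminant score from the per-condition
#' summary: the Rest level of HF, LF and LF/HF, plus the Task/Rest and
#' After/Rest ratios of each index. Ratios are ratios of period means (not
#' means of per-estimate ratios), matching the bracketed period quantities of
#' the discriminant equation.
#'
#' @param p A `period_summary` from [period_means()] whose labels include
#'   `Rest`, `Task` and `After`.
#' @return Named numeric vector of length 9 in [hrv_feature_names()] order.
#' @export
build_features <- function(p) {
  stopifnot(inherits(p, "period_summary"))
  need <- c("Rest", "Task", "After")
  if (!all(need %in% p$label)) {
    stop("build_features: period summary must contain Rest, Task and After",
         call. = FALSE)
  }
  val <- function(lab, col) p[[col]][p$label == lab][1L]
  out <- numeric(0)
  for (col in c("hf_ms2", "lf_ms2", "lfhf_ratio")) {
    rest <- val("Rest", col)
    if (!is.finite(rest) || rest <= 0) {
      stop("build_features: Rest value of ", col,
           " is zero or undefined; ratio features cannot be formed",
           call. = FALSE)
    }
    out <- c(out, rest, val("Task", col) / rest, val("After", col) / rest)
  }
  names(out) <- hrv_feature_names()
  out
}

#' Write a per-subject feature table as CSV
#'
#' One row per subject: `subject_id,group`, the nine feature columns, and any
#' extra reporting columns present.
#'
#' @param tab A `cohort_table` (or compatible data frame).
#' @param path Output path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-subject feature table
#'
#' @param path CSV path with columns `subject_id`, `group` and the nine
#'   features of [hrv_feature_names()].
#' @return A `cohort_table` data frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("subject_id", "group", hrv_feature_names()), names(df))
  if (length(miss)) {
    stop("read_feature_table: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
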