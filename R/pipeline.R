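#' Analysis configuration
#'
#' Collects the tunable options of the per-subject pipeline. The LF and HF
#' integration bands default to the standard short-term HRV definitions
#' (0.04-0.15 and 0.15-0.4 Hz); overriding them is possible but emits a
#' warning, because downstream summaries are defined in terms of these bands.
#'
#' @param rr_range_ms Acceptance range of the beat filter (ms).
#' @param interpolation `"spline"` or `"linear"` resampling.
#' @param window_s,step_s Spectral window and update interval (s).
#' @param ar_order AR order or `NULL` for the adaptive default.
#' @param lf_band,hf_band Band limits in Hz.
#' @param skip_s Seconds skipped at each condition onset before averaging.
#' @return A `run_config` list.
#' @export
run_config <- function(rr_range_ms = c(273, 1500),
                       interpolation = c("spline", "linear"),
                       window_s = 30, step_s = 2, ar_order = NULL,
                       lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                       skip_s = 30) {
  interpolation <- match.arg(interpolation)
  if (!isTRUE(all.equal(lf_band, c(0.04, 0.15))) ||
      !isTRUE(all.equal(hf_band, c(0.15, 0.4)))) {
    warning("non-standard LF/HF bands in use: LF ", lf_band[1L], "-",
            lf_band[2L], " Hz, HF ", hf_band[1L], "-", hf_band[2L], " Hz",
            call. = FALSE)
  }
  structure(list(rr_range_ms = rr_range_ms, interpolation = interpolation,
                 window_s = window_s, step_s = step_s, ar_order = ar_order,
                 lf_band = lf_band, hf_band = hf_band, skip_s = skip_s),
            class = "run_config")
}

#' Run the full per-subject pipeline
#'
#' Composes the four per-subject stages: range filtering, uniform resampling,
#' the sliding-window maximum-entropy spectral trend, condition averaging,
#' and the nine-feature vector. Errors are re-thrown with the failing stage
#' named.
#'
#' @param rr An [rr_series()] covering the schedule.
#' @param schedule A [condition_schedule()]; defaults to the one attached to
#'   `rr`, else the standard 60/100/60 layout.
#' @param config A [run_config()].
#' @return A `subject_result` list: `features` (named length-9 vector),
#'   `periods` (the `period_summary`), `trend`, `n_replaced`, `mean_hr_bpm`.
#' @export
#' @examples
#' rr <- generate_rr_trace(trace_spec(hf_amp_ms = c(30, 10, 40),
#'                                    white_noise_sd_ms = 2, seed = 7))
#' res <- run_subject(rr)
#' res$features["hf_task_rest"]
run_subject <- function(rr, schedule = NULL, config = run_config()) {
  stopifnot(inherits(rr, "rr_series"), inherits(config, "run_config"))
  if (is.null(schedule)) schedule <- attr(rr, "schedule")
  if (is.null(schedule)) schedule <- condition_schedule()
  schedule <- as_condition_schedule(schedule)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  filt <- stage("filter_rr_range",
                filter_rr_range(rr, config$rr_range_ms[1L],
                                config$rr_range_ms[2L]))
  u <- stage("resample_uniform",
             resample_uniform(filt, method = config$interpolation))
  trend <- stage("spectral_trend",
                 spectral_trend(u, window_s = config$window_s,
                                step_s = config$step_s,
                                order = config$ar_order,
                                lf_band = config$lf_band,
                                hf_band = config$hf_band))
  periods <- stage("period_means",
                   period_means(trend, schedule, skip_s = config$skip_s))
  features <- stage("build_features", build_features(periods))
  structure(list(features = features, periods = periods, trend = trend,
                 n_replaced = attr(filt, "n_replaced"),
                 mean_hr_bpm = mean(hr_trend(filt))),
            class = "subject_result")
}

#' Run a study-level analysis over a feature cohort
#'
#' Fits the requested pairwise discriminants on a cohort table, classifies
#' the training cohort (resubstitution, as in the published layout), and
#' reports sensitivity/specificity, Mahalanobis separation, and per-group
#' feature summaries. Cross-validated (leave-one-out) percentages can be
#' added for comparison.
#'
#' @param cohort A `cohort_table` (e.g. from [generate_cohort()] or built
#'   with [run_subject()] over many recordings).
#' @param contrasts List of `c(positive, negative)` label pairs; default all
#'   ordered pairs of the groups present, first-listed group positive.
#' @param cross_validate Also compute leave-one-out estimates (slower).
#' @return A `study_result` list: per contrast a list with `model`, `counts`,
#'   `sens_spec`, `mahalanobis`, and optionally `cv_sens_spec`; plus
#'   `group_summaries` (mean and sd of each feature per group).
#' @export
run_study <- function(cohort, contrasts = NULL, cross_validate = FALSE) {
  g <- unique(as.character(cohort$group))
  if (length(g) < 2L) {
    stop("run_study: need at least 2 groups", call. = FALSE)
  }
  if (is.null(contrasts)) {
    contrasts <- utils::combn(g, 2L, simplify = FALSE)
  }
  x <- feature_matrix(cohort)
  gs <- lapply(g, function(lab) {
    xi <- x[cohort$group == lab, , drop = FALSE]
    data.frame(group = lab, feature = colnames(x), n = nrow(xi),
               mean = colMeans(xi), sd = apply(xi, 2L, stats::sd),
               row.names = NULL)
  })
  out <- lapply(contrasts, function(pr) {
    model <- fit_lda(cohort, pr[1L], pr[2L])
    sub <- cohort[cohort$group %in% pr, , drop = FALSE]
    counts <- classify_cohort(model, sub)
    res <- list(model = model, counts = counts,
                sens_spec = sensitivity_specificity(counts, pr[1L], pr[2L]),
                mahalanobis = mahalanobis_separation(cohort, pr[1L], pr[2L]))
    if (cross_validate) {
      pred <- vapply(seq_len(nrow(sub)), function(i) {
        m <- fit_lda(sub[-i, , drop = FALSE], pr[1L], pr[2L])
        d_score(m, sub[i, , drop = FALSE]) >= 0
      }, logical(1))
      cc <- confusion_counts(
        pr,
        c(sum(pred[sub$group == pr[1L]]), sum(pred[sub$group == pr[2L]])),
        c(sum(!pred[sub$group == pr[1L]]), sum(!pred[sub$group == pr[2L]])))
      res$cv_sens_spec <- sensitivity_specificity(cc, pr[1L], pr[2L])
    }
    res
  })
  names(out) <- vapply(contrasts, paste, character(1), collapse = "_vs_")
  structure(list(contrasts = out, group_summaries = do.call(rbind, gs)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("== %s ==\n", nm))
    cat(sprintf("  %-10s D>0 %4d   D<0 %4d   total %4d\n",
                ct$counts$group, ct$counts$n_positive, ct$counts$n_negative,
                ct$counts$total), sep = "")
    cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%\n",
                ct$sens_spec["sensitivity"], ct$sens_spec["specificity"]))
    cat(sprintf("  Mahalanobis d = %.3f (F = %.2f, p = %.3g)\n",
                ct$mahalanobis$distance, ct$mahalanobis$statistic,
                ct$mahalanobis$p_value))
    if (!is.null(ct$cv_sens_spec)) {
      cat(sprintf("  leave-one-out: sensitivity %.1f%%  specificity %.1f%%\n",
                  ct$cv_sens_spec["sensitivity"],
                  ct$cv_sens_spec["specificity"]))
    }
  }
  invisible(x)
}
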