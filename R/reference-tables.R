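#' Published reference tables for the MDD / CFS / control study
#'
#' Summary-level results of the case-control study that motivates this
#' pipeline: 49 patients with major depressive disorder (MDD), 44 patients
#' with chronic fatigue syndrome (CFS) and 46 healthy controls measured under
#' the Rest (60 s) / Task (100 s) / After (60 s) paradigm. Raw recordings are
#' not public; these printed group-level numbers are the inputs for the
#' summary-statistic reconstructions and for parameterising synthetic
#' cohorts.
#'
#' `hrv_reference_summaries()` returns the group mean and s.d. of each HRV
#' index (LF, HF, LF+HF in ms^2; LF/HF unitless; HR in beats/min) in each
#' condition, as a long data frame with columns `index`, `period`, `group`,
#' `n`, `mean`, `sd`.
#'
#' `discriminant_reference_counts()` returns the published counts of subjects
#' with positive and negative discriminant scores for the three contrasts
#' (MDD vs Control, CFS vs Control, MDD vs CFS), plus the reported
#' Mahalanobis distance of each contrast, as a list of
#' `list(counts = confusion_counts, positive, negative, mahalanobis_d)`.
#'
#' `cohort_sex_counts()` returns the 2 x 3 male/female by group table.
#'
#' @return See details per function.
#' @export
hrv_reference_summaries <- function() {
  n <- c(Control = 46L, MDD = 49L, CFS = 44L)
  rows <- list(
    # index, period, group, mean, sd
    c("lf", "Rest", "Control", 780, 742), c("lf", "Task", "Control", 517, 475),
    c("lf", "After", "Control", 966, 799),
    c("lf", "Rest", "MDD", 266, 320), c("lf", "Task", "MDD", 340, 463),
    c("lf", "After", "MDD", 572, 821),
    c("lf", "Rest", "CFS", 601, 979), c("lf", "Task", "CFS", 469, 438),
    c("lf", "After", "CFS", 802, 1328),
    c("hf", "Rest", "Control", 388, 368), c("hf", "Task", "Control", 136, 122),
    c("hf", "After", "Control", 438, 392),
    c("hf", "Rest", "MDD", 77, 105), c("hf", "Task", "MDD", 86, 127),
    c("hf", "After", "MDD", 165, 215),
    c("hf", "Rest", "CFS", 214, 255), c("hf", "Task", "CFS", 152, 165),
    c("hf", "After", "CFS", 395, 587),
    c("lfhf_sum", "Rest", "Control", 780, 742),
    c("lfhf_sum", "Task", "Control", 517, 475),
    c("lfhf_sum", "After", "Control", 966, 799),
    c("lfhf_sum", "Rest", "MDD", 266, 320),
    c("lfhf_sum", "Task", "MDD", 340, 463),
    c("lfhf_sum", "After", "MDD", 572, 821),
    c("lfhf_sum", "Rest", "CFS", 815, 1129),
    c("lfhf_sum", "Task", "CFS", 622, 588),
    c("lfhf_sum", "After", "CFS", 1196, 1656),
    c("lfhf_ratio", "Rest", "Control", 1.58, 1.49),
    c("lfhf_ratio", "Task", "Control", 4.10, 4.11),
    c("lfhf_ratio", "After", "Control", 1.71, 1.37),
    c("lfhf_ratio", "Rest", "MDD", 3.34, 3.71),
    c("lfhf_ratio", "Task", "MDD", 4.93, 5.00),
    c("lfhf_ratio", "After", "MDD", 3.60, 3.73),
    c("lfhf_ratio", "Rest", "CFS", 4.98, 8.99),
    c("lfhf_ratio", "Task", "CFS", 4.63, 3.98),
    c("lfhf_ratio", "After", "CFS", 3.19, 3.17),
    c("hr", "Rest", "Control", 73.2, 8.51), c("hr", "Task", "Control", 82.2, 9.6),
    c("hr", "After", "Control", 72.4, 8.7),
    c("hr", "Rest", "MDD", 80.6, 12.2), c("hr", "Task", "MDD", 84.4, 13.7),
    c("hr", "After", "MDD", 79.0, 11.9),
    c("hr", "Rest", "CFS", 79.2, 10.8), c("hr", "Task", "CFS", 85.1, 13.1),
    c("hr", "After", "CFS", 77.6, 12.1))
  out <- data.frame(index = vapply(rows, `[`, character(1), 1L),
                    period = vapply(rows, `[`, character(1), 2L),
                    group = vapply(rows, `[`, character(1), 3L),
                    mean = as.numeric(vapply(rows, `[`, character(1), 4L)),
                    sd = as.numeric(vapply(rows, `[`, character(1), 5L)))
  out$n <- n[out$group]
  out[, c("index", "period", "group", "n", "mean", "sd")]
}

#' @rdname hrv_reference_summaries
#' @export
discriminant_reference_counts <- function() {
  list(
    mdd_vs_control = list(
      counts = confusion_counts(c("MDD", "Control"), c(43, 11), c(6, 35)),
      positive = "MDD", negative = "Control", mahalanobis_d = 2.62961),
    cfs_vs_control = list(
      counts = confusion_counts(c("CFS", "Control"), c(44, 4), c(0, 42)),
      positive = "CFS", negative = "Control", mahalanobis_d = 6.48905),
    mdd_vs_cfs = list(
      counts = confusion_counts(c("MDD", "CFS"), c(45, 0), c(4, 44)),
      positive = "MDD", negative = "CFS", mahalanobis_d = 4.05344))
}

#' @rdname hrv_reference_summaries
#' @export
cohort_sex_counts <- function() {
  m <- rbind(male = c(20, 11, 20), female = c(29, 33, 26))
  colnames(m) <- c("MDD", "CFS", "Control")
  m
}

#' Group summaries of one HRV index in one period
#'
#' Convenience accessor over [hrv_reference_summaries()] returning
#' [group_summary()] objects ready for [t_from_summary()] or
#' [anova_from_summary()].
#'
#' @param index One of `"lf"`, `"hf"`, `"lfhf_sum"`, `"lfhf_ratio"`, `"hr"`.
#' @param period One of `"Rest"`, `"Task"`, `"After"`.
#' @param groups Which groups, in order.
#' @return List of [group_summary()] objects.
#' @export
#' @examples
#' anova_from_summary(reference_group_summaries("hf", "Rest"))$F
reference_group_summaries <- function(index, period,
                                      groups = c("Control", "MDD", "CFS")) {
  tab <- hrv_reference_summaries()
  lapply(groups, function(g) {
    row <- tab[tab$index == index & tab$period == period & tab$group == g, ]
    if (nrow(row) != 1L) {
      stop("no reference summary for ", index, "/", period, "/", g,
           call. = FALSE)
    }
    group_summary(g, row$n, row$mean, row$sd)
  })
}

#' Reference-parameterised cohort specification
#'
#' Builds a [cohort_spec()] whose nine-feature marginals match the published
#' group summaries: Rest levels of HF, LF and LF/HF taken directly, and the
#' Task/Rest and After/Rest ratio features given the ratio of the published
#' period means, with a coefficient of variation matched to the published
#' within-period CVs. Features are sampled independently (the within-subject
#' correlation structure is not published), so cohorts drawn from this spec
#' are distributionally faithful per feature but not jointly; discrimination
#' measured on them is reported, not asserted against the published
#' percentages.
#'
#' @param groups Group labels to include.
#' @param seed Integer seed passed to the spec.
#' @return A [cohort_spec()].
#' @export
reference_cohort_spec <- function(groups = c("Control", "MDD", "CFS"),
                                  seed = NULL) {
  tab <- hrv_reference_summaries()
  cell <- function(index, period, g) {
    tab[tab$index == index & tab$period == period & tab$group == g, ]
  }
  gspecs <- lapply(groups, function(g) {
    means <- numeric(0)
    sds <- numeric(0)
    for (index in c("hf", "lf", "lfhf_ratio")) {
      rest <- cell(index, "Rest", g)
      for (period in c("Rest", "Task", "After")) {
        row <- cell(index, period, g)
        if (period == "Rest") {
          means <- c(means, row$mean)
          sds <- c(sds, row$sd)
        } else {
          # ratio feature: mean from the ratio of period means, spread from
          # the combined CV of numerator and denominator
          m <- row$mean / rest$mean
          cv <- sqrt((row$sd / row$mean)^2 + (rest$sd / rest$mean)^2)
          means <- c(means, m)
          sds <- c(sds, m * cv)
        }
      }
    }
    list(n = cell("hf", "Rest", g)$n, mean = means, sd = sds)
  })
  names(gspecs) <- groups
  cohort_spec(gspecs, transform = "lognormal", seed = seed)
}
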