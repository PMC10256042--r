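#' Group summary
#'
#' A (label, n, mean, sd) record, the unit of summary-level statistics. Most
#' published cohort tables report exactly this, so the pooled t and one-way F
#' below can be recomputed without raw data.
#'
#' @param label Group label.
#' @param n Group size, >= 2.
#' @param mean,sd Group mean and standard deviation (sd >= 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(label, n, mean, sd) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("group_summary: n must be >= 2", call. = FALSE)
  if (sd < 0) stop("group_summary: sd must be >= 0", call. = FALSE)
  structure(list(label = as.character(label), n = n, mean = as.numeric(mean),
                 sd = as.numeric(sd)),
            class = "group_summary")
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson chi-square on a contingency table, without continuity
#' correction (sum over cells of (O - E)^2 / E, expected counts from the
#' margins), df = (r - 1)(c - 1). Used for the sex-by-diagnosis table.
#'
#' @param counts Matrix (or table) of non-negative integer counts, at least
#'   2 x 2, with positive row and column totals.
#' @return List with `chi2`, `df`, `p`.
#' @export
#' @examples
#' sex <- rbind(male = c(20, 11, 20), female = c(29, 33, 26))
#' chi_square_independence(sex)$chi2  # about 3.86
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("chi_square_independence: table must be at least 2 x 2",
         call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("chi_square_independence: counts must be non-negative",
         call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square_independence: zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pooled two-sample t from group summaries
#'
#' Student's pooled-variance two-sample t reconstructed from (n, mean, sd):
#' sp^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2),
#' t = (meanA - meanB) / (sp sqrt(1/nA + 1/nB)), df = nA + nB - 2,
#' two-sided p. When both sds are zero the statistic is 0 for equal means
#' and flagged infinite otherwise.
#'
#' @param a,b [group_summary()] objects.
#' @return List with `t`, `df`, `p`, `infinite` flag.
#' @export
t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) {
      return(list(t = 0, df = df, p = 1, infinite = FALSE))
    }
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0,
                infinite = TRUE))
  }
  tval <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       infinite = FALSE)
}

#' One-way ANOVA F from group summaries
#'
#' Reconstructs the one-way fixed-effects F statistic from per-group
#' (n, mean, sd): between-group sum of squares
#' SSB = sum n_i (mean_i - grand)^2 with the n-weighted grand mean, and
#' within-group sum of squares SSW = sum (n_i - 1) sd_i^2;
#' F = (SSB / (k - 1)) / (SSW / (N - k)).
#'
#' @param groups List of [group_summary()] objects, length >= 2.
#' @return List with `F`, `df1`, `df2`, `p`, `infinite` flag.
#' @export
#' @examples
#' hf_rest <- list(group_summary("Control", 46, 388, 368),
#'                 group_summary("MDD", 49, 77, 105),
#'                 group_summary("CFS", 44, 214, 255))
#' anova_from_summary(hf_rest)$F  # about 16.6
anova_from_summary <- function(groups) {
  if (length(groups) < 2L) {
    stop("anova_from_summary: need at least 2 groups", call. = FALSE)
  }
  stopifnot(all(vapply(groups, inherits, logical(1), "group_summary")))
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  big_n <- sum(n)
  k <- length(groups)
  grand <- sum(n * m) / big_n
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1L
  df2 <- big_n - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                              infinite = FALSE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, infinite = TRUE))
  }
  fval <- (ssb / df1) / (ssw / df2)
  list(F = fval, df1 = df1, df2 = df2,
       p = stats::pf(fval, df1, df2, lower.tail = FALSE), infinite = FALSE)
}

#' Read group summaries from CSV
#'
#' Expects columns `label,n,mean,sd`.
#'
#' @param path CSV path.
#' @return List of [group_summary()] objects.
#' @export
read_group_summaries <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    group_summary(df$label[i], df$n[i], df$mean[i], df$sd[i])
  })
}
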