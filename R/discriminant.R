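#' Fisher linear discriminant over the nine HRV features
#'
#' Fits the two-group Fisher discriminant with equal priors and a midpoint
#' cut: w = S_pooled^-1 (mu_pos - mu_neg) and discriminant point
#' w . (mu_pos + mu_neg) / 2, so the D-score of a subject is
#' D = w . x - point, positive when the features support `positive_label` and
#' negative when they support `negative_label`. Features are used in raw
#' units (LDA is affine-invariant; no standardisation).
#'
#' If the pooled covariance is numerically singular a small ridge
#' (1e-6 * trace / p on the diagonal) is applied once and noted on the model.
#'
#' @param cohort A `cohort_table` with a `group` column and the nine feature
#'   columns of [hrv_feature_names()] (any numeric feature set works; all
#'   non-id, non-group numeric columns are used in column order).
#' @param positive_label,negative_label Group labels to contrast; subjects in
#'   other groups are ignored.
#' @return A `discriminant_model` list: `coefficients` (named),
#'   `discriminant_point`, `positive_label`, `negative_label`, `features`,
#'   `ridge_applied`.
#' @export
fit_lda <- function(cohort, positive_label, negative_label) {
  x <- feature_matrix(cohort)
  g <- as.character(cohort$group)
  for (lab in c(positive_label, negative_label)) {
    if (sum(g == lab) < 2L) {
      stop("fit_lda: group '", lab, "' needs at least 2 subjects",
           call. = FALSE)
    }
  }
  xp <- x[g == positive_label, , drop = FALSE]
  xn <- x[g == negative_label, , drop = FALSE]
  mp <- colMeans(xp)
  mn <- colMeans(xn)
  sp <- ((nrow(xp) - 1) * stats::cov(xp) + (nrow(xn) - 1) * stats::cov(xn)) /
    (nrow(xp) + nrow(xn) - 2)
  ridge <- FALSE
  w <- tryCatch(solve(sp, mp - mn), error = function(e) NULL)
  if (is.null(w)) {
    sp <- sp + diag(1e-6 * sum(diag(sp)) / ncol(x), ncol(x))
    ridge <- TRUE
    w <- tryCatch(solve(sp, mp - mn), error = function(e) {
      stop("fit_lda: pooled covariance singular even after ridge guard",
           call. = FALSE)
    })
  }
  structure(list(coefficients = stats::setNames(as.numeric(w), colnames(x)),
                 discriminant_point = sum(w * (mp + mn) / 2),
                 positive_label = positive_label,
                 negative_label = negative_label,
                 features = colnames(x), ridge_applied = ridge),
            class = "discriminant_model")
}

# numeric feature columns of a cohort table, in stable order
feature_matrix <- function(cohort, features = NULL) {
  df <- as.data.frame(cohort)
  if (is.null(features)) {
    drop <- c("subject_id", "group")
    features <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], drop)
  }
  miss <- setdiff(features, names(df))
  if (length(miss)) {
    stop("cohort is missing feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(df[, features, drop = FALSE])
  if (anyNA(x) || any(!is.finite(x))) {
    stop("cohort features contain missing or non-finite values",
         call. = FALSE)
  }
  x
}

#' Discriminant score (D-score)
#'
#' D = sum of coefficients times features minus the discriminant point.
#' Positive supports the model's `positive_label`.
#'
#' @param model A `discriminant_model` from [fit_lda()].
#' @param fv Named numeric feature vector, or a matrix / `cohort_table` of
#'   subjects (one score per row).
#' @return Numeric vector of D-scores.
#' @export
d_score <- function(model, fv) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.data.frame(fv)) {
    x <- feature_matrix(fv, model$features)
  } else if (is.matrix(fv)) {
    x <- fv[, model$features, drop = FALSE]
  } else {
    x <- matrix(fv[model$features], nrow = 1L,
                dimnames = list(NULL, model$features))
  }
  as.numeric(x %*% model$coefficients) - model$discriminant_point
}

#' Confusion counts of a cohort under a discriminant model
#'
#' Counts, per group, subjects with positive (D > 0) and negative (D < 0)
#' scores. The tie D = 0 is counted as positive so that the two bins
#' exhaust every subject; ties are reported on the result.
#'
#' @param model A `discriminant_model`.
#' @param cohort A `cohort_table` with the model's features.
#' @return A `confusion_counts` data frame: `group`, `n_positive`,
#'   `n_negative`, `total`, with attribute `n_ties`.
#' @export
classify_cohort <- function(model, cohort) {
  d <- d_score(model, cohort)
  g <- as.character(cohort$group)
  out <- do.call(rbind, lapply(unique(g), function(lab) {
    di <- d[g == lab]
    data.frame(group = lab, n_positive = sum(di >= 0),
               n_negative = sum(di < 0), total = length(di))
  }))
  class(out) <- c("confusion_counts", "data.frame")
  attr(out, "n_ties") <- sum(d == 0)
  out
}

#' Build confusion counts directly from numbers
#'
#' For working with published positive/negative score counts rather than raw
#' subjects.
#'
#' @param group Character vector of group labels.
#' @param n_positive,n_negative Non-negative integer counts per group.
#' @return A `confusion_counts` data frame.
#' @export
confusion_counts <- function(group, n_positive, n_negative) {
  if (any(n_positive < 0) || any(n_negative < 0)) {
    stop("confusion_counts: counts must be non-negative", call. = FALSE)
  }
  out <- data.frame(group = as.character(group),
                    n_positive = as.integer(n_positive),
                    n_negative = as.integer(n_negative),
                    total = as.integer(n_positive + n_negative))
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the fraction of the positive (disease) group with D > 0;
#' specificity the fraction of the negative (comparison) group with D < 0.
#' Both are returned as percentages rounded to one decimal, the convention
#' used in diagnostic reporting.
#'
#' @param counts A `confusion_counts` (from [classify_cohort()] or
#'   [confusion_counts()]).
#' @param positive_label,negative_label Which groups play the disease and
#'   comparison roles.
#' @return Named numeric vector `c(sensitivity =, specificity =)` in percent.
#' @export
#' @examples
#' cc <- confusion_counts(c("MDD", "CFS"), c(45, 0), c(4, 44))
#' sensitivity_specificity(cc, "MDD", "CFS")  # 91.8, 100.0
sensitivity_specificity <- function(counts, positive_label, negative_label) {
  stopifnot(inherits(counts, "confusion_counts"))
  row_of <- function(lab) {
    i <- which(counts$group == lab)
    if (!length(i)) {
      stop("sensitivity_specificity: group '", lab, "' not in counts",
           call. = FALSE)
    }
    counts[i[1L], ]
  }
  pos <- row_of(positive_label)
  neg <- row_of(negative_label)
  if (pos$total == 0 || neg$total == 0) {
    stop("sensitivity_specificity: zero group total", call. = FALSE)
  }
  c(sensitivity = round(100 * pos$n_positive / pos$total, 1L),
    specificity = round(100 * neg$n_negative / neg$total, 1L))
}

#' Mahalanobis separation between two groups
#'
#' d = sqrt((mu_A - mu_B)' S_pooled^-1 (mu_A - mu_B)), the covariance-scaled
#' distance between group mean vectors, with a p-value from the two-sample
#' Hotelling T-squared statistic via its F transform:
#' T2 = (nA nB / (nA + nB)) d^2,
#' F = T2 (nA + nB - p - 1) / ((nA + nB - 2) p) on (p, nA + nB - p - 1) df.
#'
#' @param cohort A `cohort_table`.
#' @param label_a,label_b Group labels to compare.
#' @return List with `distance`, `statistic` (F), `df`, `p_value`.
#' @export
mahalanobis_separation <- function(cohort, label_a, label_b) {
  x <- feature_matrix(cohort)
  g <- as.character(cohort$group)
  xa <- x[g == label_a, , drop = FALSE]
  xb <- x[g == label_b, , drop = FALSE]
  na <- nrow(xa)
  nb <- nrow(xb)
  if (na < 2L || nb < 2L) {
    stop("mahalanobis_separation: each group needs >= 2 subjects",
         call. = FALSE)
  }
  p <- ncol(x)
  sp <- ((na - 1) * stats::cov(xa) + (nb - 1) * stats::cov(xb)) /
    (na + nb - 2)
  dm <- colMeans(xa) - colMeans(xb)
  w <- tryCatch(solve(sp, dm), error = function(e) {
    solve(sp + diag(1e-6 * sum(diag(sp)) / p, p), dm)
  })
  d2 <- sum(dm * w)
  t2 <- (na * nb) / (na + nb) * d2
  df2 <- na + nb - p - 1
  if (df2 < 1) {
    stop("mahalanobis_separation: too few subjects for ", p, " features",
         call. = FALSE)
  }
  fstat <- t2 * df2 / ((na + nb - 2) * p)
  list(distance = sqrt(d2), statistic = fstat, df = c(p, df2),
       p_value = stats::pf(fstat, p, df2, lower.tail = FALSE))
}

#' Serialize / read a discriminant model as JSON
#'
#' @param model A `discriminant_model`.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  jsonlite::write_json(
    list(positive_label = model$positive_label,
         negative_label = model$negative_label,
         coefficients = as.list(model$coefficients),
         discriminant_point = model$discriminant_point,
         ridge_applied = model$ridge_applied),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(coefficients = unlist(x$coefficients),
                 discriminant_point = x$discriminant_point,
                 positive_label = x$positive_label,
                 negative_label = x$negative_label,
                 features = names(x$coefficients),
                 ridge_applied = isTRUE(x$ridge_applied)),
            class = "discriminant_model")
}
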