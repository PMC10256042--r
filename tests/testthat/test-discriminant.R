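test_that("single-feature LDA cuts at the midpoint of the group means", {
  set.seed(21)
  co <- data.frame(group = rep(c("pos", "neg"), each = 100),
                   x = c(stats::rnorm(100, 2, 1), stats::rnorm(100, 0, 1)))
  m <- fit_lda(co, "pos", "neg")
  mu_p <- mean(co$x[co$group == "pos"])
  mu_n <- mean(co$x[co$group == "neg"])
  mid <- (mu_p + mu_n) / 2
  # D-score vanishes at the midpoint, is positive at the positive mean
  expect_equal(d_score(m, c(x = mid)), 0, tolerance = 1e-10)
  expect_gt(d_score(m, c(x = mu_p)), 0)
  expect_lt(d_score(m, c(x = mu_n)), 0)
  # the two training means score symmetrically
  expect_equal(d_score(m, c(x = mu_p)), -d_score(m, c(x = mu_n)),
               tolerance = 1e-10)
})

test_that("swapping the contrast labels negates every D-score", {
  co <- gaussian_cohort(60, 50, delta = 1.5, seed = 22)
  m1 <- fit_lda(co, "pos", "neg")
  m2 <- fit_lda(co, "neg", "pos")
  d1 <- d_score(m1, co)
  d2 <- d_score(m2, co)
  expect_equal(d1, -d2, tolerance = 1e-10)
  s1 <- sensitivity_specificity(classify_cohort(m1, co), "pos", "neg")
  s2 <- sensitivity_specificity(classify_cohort(m2, co), "neg", "pos")
  expect_equal(unname(s1["sensitivity"]), unname(s2["specificity"]))
  expect_equal(unname(s1["specificity"]), unname(s2["sensitivity"]))
})

test_that("the fitted direction agrees with the reference LDA", {
  skip_if_not_installed("MASS")
  co <- gaussian_cohort(200, 200, delta = 2, seed = 23)
  m <- fit_lda(co, "pos", "neg")
  ref <- MASS::lda(group ~ ., data = co[, c("group", hrv_feature_names())])
  cosine <- sum(m$coefficients * ref$scaling) /
    sqrt(sum(m$coefficients^2) * sum(ref$scaling^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-6)
})

test_that("fitting recovers the true discriminant direction", {
  co <- gaussian_cohort(2000, 2000, delta = 2, seed = 24)
  m <- fit_lda(co, "pos", "neg")
  true_w <- rep(1 / sqrt(9), 9)  # Sigma = I, mean difference along 1-vector
  cosine <- sum(m$coefficients * true_w) /
    sqrt(sum(m$coefficients^2) * sum(true_w^2))
  expect_gt(cosine, 0.95)
})

test_that("degenerate and trivial scoring behave as documented", {
  m <- structure(list(coefficients = stats::setNames(numeric(9),
                                                     hrv_feature_names()),
                      discriminant_point = 0, positive_label = "a",
                      negative_label = "b", features = hrv_feature_names(),
                      ridge_applied = FALSE),
                 class = "discriminant_model")
  fv <- stats::setNames(stats::runif(9), hrv_feature_names())
  expect_equal(d_score(m, fv), 0)
  m$coefficients["hf_rest"] <- 1
  m$discriminant_point <- 50
  fv["hf_rest"] <- 100
  expect_equal(d_score(m, fv), 50)
})

test_that("classification counts are exhaustive and tie goes positive", {
  co <- gaussian_cohort(50, 40, delta = 6, seed = 25)
  m <- fit_lda(co, "pos", "neg")
  cc <- classify_cohort(m, co)
  expect_equal(cc$n_positive + cc$n_negative, cc$total)
  # strongly separated cohort: at least 99% on the correct side
  ss <- sensitivity_specificity(cc, "pos", "neg")
  expect_gte(ss["sensitivity"], 99)
  expect_gte(ss["specificity"], 99)
  # huge offset forces everyone positive
  m$discriminant_point <- -1e9
  cc2 <- classify_cohort(m, co)
  expect_true(all(cc2$n_negative == 0))
})

test_that("published confusion counts reproduce the printed percentages", {
  rc <- discriminant_reference_counts()
  ss <- sensitivity_specificity(rc$mdd_vs_control$counts, "MDD", "Control")
  expect_equal(unname(ss), c(87.8, 76.1))
  ss <- sensitivity_specificity(rc$cfs_vs_control$counts, "CFS", "Control")
  expect_equal(unname(ss), c(100.0, 91.3))
  ss <- sensitivity_specificity(rc$mdd_vs_cfs$counts, "MDD", "CFS")
  expect_equal(unname(ss), c(91.8, 100.0))
  expect_error(
    sensitivity_specificity(confusion_counts(c("a", "b"), c(0, 0), c(0, 0)),
                            "a", "b"), "total")
  all_wrong <- confusion_counts(c("a", "b"), c(0, 5), c(5, 0))
  expect_equal(unname(sensitivity_specificity(all_wrong, "a", "b")), c(0, 0))
})

test_that("Mahalanobis distance reduces to |diff|/sd in one dimension", {
  set.seed(26)
  co <- data.frame(group = rep(c("a", "b"), each = 500),
                   x = c(stats::rnorm(500, 3, 2), stats::rnorm(500, 0, 2)))
  ms <- mahalanobis_separation(co, "a", "b")
  mu <- tapply(co$x, co$group, mean)
  sp <- sqrt((stats::var(co$x[co$group == "a"]) * 499 +
                stats::var(co$x[co$group == "b"]) * 499) / 998)
  expect_equal(ms$distance, abs(mu["a"] - mu["b"]) / sp,
               ignore_attr = TRUE, tolerance = 1e-10)
  # identical groups: zero distance
  co2 <- co
  co2$x <- rep(co$x[1:500], 2)
  expect_equal(mahalanobis_separation(co2, "a", "b")$distance, 0)
})

test_that("separation and classification are affine-invariant", {
  co <- gaussian_cohort(80, 80, delta = 2, seed = 27)
  x <- as.matrix(co[, hrv_feature_names()])
  d0 <- mahalanobis_separation(co, "pos", "neg")$distance
  cc0 <- classify_cohort(fit_lda(co, "pos", "neg"), co)
  set.seed(28)
  for (i in 1:3) {
    a <- matrix(stats::rnorm(81), 9)
    while (abs(det(a)) < 1e-3) a <- matrix(stats::rnorm(81), 9)
    shift <- stats::rnorm(9)
    xt <- sweep(x %*% a, 2, shift, "+")
    co2 <- co
    co2[, hrv_feature_names()] <- xt
    expect_equal(mahalanobis_separation(co2, "pos", "neg")$distance, d0,
                 tolerance = 1e-8)
    cc <- classify_cohort(fit_lda(co2, "pos", "neg"), co2)
    expect_equal(cc$n_positive, cc0$n_positive)
  }
})

test_that("Hotelling p-value matches the F reference", {
  co <- gaussian_cohort(40, 30, delta = 1, seed = 29)
  ms <- mahalanobis_separation(co, "pos", "neg")
  expect_equal(ms$df, c(9, 40 + 30 - 10))
  expect_equal(ms$p_value,
               stats::pf(ms$statistic, 9, 60, lower.tail = FALSE))
})

test_that("model JSON round-trip preserves coefficients and scores", {
  co <- gaussian_cohort(30, 30, delta = 2, seed = 30)
  m <- fit_lda(co, "pos", "neg")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(d_score(m2, co), d_score(m, co))
})
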