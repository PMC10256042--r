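test_that("unmodulated trace is constant with boundaries at 60 and 160 s", {
  rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800))
  expect_true(all(rr$rr_ms == 800))
  sch <- attr(rr, "schedule")
  expect_equal(sch$onset_s, c(0, 60, 160))
  expect_equal(rr$t_ms, cumsum(rr$rr_ms))
  expect_gte(rr$t_ms[nrow(rr)], 220000)
})

test_that("trace generation is reproducible under a fixed seed", {
  sp <- trace_spec(mean_rr_ms = 820, hf_amp_ms = 25, white_noise_sd_ms = 4,
                   artifact_rate = 0.05, seed = 123)
  a <- generate_rr_trace(sp)
  b <- generate_rr_trace(sp)
  expect_identical(a$rr_ms, b$rr_ms)
  expect_identical(attr(a, "artifact_idx"), attr(b, "artifact_idx"))
})

test_that("sinusoidal modulation contributes a^2/2 variance before noise", {
  for (amp in c(15, 40)) {
    rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, hf_amp_ms = amp))
    v <- stats::var(rr$rr_ms) * (nrow(rr) - 1) / nrow(rr)
    expect_equal(v, amp^2 / 2, tolerance = 0.05)
  }
})

test_that("artifact beats are out of range and leave beat times clean", {
  sp <- trace_spec(mean_rr_ms = 800, artifact_rate = 0.1, seed = 5)
  rr <- generate_rr_trace(sp)
  idx <- attr(rr, "artifact_idx")
  expect_gt(length(idx), 0)
  expect_true(all(rr$rr_ms[idx] < 273 | rr$rr_ms[idx] > 1500))
  expect_identical(rr$t_ms, cumsum(attr(rr, "clean_rr_ms")))
})

test_that("trace spec validation names the offending field", {
  expect_error(trace_spec(mean_rr_ms = 200), "mean_rr_ms")
  expect_error(trace_spec(lf_freq_hz = 0.2), "lf_freq_hz")
  expect_error(trace_spec(hf_freq_hz = 0.1), "hf_freq_hz")
  expect_error(trace_spec(artifact_rate = 0.25), "artifact_rate")
  expect_error(trace_spec(hf_amp_ms = -1), "hf_amp_ms")
})

test_that("zero-sd cohorts collapse onto the group means", {
  sp <- cohort_spec(list(A = list(n = 4, mean = 1:9, sd = 0),
                         B = list(n = 3, mean = rep(2, 9), sd = 0)))
  co <- generate_cohort(sp)
  expect_equal(nrow(co), 7)
  expect_true(all(co$hf_rest[co$group == "A"] == 1))
  expect_true(all(co$ratio_after_rest[co$group == "A"] == 9))
  expect_true(all(unlist(co[co$group == "B", hrv_feature_names()]) == 2))
})

test_that("moment-matched lognormal reproduces published-scale moments", {
  # target: HF at Rest in controls, mean 388 sd 368 ms^2
  sp <- cohort_spec(list(C = list(n = 10000, mean = c(388, rep(1, 8)),
                                  sd = c(368, rep(0.1, 8)))), seed = 5)
  co <- generate_cohort(sp)
  # oracle: lognormal with mu, sigma from the moment-matching formulas
  sigma2 <- log(1 + (368 / 388)^2)
  mu <- log(388) - sigma2 / 2
  expect_equal(exp(mu + sigma2 / 2), 388, tolerance = 1e-12)
  expect_equal(mean(co$hf_rest), 388, tolerance = 0.05)
  expect_equal(stats::sd(co$hf_rest), 368, tolerance = 0.05)
  expect_true(all(co$hf_rest > 0))
})

test_that("cohort sample moments tighten as n grows", {
  err_for <- function(n) {
    sp <- cohort_spec(list(A = list(n = n, mean = rep(10, 9), sd = rep(8, 9))),
                      seed = 99)
    co <- generate_cohort(sp)
    abs(mean(co$lf_rest) - 10)
  }
  expect_lt(err_for(40000), err_for(400))
})

test_that("cohort spec validation rejects bad groups", {
  expect_error(cohort_spec(list(A = list(n = 1, mean = rep(1, 9), sd = 1))),
               "n")
  expect_error(cohort_spec(list(A = list(n = 5, mean = rep(-1, 9), sd = 1))),
               "mean")
  expect_error(cohort_spec(list(A = list(n = 5, mean = rep(1, 8), sd = 1))),
               "length 9")
})

test_that("identical group specs give chance-level discrimination", {
  sp <- cohort_spec(list(A = list(n = 200, mean = rep(2, 9), sd = rep(1, 9)),
                         B = list(n = 200, mean = rep(2, 9), sd = rep(1, 9))),
                    seed = 33)
  co <- generate_cohort(sp)
  st <- run_study(co, contrasts = list(c("A", "B")))
  ss <- st$contrasts$A_vs_B$sens_spec / 100
  expect_equal(unname(ss["sensitivity"]), 0.5, tolerance = 0.2)
  expect_equal(unname(ss["specificity"]), 0.5, tolerance = 0.2)
})

test_that("digit sequences honor length, range, seed and counting mode", {
  s <- generate_digit_sequence(digit_spec(seed = 1))
  expect_length(s, 100)
  expect_true(all(unclass(s) %in% 0:9))
  expect_identical(unclass(generate_digit_sequence(digit_spec(seed = 8))),
                   unclass(generate_digit_sequence(digit_spec(seed = 8))))
  pure <- generate_digit_sequence(digit_spec(p_count = 1, seed = 3), start = 0)
  expect_equal(counting_bias(pure), 1)
})

test_that("digit spec validation enforces probability bounds", {
  expect_error(digit_spec(length = 1), "length")
  expect_error(digit_spec(p_count = 1.2), "p_count")
  expect_error(digit_spec(p_count = 0.7, p_repeat_interval = 0.5), "p_count")
})
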