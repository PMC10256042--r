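test_that("Burg estimate of an AR(1) agrees with the Yule-Walker oracle", {
  set.seed(11)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 1000))
  m <- fit_burg(x, 1, fs_hz = 1)
  phi_burg <- -m$a
  phi_yw <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(phi_burg, 0.9, tolerance = 0.06)
  expect_equal(phi_burg, phi_yw, tolerance = 0.02)
  # and with the reference Burg implementation
  ref <- stats::ar.burg(x, aic = FALSE, order.max = 1)
  expect_equal(phi_burg, as.numeric(ref$ar), tolerance = 1e-6)
})

test_that("white noise yields near-zero AR coefficients", {
  set.seed(12)
  x <- stats::rnorm(5000)
  m <- fit_burg(x, 6, fs_hz = 1)
  expect_true(all(abs(m$a) < 0.1))
})

test_that("constant input gives a degenerate zero-variance model", {
  m <- fit_burg(rep(5, 100), 4, fs_hz = 1)
  expect_true(m$degenerate)
  expect_equal(m$noise_variance, 0)
  psd <- ar_psd(m)
  expect_true(all(psd$power == 0))
})

test_that("order and length preconditions are enforced", {
  expect_error(fit_burg(stats::rnorm(20), 10, fs_hz = 1), "order")
  expect_error(fit_burg(stats::rnorm(20), 0, fs_hz = 1), "order")
})

test_that("reflection coefficients are always within [-1, 1]", {
  set.seed(13)
  for (i in 1:20) {
    x <- 800 + 30 * sin(2 * pi * 0.25 * (1:40) * 0.8) + stats::rnorm(40, 0, i)
    m <- fit_burg(x, 12, fs_hz = 1.25)
    expect_true(all(abs(m$k) <= 1))
  }
})

test_that("white-noise PSD is flat and integrates to the variance", {
  set.seed(14)
  x <- stats::rnorm(4000, sd = 3)
  m <- fit_burg(x, 2, fs_hz = 2)
  psd <- ar_psd(m)
  tot <- sum(diff(psd$freq_hz) *
               (psd$power[-1] + psd$power[-nrow(psd)]) / 2)
  expect_equal(tot, stats::var(x), tolerance = 0.05)
  expect_lt(stats::sd(psd$power) / mean(psd$power), 0.2)
})

test_that("an AR(2) resonance peaks at its design frequency", {
  # oracle: analytic AR(2) with conjugate poles at r, +/- 2 pi f0 / fs
  fs <- 2
  f0 <- 0.25
  r <- 0.95
  phi1 <- 2 * r * cos(2 * pi * f0 / fs)
  phi2 <- -r^2
  set.seed(15)
  x <- as.numeric(stats::arima.sim(list(ar = c(phi1, phi2)), 4000))
  m <- fit_burg(x, 2, fs_hz = fs)
  psd <- ar_psd(m, seq(0, fs / 2, by = 1e-4))
  f_peak <- psd$freq_hz[which.max(psd$power)]
  # analytic peak of the true AR(2) spectrum
  true_psd <- function(f) {
    om <- 2 * pi * f / fs
    1 / Mod(1 - phi1 * exp(-1i * om) - phi2 * exp(-2i * om))^2
  }
  grid <- seq(0.2, 0.3, by = 1e-5)
  f_true <- grid[which.max(true_psd(grid))]
  expect_equal(f_peak, f_true, tolerance = 0.01)
})

test_that("Parseval holds for every window of a noisy modulated trace", {
  rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, lf_amp_ms = 20,
                                     hf_amp_ms = 30, white_noise_sd_ms = 3,
                                     seed = 11))
  u <- resample_uniform(filter_rr_range(rr))
  t_s <- u$t_s
  for (tt in seq(30, t_s[length(t_s)], by = 10)) {
    idx <- which(t_s > tt - 30 + 1e-9 & t_s <= tt + 1e-9)
    w <- u$values_ms[idx]
    m <- fit_burg(w, min(floor(length(w) / 3), 20), fs_hz = u$fs_hz)
    psd <- ar_psd(m)
    tot <- sum(diff(psd$freq_hz) *
                 (psd$power[-1] + psd$power[-nrow(psd)]) / 2)
    expect_equal(tot, mean((w - mean(w))^2), tolerance = 0.02)
  }
})

test_that("band integration recovers sinusoid power with concentration", {
  rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, hf_amp_ms = 30,
                                     seed = 2))
  p <- run_subject(rr)$periods
  expect_equal(mean(p$hf_ms2), 450, tolerance = 0.1)
  # concentration: HF captures >= 90% of total power, LF < 10% of HF
  expect_gt(mean(p$hf_ms2) / mean(p$lfhf_sum_ms2), 0.9)
  expect_lt(mean(p$lf_ms2), 0.1 * mean(p$hf_ms2))
})

test_that("band_power validates its band and zero signal gives zero", {
  m <- fit_burg(rep(1, 50) + c(0.001, numeric(49)), 2, fs_hz = 1.25)
  psd <- ar_psd(m)
  expect_error(band_power(psd, c(0.4, 0.15)), "lo < hi")
  expect_error(band_power(psd, c(0.1, 0.9)), "grid")
  zero <- fit_burg(rep(3, 50), 2, fs_hz = 1.25)
  expect_equal(band_power(ar_psd(zero), c(0.15, 0.4)), 0)
})

test_that("trend estimates appear every 2 s from 30 s onward", {
  u60 <- resample_uniform(rr_series(rep(800, 75)))
  tr <- spectral_trend(u60)
  expect_equal(tr$t_s, seq(30, 60, by = 2))
  expect_equal(nrow(tr), 16)

  rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, seed = 1))
  tr220 <- spectral_trend(resample_uniform(filter_rr_range(rr)))
  expect_equal(nrow(tr220), 96)
  expect_true(all(tr220$lf_ms2 >= 0 & tr220$hf_ms2 >= 0))
  expect_equal(tr220$lfhf_sum_ms2, tr220$lf_ms2 + tr220$hf_ms2)
})

test_that("stationary input gives a stable HF trend", {
  rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, hf_amp_ms = 30,
                                     white_noise_sd_ms = 3, seed = 17))
  tr <- spectral_trend(resample_uniform(filter_rr_range(rr)))
  expect_lt(stats::sd(tr$hf_ms2) / mean(tr$hf_ms2), 0.5)
})

test_that("doubling modulation amplitude quadruples band power", {
  hf_of <- function(amp) {
    rr <- generate_rr_trace(trace_spec(mean_rr_ms = 800, hf_amp_ms = amp,
                                       white_noise_sd_ms = 2, seed = 19))
    mean(spectral_trend(resample_uniform(filter_rr_range(rr)))$hf_ms2)
  }
  expect_equal(hf_of(40) / hf_of(20), 4, tolerance = 0.2)
})
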