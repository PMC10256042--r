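# shared fixtures, built in code

digits_of <- function(s) as.integer(strsplit(s, "")[[1L]])

# two-group Gaussian cohort with identity covariance and Mahalanobis
# separation `delta` spread equally over the nine features
gaussian_cohort <- function(n_pos, n_neg, delta, seed) {
  p <- 9L
  mu <- rep(delta / sqrt(p), p)
  set.seed(seed)
  xp <- matrix(stats::rnorm(n_pos * p), n_pos) +
    matrix(mu, n_pos, p, byrow = TRUE)
  xn <- matrix(stats::rnorm(n_neg * p), n_neg)
  colnames(xp) <- colnames(xn) <- hrv_feature_names()
  out <- rbind(data.frame(group = "pos", xp), data.frame(group = "neg", xn))
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(nrow(out))), out)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# hand-built spectral trend with prescribed per-condition values
constant_trend <- function(times, lf, hf, ratio = lf / hf, hr = 75) {
  out <- data.frame(t_s = times, lf_ms2 = lf, hf_ms2 = hf,
                    lfhf_sum_ms2 = lf + hf, lfhf_ratio = ratio, hr_bpm = hr)
  class(out) <- c("spectral_trend", "data.frame")
  out
}
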