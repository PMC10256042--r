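#' Names of the nine discriminant features
#'
#' The feature vector entering the discriminant equation: HF, LF and LF/HF at
#' Rest, plus the Task/Rest and After/Rest ratios of each index (`ratio_*`
#' columns hold LF/HF).
#'
#' @return Character vector of length 9, in equation order.
#' @export
hrv_feature_names <- function() {
  c("hf_rest", "hf_task_rest", "hf_after_rest",
    "lf_rest", "lf_task_rest", "lf_after_rest",
    "ratio_rest", "ratio_task_rest", "ratio_after_rest")
}

# Run `expr` under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

#' Specification of a synthetic R-R trace
#'
#' Describes an R-R recording over the Rest/Task/After paradigm as a
#' piecewise-stationary signal: per condition a mean interval plus sinusoidal
#' modulations in the LF band (default 0.10 Hz, blood-pressure rhythm) and the
#' HF band (default 0.25 Hz, respiratory rhythm), white measurement noise, and
#' occasional artifact beats outside the physiological 273-1500 ms range.
#' Sinusoidal modulation of amplitude `a` contributes a known band power of
#' a^2/2 ms^2, which is what makes spectral recovery checkable in closed form.
#'
#' @param mean_rr_ms Mean R-R interval per condition (ms); each in (273, 1500).
#' @param lf_amp_ms,hf_amp_ms Modulation amplitudes per condition (ms, >= 0).
#'   Scalars are recycled across the three conditions.
#' @param lf_freq_hz LF modulation frequency, inside 0.04-0.15 Hz.
#' @param hf_freq_hz HF modulation frequency, inside 0.15-0.4 Hz.
#' @param white_noise_sd_ms Standard deviation of additive white noise (ms).
#' @param artifact_rate Fraction of beats replaced by out-of-range values,
#'   in [0, 0.2).
#' @param schedule A [condition_schedule()]; defaults to 60/100/60 s.
#' @param seed Integer seed for reproducibility.
#'
#' @return A `trace_spec` list.
#' @export
#' @examples
#' spec <- trace_spec(hf_amp_ms = 30, seed = 1)
#' rr <- generate_rr_trace(spec)
trace_spec <- function(mean_rr_ms = c(800, 750, 820),
                       lf_amp_ms = 0, hf_amp_ms = 0,
                       lf_freq_hz = 0.10, hf_freq_hz = 0.25,
                       white_noise_sd_ms = 0, artifact_rate = 0,
                       schedule = condition_schedule(), seed = NULL) {
  schedule <- as_condition_schedule(schedule)
  k <- nrow(schedule)
  mean_rr_ms <- rep_len(as.numeric(mean_rr_ms), k)
  lf_amp_ms <- rep_len(as.numeric(lf_amp_ms), k)
  hf_amp_ms <- rep_len(as.numeric(hf_amp_ms), k)
  if (any(mean_rr_ms <= 273 | mean_rr_ms >= 1500)) {
    stop_field("mean_rr_ms", "must lie in (273, 1500) ms")
  }
  if (any(lf_amp_ms < 0)) stop_field("lf_amp_ms", "must be >= 0")
  if (any(hf_amp_ms < 0)) stop_field("hf_amp_ms", "must be >= 0")
  if (lf_freq_hz < 0.04 || lf_freq_hz > 0.15) {
    stop_field("lf_freq_hz", "must lie in the LF band 0.04-0.15 Hz")
  }
  if (hf_freq_hz < 0.15 || hf_freq_hz > 0.4) {
    stop_field("hf_freq_hz", "must lie in the HF band 0.15-0.4 Hz")
  }
  if (white_noise_sd_ms < 0) stop_field("white_noise_sd_ms", "must be >= 0")
  if (artifact_rate < 0 || artifact_rate >= 0.2) {
    stop_field("artifact_rate", "must lie in [0, 0.2)")
  }
  structure(list(mean_rr_ms = mean_rr_ms, lf_amp_ms = lf_amp_ms,
                 hf_amp_ms = hf_amp_ms, lf_freq_hz = lf_freq_hz,
                 hf_freq_hz = hf_freq_hz,
                 white_noise_sd_ms = white_noise_sd_ms,
                 artifact_rate = artifact_rate, schedule = schedule,
                 seed = seed),
            class = "trace_spec")
}

#' Generate a synthetic R-R trace
#'
#' Beats are laid down sequentially: the interval terminating at cumulative
#' time t is mean_rr + lf_amp sin(2 pi f_LF t) + hf_amp sin(2 pi f_HF t) +
#' noise, with the condition-specific parameters of the condition containing
#' t. Generation continues until the schedule is covered, so a default
#' paradigm trace spans the full 220 s. Artifact beats overwrite the interval
#' value with a draw outside 273-1500 ms while beat times keep their clean
#' cumulative values, so condition boundaries are unaffected; the range filter
#' is expected to repair them.
#'
#' @param spec A [trace_spec()].
#' @return An [rr_series()] carrying the schedule, with attributes
#'   `artifact_idx` (positions of injected artifacts) and `clean_rr_ms`
#'   (the pre-artifact intervals).
#' @export
generate_rr_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  sch <- spec$schedule
  total_ms <- (sch$onset_s[nrow(sch)] + sch$duration_s[nrow(sch)]) * 1000
  with_seed(spec$seed, {
    t_ms <- numeric(0)
    rr_ms <- numeric(0)
    t <- 0
    repeat {
      cond <- max(which(sch$onset_s * 1000 <= t + 1e-9))
      ts <- t / 1000
      rr <- spec$mean_rr_ms[cond] +
        spec$lf_amp_ms[cond] * sin(2 * pi * spec$lf_freq_hz * ts) +
        spec$hf_amp_ms[cond] * sin(2 * pi * spec$hf_freq_hz * ts)
      if (spec$white_noise_sd_ms > 0) {
        rr <- rr + stats::rnorm(1L, 0, spec$white_noise_sd_ms)
      }
      rr <- max(rr, 1)  # guard: intervals must stay positive
      t <- t + rr
      t_ms <- c(t_ms, t)
      rr_ms <- c(rr_ms, rr)
      if (t >= total_ms) break
    }
    clean <- rr_ms
    artifact_idx <- integer(0)
    if (spec$artifact_rate > 0) {
      hit <- which(stats::runif(length(rr_ms)) < spec$artifact_rate)
      if (length(hit)) {
        low <- stats::runif(length(hit)) < 0.5
        rr_ms[hit] <- ifelse(low,
                             stats::runif(length(hit), 100, 272),
                             stats::runif(length(hit), 1501, 2400))
        artifact_idx <- hit
      }
    }
    out <- rr_series(rr_ms, t_ms, schedule = sch)
    attr(out, "artifact_idx") <- artifact_idx
    attr(out, "clean_rr_ms") <- clean
    out
  })
}

#' Specification of a synthetic feature cohort
#'
#' Describes diagnostic groups by the marginal mean and standard deviation of
#' each of the nine discriminant features (see [hrv_feature_names()]).
#' Band-power features in short-recording HRV are positive and strongly
#' right-skewed (group s.d. is of the order of the mean), so the default
#' sampling distribution is a moment-matched lognormal; a zero-truncated
#' normal is available as an alternative. Features are drawn independently:
#' within-subject correlation across indices is not part of the published
#' group summaries and is deliberately not invented.
#'
#' @param groups Named list; one element per group, each a list with `n`
#'   (subjects, >= 2) and `mean` / `sd` (numeric length 9, in
#'   [hrv_feature_names()] order; `sd` recycled if scalar).
#' @param transform `"lognormal"` (moment-matched; requires positive means)
#'   or `"truncnorm"` (normal truncated at 0).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' sp <- cohort_spec(list(
#'   A = list(n = 5, mean = rep(1, 9), sd = 0),
#'   B = list(n = 5, mean = rep(2, 9), sd = 0)))
#' generate_cohort(sp)
cohort_spec <- function(groups, transform = c("lognormal", "truncnorm"),
                        seed = NULL) {
  transform <- match.arg(transform)
  if (length(groups) < 1L || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    stop_field("groups", "must be a non-empty named list")
  }
  labels <- names(groups)
  groups <- lapply(labels, function(g) {
    x <- groups[[g]]
    n <- as.integer(x$n)
    m <- as.numeric(x$mean)
    s <- rep_len(as.numeric(x$sd), length(m))
    if (is.na(n) || n < 2L) stop_field(paste0(g, "$n"), "must be >= 2")
    if (length(m) != 9L) stop_field(paste0(g, "$mean"), "must have length 9")
    if (any(s < 0)) stop_field(paste0(g, "$sd"), "must be >= 0")
    if (transform == "lognormal" && any(m <= 0)) {
      stop_field(paste0(g, "$mean"),
                 "must be > 0 for the lognormal transform")
    }
    list(n = n, mean = m, sd = s)
  })
  names(groups) <- labels
  structure(list(groups = groups, transform = transform, seed = seed),
            class = "cohort_spec")
}

# draw n values with given mean/sd from the configured positive family
draw_feature <- function(n, m, s, transform) {
  if (s == 0) return(rep(m, n))
  if (transform == "lognormal") {
    sigma2 <- log(1 + (s / m)^2)
    mu <- log(m) - sigma2 / 2
    stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
  } else {
    # normal truncated at 0 via inverse-CDF sampling
    p0 <- stats::pnorm(0, mean = m, sd = s)
    u <- stats::runif(n, p0, 1)
    stats::qnorm(u, mean = m, sd = s)
  }
}

#' Generate a synthetic cohort of discriminant features
#'
#' Each subject receives the nine features drawn independently from the
#' group's moment-matched marginal distributions.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table` data frame: `subject_id`, `group`, then the nine
#'   feature columns of [hrv_feature_names()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(names(spec$groups), function(g) {
      gs <- spec$groups[[g]]
      feats <- vapply(seq_len(9L), function(j) {
        draw_feature(gs$n, gs$mean[j], gs$sd[j], spec$transform)
      }, numeric(gs$n))
      feats <- matrix(feats, nrow = gs$n)
      colnames(feats) <- hrv_feature_names()
      data.frame(group = g, feats, check.names = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(nrow(out))), out,
                      check.names = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Specification of a synthetic digit sequence
#'
#' Models output of the 1-Hz random-number-generation task (100 digits, 0-9)
#' as a mixture: with probability `p_count` the next digit is the previous
#' one plus or minus 1 (the "counting" habit; at 0 or 9 the step reflects
#' inward), with probability `p_repeat_interval` the previous inter-digit
#' difference is repeated (clamped to 0-9), and otherwise the digit is drawn
#' uniformly.
#'
#' @param length Sequence length (default 100, the task length).
#' @param p_count Probability of a +/-1 counting step.
#' @param p_repeat_interval Probability of repeating the last difference.
#' @param seed Integer seed.
#' @return A `digit_spec` list.
#' @export
digit_spec <- function(length = 100L, p_count = 0, p_repeat_interval = 0,
                       seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 2L) stop_field("length", "must be >= 2")
  if (p_count < 0 || p_count > 1) stop_field("p_count", "must be in [0, 1]")
  if (p_repeat_interval < 0 || p_repeat_interval > 1) {
    stop_field("p_repeat_interval", "must be in [0, 1]")
  }
  if (p_count + p_repeat_interval > 1) {
    stop_field("p_count", "p_count + p_repeat_interval must be <= 1")
  }
  structure(list(length = length, p_count = p_count,
                 p_repeat_interval = p_repeat_interval, seed = seed),
            class = "digit_spec")
}

#' Generate a synthetic digit sequence
#'
#' @param spec A [digit_spec()].
#' @param start Optional first digit (0-9); drawn uniformly when `NULL`.
#' @return Integer vector of digits in 0-9, class `digit_sequence`.
#' @export
#' @examples
#' counting_bias(generate_digit_sequence(digit_spec(p_count = 1, seed = 1)))
generate_digit_sequence <- function(spec, start = NULL) {
  stopifnot(inherits(spec, "digit_spec"))
  with_seed(spec$seed, {
    n <- spec$length
    s <- integer(n)
    s[1L] <- if (is.null(start)) sample(0:9, 1L) else as.integer(start)
    if (s[1L] < 0L || s[1L] > 9L) stop_field("start", "must be a digit 0-9")
    for (i in 2:n) {
      u <- stats::runif(1L)
      if (u < spec$p_count) {
        step <- sample(c(-1L, 1L), 1L)
        if (s[i - 1L] == 0L) step <- 1L
        if (s[i - 1L] == 9L) step <- -1L
        s[i] <- s[i - 1L] + step
      } else if (u < spec$p_count + spec$p_repeat_interval && i > 2L) {
        s[i] <- min(max(s[i - 1L] + (s[i - 1L] - s[i - 2L]), 0L), 9L)
      } else {
        s[i] <- sample(0:9, 1L)
      }
    }
    structure(s, class = "digit_sequence")
  })
}

#' Read and write digit sequences
#'
#' Plain-text format: one line, one character per digit.
#'
#' @param path File path.
#' @return `read_digit_sequence()` returns a `digit_sequence` integer vector.
#' @export
read_digit_sequence <- function(path) {
  line <- paste(readLines(path), collapse = "")
  s <- as.integer(strsplit(line, "")[[1L]])
  if (anyNA(s) || any(s < 0L | s > 9L)) {
    stop("digit sequence file must contain only digits 0-9", call. = FALSE)
  }
  structure(s, class = "digit_sequence")
}

#' @rdname read_digit_sequence
#' @param s A digit sequence (integer vector, values 0-9).
#' @export
write_digit_sequence <- function(s, path) {
  writeLines(paste(unclass(s), collapse = ""), path)
  invisible(path)
}
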