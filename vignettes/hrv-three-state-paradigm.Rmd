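---
title: "Frequency-domain HRV over a rest-task-recovery paradigm: methods and design"
author: "hrvtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain HRV over a rest-task-recovery paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvtriad)
```

## The problem

Major depressive disorder (MDD) and chronic fatigue syndrome (CFS) overlap
symptomatically but call for different treatment, and both are accompanied by
autonomic dysregulation that heart rate variability (HRV) can index. A short
three-behavioral-state protocol — about 60 s of seated rest (*Rest*), 100 s
of an oral random-number-generation task (*Task*), and 60 s of post-task rest
(*After*) — probes three things at once: the autonomic baseline, the
reactivity to a mild cognitive load, and the recovery from it. This package
implements the full analysis chain for that paradigm: R-R interval cleaning,
maximum-entropy spectral HRV indices on a sliding window, per-condition
features, randomness indices of the task output, linear-discriminant
classification of diagnostic groups, and summary-level statistics. Because no
raw recordings are public, a synthetic-data layer generates RR traces, digit
sequences and feature cohorts with known ground truth, which is what the test
suite exercises.

## Preprocessing

R-R intervals outside 273–1500 ms are treated as paroxysmal beats or
detection failures and replaced by the average of the nearest in-range
interval on each side (`filter_rr_range()`). Two edge rules make the
published replacement rule total: an edge beat with a single valid neighbor
copies that neighbor, and runs of consecutive bad beats all use the nearest
*originally* valid values on each side, so the result is independent of
processing order and a second pass is a no-op (idempotence is a tested
invariant). Replacement happens before the beat timeline is rebuilt from the
cumulative repaired intervals. A recording with more than half of its beats
out of range is rejected as unusable rather than repaired.

Spectral estimation needs evenly spaced samples, so the beat-stamped
tachogram is interpolated onto a uniform grid at the mean heart rate,
`fs = 1/mean(RR)` (`resample_uniform()`), spanning first to last beat with
both endpoints on the grid. Cubic splines are the default interpolant — the
common choice in HRV practice, smooth enough not to manufacture
high-frequency power; a linear mode exists because interpolating a
linear-in-time tachogram is then exact, which the tests exploit. Heart rate
is the per-beat conversion `HR = 60000/RR` in beats/min.

## Maximum-entropy spectra

The spectral engine is Burg's method (`fit_burg()`): reflection coefficients
chosen to minimise summed forward and backward prediction-error power under
the Levinson recursion. It is the canonical realisation of maximum-entropy
spectral estimation and the reason this paradigm works at all: a 30-s window
at a typical 1.25-Hz resampling rate has only ~37 samples, far too few for a
periodogram to resolve the LF band, while an AR model resolves both bands
cleanly. Windows are mean-detrended (DC removal only — slope detrending
would distort the LF band). The default order is `min(floor(N/3), 20)`,
i.e. about 12 for a standard window: enough poles for one peak per band plus
the noise floor, small enough to stay stable at N ≈ 37.

The one-sided PSD is `S(f) = 2 sigma^2 / (fs |A(e^{-i2*pi*f/fs})|^2)`
(`ar_psd()`), normalised so the integral over `[0, fs/2]` equals the process
variance. For Burg fits this is an identity, because the stage-0 prediction
error is the biased sample variance — which gives the suite a sharp check:
trapezoidal integration of every fitted window's PSD must return that
window's variance to within 2% (Parseval).

Two numerical choices deserve a note:

* **Pole-aware integration grid.** On a nearly noise-free window Burg drives
  its poles to within 1e-9 of the unit circle and the spectrum collapses
  toward a line — far narrower than any fixed frequency grid. The default
  grid is therefore uniform at 0.001 Hz *augmented with geometrically spaced
  points around every pole of radius > 0.9*, which lets the trapezoid
  capture the full mass of quasi-singular peaks. Without this, band powers
  of clean sinusoidal test signals are wrong by orders of magnitude in
  either direction depending on whether a grid point lands near the peak.
* **Band edges.** LF is integrated over the closed band 0.04–0.15 Hz and HF
  over 0.15–0.4 Hz (`band_power()` adds the exact band endpoints to the
  grid by interpolation). The shared 0.15-Hz point closes LF and opens HF,
  receiving half trapezoid weight in each, so LF + HF equals the 0.04–0.4 Hz
  integral exactly. Power below 0.04 Hz is never reported: a 30-s window
  cannot resolve very-low-frequency components.

`spectral_trend()` slides this machinery along the recording: an estimate
every 2 s from t = 30 s onward, each summarising the trailing 30-s window
(so a 60-s record yields 16 estimates, the 220-s paradigm 96). The LF/HF
ratio is guarded: if HF falls below 1e-6 ms² the ratio is reported as
undefined (`NA`) rather than as a meaningless large number.

## Condition averaging and features

`period_means()` averages the trend inside each scheduled condition from
30 s after its onset to its end. The 30-s skip has a double role: it drops
the physiological carry-over from the previous state, and — because each
estimate is stamped at its window *end* — it exactly excludes every window
that reaches back across the boundary, so condition means never mix states
(a step-trend fixture in the tests proves no bleed). Each condition must be
longer than 30 s for its averaging interval to be non-empty; with the
default 60/100/60-s schedule, Rest/Task/After average 16/36/16 estimates.

`build_features()` assembles the nine discriminant predictors: the Rest
levels of HF, LF and LF/HF, and the Task/Rest and After/Rest ratios of each.
Ratios are ratios of period means — not means of per-estimate ratios — so HF
rescaling multiplies the level features and leaves the ratio features
untouched (a tested equivariance). Zero or undefined Rest denominators are
an error naming the index, not a silent `Inf`.

## Randomness indices of the digit task

The task output — 100 digits, 0–9, at 1 Hz — is scored by three proportions
in [0, 1]. Counting bias (CB) is the fraction of adjacent pairs stepping by
exactly ±1; adjacency is non-modular (9→0 is not counting) because no wrap
rule is documented for the paradigm. Interval bias (IB) is the fraction of
adjacent *signed* inter-digit differences that repeat — "the same interval"
is read as the same step, so +2 followed by −2 does not count. The RNG index
is the classical digram-concentration ratio
`sum(n_ij log n_ij) / sum(n_i log n_i)` over the 10×10 first-order pair
table with row marginals `n_i`: 0 when every occupied digram is a singleton,
1 when each row's mass sits in one cell; an all-singleton denominator is
defined as 0 and flagged in the documentation. The ratio is base-invariant
only when numerator and denominator share a base; natural log is used. Under
these definitions a uniform random sequence gives CB = 0.18 (18 of 100
ordered pairs differ by 1) and IB = 0.05 (50 of 1000 ordered triples repeat
a step) — both frozen into the tests from exhaustive enumeration.

## Discriminant analysis

`fit_lda()` is the two-group Fisher discriminant with equal priors:
`w = S_pooled^-1 (mu_pos - mu_neg)`, discriminant point at the projected
midpoint of the group means, and the sign convention that a positive D-score
supports the first (disease) label. Equal priors and the midpoint cut are
the documented defaults because the published analysis reports neither
priors nor a cut optimisation; features enter in raw units since LDA is
affine-invariant (an invariance the tests verify under random invertible
feature transforms). A D-score of exactly 0 is counted positive so the
positive/negative bins are exhaustive. Sensitivity and specificity are
resubstitution (training-set) percentages rounded to one decimal — matching
how the published confusion table is laid out — with leave-one-out
cross-validation available as a clearly separate mode. Group separation is
summarised by the Mahalanobis distance with a p-value from the two-sample
Hotelling T² → F transform on (p, n_A + n_B − p − 1) degrees of freedom. A
numerically singular pooled covariance receives one ridge of
`1e-6 * trace/p` on the diagonal, recorded on the model.

## Summary-level statistics

Three statistics are recomputable from printed tables alone and are
implemented on (n, mean, sd) summaries: the Pearson chi-square on a
contingency table (no continuity correction), the pooled-variance two-sample
t, and the one-way ANOVA F rebuilt from between/within sums of squares. The
pooled (Student) rather than Welch t is the deliberate choice: on the
published LF/HF-at-Rest summaries it reproduces the printed t = 2.994 to
within input rounding, while Welch does not (≈ 3.07). Repeated-measures
ANOVA and the post hoc tests of the original analysis need per-subject data
that summaries cannot supply and are intentionally out of scope; on
synthetic cohorts the standard R routines (`aov`, `kruskal.test`) apply
directly.

## The synthetic-data layer

`generate_rr_trace()` emulates a paradigm recording as a piecewise-stationary
signal: per condition a mean interval in (273, 1500) ms plus fixed-frequency
sinusoidal modulations in the LF band (default 0.10 Hz, the blood-pressure
rhythm) and HF band (default 0.25 Hz, the respiratory rhythm), white noise,
and occasional artifact beats outside the physiological range. Sinusoids
rather than band-limited noise are the default because a sinusoid of
amplitude `a` has the closed-form band power `a^2/2`, which turns spectral
recovery into an exact test; band-limited-noise modulation can be emulated
by summing specs. Artifacts *replace* interval values while beat times keep
their clean cumulative values, so condition boundaries stay fixed and the
range filter's repair is what restores consistency. Condition transitions
are instantaneous — the pre-experiment adaptation period of the protocol is
not simulated, since the pipeline only consumes the 220-s paradigm window.

`generate_cohort()` draws the nine features per subject independently from
moment-matched marginals. Band powers in short-window HRV are positive and
strongly right-skewed (published group s.d.s are of the order of the means),
so the default family is the lognormal with `sigma^2 = log(1 + (s/m)^2)`,
`mu = log(m) - sigma^2/2`; a zero-truncated normal is the alternative for
near-symmetric quantities such as heart rate. `reference_cohort_spec()`
parameterises the three diagnostic groups from the published summaries,
deriving each ratio feature's mean from the ratio of period means and its
spread from the combined coefficient of variation of numerator and
denominator. What the generator deliberately does **not** model is the
within-subject correlation across the nine features — it is simply not
recoverable from published group marginals, and inventing it would fake
information. The consequence is visible and documented in the analysis
scripts: cohorts resampled this way separate *materially better than
chance* but less sharply than the real cohort, whose discriminant exploited
exactly those correlations. The package therefore reports, and never
asserts, agreement with the published sensitivity/specificity on synthetic
cohorts.

`generate_digit_sequence()` is a three-way mixture per step: a ±1 counting
step with probability `p_count` (reflecting inward at 0 and 9, so a pure
counting sequence has CB = 1 exactly), a repeat of the previous difference
with probability `p_repeat_interval` (clamped to the digit range), otherwise
a uniform draw.

All generators take a `seed` and restore the caller's RNG state, so
identical specs give bit-identical output without side effects.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data at
moderate sizes chosen to keep the whole suite fast while leaving Monte-Carlo
noise well inside the asserted tolerances: 220-s paradigm traces (~96
spectral windows each), a 3 × {10, 30, 60} ms × {0.10, 0.25} Hz band-recovery
grid at 3-ms white noise, 100 replicates of AR(1) recovery at n = 1000,
LDA recovery at n = 500 per group, and cohort-moment checks at n = 10⁴.
`scripts/acceptance.R --seed <int> --out <path>` recomputes every headline
quantity from scratch through the installed package and writes them as JSON;
all randomness derives from the single `--seed`.

## Known limitations

* Quantitative agreement with the proprietary spectral tool used for the
  original recordings cannot be asserted; its AR order and integration
  scheme are unpublished. The package asserts analytic properties (Parseval,
  band recovery, stability) instead.
* The exact historical definitions of CB and IB live in an earlier
  publication that does not print formulas; the implementations here follow
  the parenthetical glosses (frequencies of ±1 steps and of repeated
  intervals) and are versioned so alternative definitions can be swapped in.
* Synthetic cohorts lack within-subject feature correlation (above), and
  synthetic RR traces use fixed-frequency sinusoids rather than the
  broadband, nonstationary modulation of real recordings — passing tests
  demonstrate correctness of the machinery, not clinical performance.
* The discriminant is fit and evaluated by resubstitution to mirror the
  published table; leave-one-out numbers are reported alongside and are, as
  expected, a few points lower.
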