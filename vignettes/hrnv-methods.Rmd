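---
title: "Heart rate n-variability: models, parameters and the risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart rate n-variability: models, parameters and the risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrnv)
```

## The representation

Conventional heart rate variability (HRV) characterises one sequence of
normal-to-normal (NN) R-R intervals with one set of descriptive parameters.
Heart rate n-variability (HRnV) multiplies the views on the same recording:
every `n` adjacent NN intervals are summed into a composite interval, either
non-overlapping (stride `m = n`, the RRnI sequence, parameter family
`HR{n}V`) or overlapping (stride `m < n`, the RRnIm sequence, family
`HR{n}V{m}`, consecutive composites sharing `n - m` beats). A parent series
of length $\hat N$ yields $\lfloor(\hat N - n)/m\rfloor + 1$ composites, and
up to `n_max` one obtains $1 + (n_{\max}-1) + n_{\max}(n_{\max}-1)/2$
sequence sets. For 5–6 minute single-lead recordings `n_max = 3` is the
sensible default — six sets (HRV, HR2V, HR2V1, HR3V, HR3V1, HR3V2), 21
conventional plus 115 composite parameters — because composite sequences
shrink by a factor `n/m` and spectral and entropy estimates degrade quickly
below roughly a hundred points.

Design choices the definition leaves open, fixed here once:

* **Start offset.** Every sequence starts at the first interval; alternative
  phase offsets would give `m` near-copies of each non-overlapping sequence
  and are not part of the representation.
* **Remainders.** Trailing intervals that do not fill a complete window are
  dropped; partial windows would break the equal-`n` interpretation of every
  composite.
* **Timestamps.** A composite inherits the cumulative end-time of its last
  constituent beat. This keeps the true (uneven) time axis, which is what
  the Lomb–Scargle estimator needs; it is also why excised ectopic intervals
  leave honest gaps rather than being merged into their neighbours.
* **Units.** Intervals are carried in milliseconds throughout.

## The parameter panel

Per sequence the package computes the standard short-term panel: mean NN,
SDNN, RMSSD, skewness, kurtosis, triangular index, NN50/pNN50 — plus, on
composite sequences only, NN50n/pNN50n with threshold `50·n` ms (a composite
interval is `n` beats long, so the 50 ms criterion is scaled with it) —
total/VLF/LF/HF power, normalised LF/HF and their ratio, Poincaré SD1/SD2,
approximate and sample entropy, and DFA α1/α2.

Conventions that differ between toolboxes, with this package's defaults:

* **SDNN denominator**: sample (`N−1`); `sd_type = "population"` switches.
* **pNN50 denominator**: the number of intervals (not of successive pairs);
  `pnn_denominator = "pairs"` switches. The same denominator is used for
  pNN50n.
* **Threshold strictness**: NN50 counts differences strictly *exceeding*
  the threshold.
* **Kurtosis**: Pearson convention (normal → 3); `kurtosis_type = "excess"`
  switches. This matters when comparing against toolboxes that report
  excess kurtosis.
* **Triangular index**: bin width 1/128 s (7.8125 ms), aligned to multiples
  of the bin width, *not* scaled with `n`. Configurable via
  `tri_bin_width`.
* **Poincaré SD1** is defined as the RMS distance of the lag-1 scatter from
  the line of identity, so `SD1 = RMSSD/√2` is an exact algebraic identity.
  A variance-based (centred) SD1 differs by the mean successive difference,
  which is nonzero on any finite series; the uncentred definition is the
  one under which the identity — a useful internal consistency check —
  holds to machine precision. SD2 follows from
  `SD1² + SD2² = 2·SDNN²`, truncated at zero.

### Spectral estimation

Composite sequences are unevenly sampled by construction, and cleaning can
leave gaps; the package therefore estimates the spectrum with the classical
Lomb–Scargle periodogram on the native end-time axis — no resampling, mean
subtraction only (no polynomial detrend; VLF power is sensitive to this
choice and it is stated rather than hidden). The density is scaled so that
its trapezoidal integral over the grid returns variance-scale power in ms²:
a sinusoidal modulation of amplitude $a$ integrates to $a^2/2$, and on
evenly sampled input the integral matches the series variance within a few
percent (a Parseval check in the test suite).

The grid starts at `1/(ofac·T)` with fourfold oversampling (`psd_ofac = 4`)
and extends to `max(0.4, 0.5/median interval)` Hz, so the conventional HF
upper edge is covered even for `HR3V` sequences whose mean beat rate is only
~0.4 Hz. Band powers integrate half-open bands VLF (0, 0.04], LF
(0.04, 0.15], HF (0.15, 0.4] Hz with linear interpolation at the edges, so
the three bands partition the total exactly and no bin is counted twice.
The edges are *not* rescaled with `n`: the conventional cut-offs are used
for every sequence set, and the band edges are exposed in `hrnv_config()`
for users who wish to explore rescaled bands. Normalised powers use
`lf_norm = 100·LF/(LF+HF)` and `hf_norm = 100 − lf_norm`, which makes their
sum exactly 100 by construction.

### Entropies and DFA

ApEn and SampEn use embedding dimension `m = 2` and tolerance `r = 0.2·SD`
of the analysed sequence — so a composite sequence gets composite-scale
tolerance and both statistics are invariant under affine rescaling. ApEn
includes self-matches; SampEn excludes them and counts pairs over the first
`N − m` templates. When no template pair matches at length `m + 1`, SampEn
is mathematically undefined; the package returns `NA` with an
`undefined` attribute instead of a large sentinel value. Short
non-overlapping composite sequences (under ~200 points) are exactly where
this happens in practice, and sentinel blow-ups there are an artifact, not a
measurement; downstream model code treats them as missing (mean imputation
with an indicator below 10% missingness, exclusion of the parameter above).

DFA integrates the centred series, detrends linearly in non-overlapping
boxes, and fits log–log slopes over 4–16 beats (α1) and 16–64 beats (α2).
The short-scale window of the standard estimator carries a known
finite-size bias: for white noise the expected squared fluctuation behaves
like $\sigma^2 (s^2-4)/(6s)$, whose fitted slope over 4–16 is ≈ 0.59 rather
than the asymptotic 0.5 (the package reproduces this, and the test suite
asserts the biased range deliberately). The asymptotic exponents — 0.5 for
white noise, 1.5 for Brownian motion, 1.0 for 1/f noise — are recovered on
the long-range window, and no multiplicative bias correction is applied
because it would shift the slope of correlated signals by the same amount.
Sequences shorter than four times the largest scale get a restricted scale
range with a warning; α2 is `NA` when no usable long-range scale remains.

## ECG front-end

`detect_beats()` is an energy-based QRS detector (band-pass 5–15 Hz,
derivative, squaring, 150 ms integration window, adaptive signal/noise
thresholds, 200 ms refractory period, apex refinement on the raw signal).
`clean_nn()` excises intervals outside 300–2000 ms or deviating more than
20% from the running median of the last five accepted intervals — values
chosen to match common toolbox defaults, all configurable — and rejects
records losing more than 20% of their intervals as non-sinus or noisy.
Excision (not interpolation or merging) keeps the NN sequence honest at the
cost of timestamp gaps, which the Lomb estimator tolerates by design; the
cleaning rule is idempotent.

## The synthetic generators, and what they do not emulate

`simulate_rr()` generates intervals as a mean plus two sinusoidal
modulations (defaults 0.1 Hz and 0.25 Hz — the canonical LF and HF
rhythms) plus white jitter, with optional ectopic short–long couplets, over
330 s (the midpoint of a five-to-six-minute recording). A sinusoid of
amplitude `a` ms carries band power exactly `a²/2` ms², which is the point:
the generator's ground truth is closed-form. It is *not* an integral pulse
frequency modulation model; it does not emulate respiratory sinus
arrhythmia's frequency wander, circadian drift, or the inter-parameter
correlation structure of real HRV panels. Passing spectral-recovery tests
on this generator shows the estimator chain is calibrated, not that real
recordings behave this simply. `simulate_ecg()` places a fixed
P-QRS-T Gaussian template at each beat time, so the detector round-trip has
sample-level ground truth.

`simulate_cohort()` draws a 795-patient table (31% thirty-day MACE
prevalence) whose outcome follows a logistic model with the adjusted odds
ratios of a reference 16-predictor chest-pain model as generating
coefficients; the intercept is solved numerically for the target
prevalence. Age, sex and the HRV/HRnV predictor marginals follow reference
cohort descriptives; diastolic blood pressure, pain score and the 12-lead
ECG finding prevalences have no reference values and are invented,
plausible defaults (BP ~ N(74, 12) mmHg, pain
score a clipped rounded N(5, 2), ST-elevation/depression/Q-wave at
7/14/9%). The troponin code is derived from a log-normal concentration via
`encode_troponin()` (0: ≤ 0.03 ng/mL; 1: ≤ 3× the limit; 2: above). No
correlation between predictors is modelled.

## The risk pipeline

`fit_mace_model()` mirrors the clinical workflow: univariable logistic
screening (keep p < 0.2, flag and drop separated predictors), backward
stepwise elimination (drop while the largest Wald p exceeds 0.05; an AIC
mode via `criterion = "aic"`), leave-one-out cross-validated probabilities,
and ROC analysis (trapezoidal AUC — identical to the Mann–Whitney
concordance — DeLong CI, optimal cut-off by Euclidean distance to the
(0, 1) corner, Wald binomial CIs on the operating-point metrics).

Selection inside versus outside cross-validation is genuinely ambiguous in
this workflow's usual description. The default (`cv = "fixed"`) selects
once on the full data and cross-validates only the coefficients — the
common practice in clinical modelling, and cheap at n ≈ 800 — while
`cv = "strict"` repeats screening and stepwise selection in every fold,
which is the optimism-free variant; comparing the two AUCs exposes the
selection optimism. Whether cardiac history (0/1/2) enters as numeric or
categorical is likewise unstated; it is treated as numeric, consistent with
a single reported odds ratio per variable.

## Problem sizes and numerical checks

The verification suite uses: 1,000 random series (lengths 10–500) for the
window-sum and count-law oracle; 200 series (lengths 50–300) for the
O(N²) entropy oracles at 1e-9; length 2¹⁴ draws for the DFA limits
(asymptotic window, ±0.05 white / ±0.1 Brownian); three replicate
100,000-patient cohorts for log-OR recovery within ±10% (averaging the
replicate refits is the usual parameter-recovery design; the smallest
generating coefficients sit near the single-cohort Wald noise floor at that
n); ten outcome permutations of a 1,000-patient cohort for the chance-level
LOOCV AUC band [0.45, 0.55] (leave-one-out on permuted outcomes anti-fits
and is biased slightly below 0.5, so single permutations scatter widely);
and 500 small random datasets for exact AUC/pair-counting agreement. The
2×2 male-sex split of a reference cohort (188/59 events vs 354/194
non-events) reproduces its univariable odds ratio ≈ 1.746 through the
screening code.

## Known limitations

* No numeric parity with any particular HRV toolbox is claimed: windowing,
  detrending and entropy tolerances differ between tools, and the panel's
  absolute values shift accordingly. All conventions are stated and
  configurable.
* The cohort generator's independence between predictors understates the
  collinearity of real HRV/HRnV panels; selection behaviour on real data
  will be less stable than on simulated cohorts.
* Band edges are not adapted for composite sequences even though their
  effective Nyquist rate drops with `n`; interpretation of HF power for
  `n = 3` sequences deserves caution.
* The ECG synthesizer's fixed template does not model morphology changes,
  baseline wander or muscle noise beyond additive white noise.
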