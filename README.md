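# hrnv

Heart rate *n*-variability (HRnV) analysis and chest-pain risk modelling in R.

## The problem

Conventional heart rate variability (HRV) reduces a 5–6 minute ECG to one
sequence of normal-to-normal (NN) R-R intervals and one set of descriptive
parameters — often too little signal for clinical prediction tasks such as
risk-stratifying emergency-department chest-pain patients for 30-day major
adverse cardiac events (MACE). HRnV is a multi-scale extension: every *n*
adjacent NN intervals are summed into a composite interval, either
non-overlapping (stride *m = n*, sequence RRnI, parameter family HR*n*V) or
overlapping (stride *m < n*, sequence RRnI*m*, family HR*n*V*m*; consecutive
composites share *n − m* beats). A parent series of length N̂ yields
⌊(N̂ − n)/m⌋ + 1 composites, and with upper limit `n_max` one obtains
1 + (n_max − 1) + n_max(n_max − 1)/2 sequence sets. With `n_max = 3` —
appropriate for short recordings — that is six sets (HRV, HR2V, HR2V1,
HR3V, HR3V1, HR3V2) carrying 21 conventional plus 115 composite parameters.

On every sequence the package computes the full short-term panel: mean NN,
SDNN, RMSSD, skewness, kurtosis, triangular index, NN50/pNN50 (plus the
composite-specific NN50n/pNN50n with threshold 50·*n* ms), Lomb–Scargle
band powers (VLF ≤ 0.04, LF 0.04–0.15, HF 0.15–0.4 Hz) with normalised
units and LF/HF, Poincaré SD1/SD2, approximate and sample entropy, and DFA
α1/α2. An ECG front-end (energy-based QRS detection plus ectopic-interval
excision) converts raw single-lead traces into NN series, synthetic
generators provide records and patient cohorts with known ground truth, and
`fit_mace_model()` runs the downstream clinical pipeline: univariable
screening (p < 0.2), backward stepwise logistic regression (drop while max
Wald p > 0.05), leave-one-out cross-validated probabilities and ROC
analysis with a DeLong AUC CI and distance-to-corner optimal cut-off.

## Worked example

```r
library(hrnv)

rr <- simulate_rr(seed = 42)   # 330 s of LF+HF-modulated sinus rhythm
rr
#> <rr_series> 398 NN intervals [sim-rr-seed42]
#>   mean 829.4 ms, range 773-883 ms, duration 330.1 s

p <- hrnv_profile(rr)          # one wide row, 136 parameter columns
round(unlist(p[c("HRV_MeanNN", "HRV_SDNN", "HRV_RMSSD", "HRV_LF_HF",
                 "HR2V_MeanNN", "HR2V1_SampEn", "HR3V2_HFPower")]), 3)
#>    HRV_MeanNN      HRV_SDNN     HRV_RMSSD     HRV_LF_HF   HR2V_MeanNN
#>       829.400        24.253        23.192         1.441      1658.800
#>  HR2V1_SampEn HR3V2_HFPower
#>         1.545       959.048
```

The conventional set reads as usual (mean NN 829 ms, SDNN 24 ms, LF/HF 1.4
for this LF-dominant generator); composite sets scale with *n* (HR2V mean NN
is twice the parent's) and add views — e.g. the overlapping HR2V1 sample
entropy — that the single HRV set cannot provide.

The risk pipeline on a simulated 795-patient cohort (31% MACE prevalence,
outcome generated on a reference 16-predictor odds-ratio scale):

```r
coh <- simulate_cohort(n_patients = 795, seed = 23)
m <- fit_mace_model(coh)
m
#> 30-day MACE risk model (logistic, backward stepwise)
#>   17 candidates -> 14 screened in -> 12 selected
#>   fixed cross-validation: AUC 0.892 (95% CI 0.868-0.916)

m$roc
#> <roc_result> AUC 0.892 (95% CI 0.868-0.916), 255 pos / 540 neg
#>   optimal cut-off 0.2869: sens 83.9%, spec 79.8%, PPV 66.3%, NPV 91.3%
```

`summary(m)` prints the selected variables with adjusted odds ratios and
CIs; `predict(m, newdata)` scores new patients; `hrnv_risk()` writes the
univariable, model and ROC tables as CSVs.

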