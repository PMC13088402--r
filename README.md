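# hvsi

Acoustic scoring of arteriovenous fistula (AVF) function for hemodialysis
vascular access surveillance.

Hemodialysis patients depend on a functioning vascular access, most often a
native AVF. Progressive stenosis silently reduces access blood flow until the
fistula fails; surveillance today relies on Doppler ultrasound, which is
accurate but operator- and equipment-intensive. The bruit audible at the
arteriovenous anastomosis carries hemodynamic information: turbulence
generated by flow through the anastomosis changes in loudness and spectral
content as flow falls and downstream resistance rises. This package
implements a phonoangiographic screening index on that principle, together
with everything needed to evaluate it as a diagnostic test.

## What it computes

**Vascular sound index (0–999).** A mono anastomosis recording (≥ 3 s,
≥ 3 kHz) is resampled to 4 kHz, trimmed to a fixed 5 s analysis epoch, and
converted to a Hann-window short-time Fourier magnitude spectrogram (256 ms
window, 50 % overlap). A 50–1500 Hz band-pass and a 300 Hz low-pass
(4th-order Butterworth magnitude weight) are applied in the frequency domain,
the rectified magnitudes are integrated over frequency and averaged over
time, and the resulting band power *P* is mapped to an integer score

    HVSI = round( 999 · clip( (log₁₀P − log₁₀P_min) / (log₁₀P_max − log₁₀P_min), 0, 1 ) )

Higher scores indicate higher access flow. The clinical protocol scores three
replicate recordings and averages them.

**Doppler hemodynamics.** Brachial artery flow volume and resistance index
in consistent cm units:

    TAV (cm/s)    = MTI (cm/beat) × HR (beats/min) / 60
    FV  (mL/min)  = vessel area (cm²) × TAV (cm/s) × 60
    RI            = (PSV − lowest diastolic velocity) / PSV

**Diagnostic evaluation.** Empirical ROC curves with trapezoid AUC (identical
to the rank statistic with ties counted ½), DeLong 95 % confidence intervals
(stratified bootstrap below 30 per class), Youden-index cutoffs reported at
gap midpoints, confusion statistics (sensitivity/specificity/PPV/NPV, percent,
half-up to one decimal), concordance, and OLS/Pearson association. The test
convention is *positive iff score ≤ cutoff*: a quiet fistula is the alarm.

**Study-design tooling.** Propensity-score logistic models, greedy 1:1
nearest-neighbor matching without replacement (caliper 0.2 × SD of the logit
score) with covariate-balance tables, and multivariable logistic odds ratios
scaled per 100 score units.

**Simulator.** A seeded generative model of anastomosis bruits — flow-scaled
amplitude, cardiac-gated envelope with diastolic floor 1 − RI, band-limited
turbulence whose spectral centroid shifts upward with stenosis — and of
case–control cohorts matching the study structure (stable controls with
FV ≥ 500 mL/min and RI ≤ 0.60; cases shifted low in flow and high in
resistance; vessel bifurcation masking the stenosis signature). A fast
surrogate scoring path shares the audio path's calibration.

**Verification fixture.** The packaged 20-patient verification cohort
(checksum-pinned) and `verify_cutoff()`, which reproduces its published
diagnostic statistics exactly.

## Worked example

```r
library(hvsi)

# score a triplicate of simulated bruits at FV 650 mL/min, RI 0.55
rec <- lapply(1:3, function(s)
  simulate_bruit(bruit_scenario(flow_volume = 650, resistance_index = 0.55,
                                seed = s)))
compute_hvsi(rec)
#> HVSI 471.7 (replicates: 478, 471, 466; calibration default-v1)

# Doppler hemodynamics
m <- doppler_measurement(vessel_area = 0.25, mean_time_integral = 45,
                         heart_rate = 72, peak_systolic_velocity = 95,
                         lowest_diastolic_velocity = 38)
flow_volume(m)       #> 810 mL/min
resistance_index(m)  #> 0.6

# diagnostic performance on a synthetic 101 + 101 cohort
co <- simulate_cohort(101, 101, seed = 42)
hvsi_roc(co$records, "fv<400")
#> ROC: AUC 0.962 (95% CI 0.940-0.983), 63 pos / 139 neg
#> Youden cutoff 359.2 (sens 98.4%, spec 82.7%)
```

The replicate scores (478, 471, 466) differ only through turbulence-noise
realization; the mean is the reported index. The ROC output reads: at the
Youden-optimal cutoff, 98.4 % of reduced-flow records (FV < 400 mL/min) fall
at or below the cutoff while 82.7 % of adequate-flow records lie above it.

### Verification-cohort reproduction

```sh
./exec/hvsi verify
#> Verification cohort (n = 20), cutoff 121 vs fv<400
#>   tp 2  fp 1  fn 1  tn 16
#>   sens 66.7%  spec 94.1%  ppv 66.7%  npv 94.1%
#>   concordance 18/20 (90.0%)
#> PASS: matches the published verification statistics
```

The CLI also provides `score`, `simulate`, `cohort`, `evaluate`, `roc`,
`match` and `adjust`; run any subcommand with a cohort CSV produced by
`hvsi cohort` to get JSON reports with embedded provenance (seed, config,
calibration id).

## Further reading

`vignettes/hvsi-methods.Rmd` documents the analysis pipeline, the generative
model behind the simulator, all tunable parameters with their defaults and
rationale, numerical conventions, and known limitations.
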