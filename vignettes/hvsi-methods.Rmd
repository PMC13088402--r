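---
title: "Methods: acoustic index, simulator, and diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic index, simulator, and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvsi)
```

## The problem

An arteriovenous fistula (AVF) generates an audible bruit at the anastomosis.
As stenosis reduces access flow and raises downstream resistance, the bruit
weakens and its character changes. This package computes a 0–999 acoustic
index of AVF function from anastomosis recordings and supplies the full
apparatus to evaluate it against Doppler ultrasound reference standards —
including a seeded simulator, so that every downstream statistical component
is testable without patient data.

## The scoring pipeline

Per replicate recording:

1. **Resample** to 4000 Hz (Fourier-domain), fixing spectrogram bin
   alignment across devices. The input must be mono with a native rate
   ≥ 3000 Hz so the 1500 Hz band edge is below Nyquist.
2. **Trim** to a fixed analysis epoch: the first 5 s after a 0.25 s onset
   trim when the recording allows, otherwise the whole recording (3 s
   minimum). Clinical recordings run 5–10 s; a fixed epoch stabilizes the
   time average against variable recording lengths and handling transients
   at the start.
3. **Spectrogram**: Hann window, 256 ms, 50 % overlap, one-sided magnitude.
   256 ms gives ~3.9 Hz resolution — enough to place the 50 Hz lower band
   edge — and ≥ 12 frames even on a 3 s minimum recording.
4. **Filter** as frequency-domain weights: brick-wall band-pass 50–1500 Hz,
   then a 4th-order Butterworth low-pass *magnitude* response with −3 dB at
   300 Hz. The source description filters first and takes absolute values of
   frequency components afterwards, which reads as spectral-domain
   operation; the analog topology of the clinical device is unpublished, so
   a maximally standard magnitude response was chosen. The band-pass is
   retained even though the low-pass dominates above 300 Hz (net pass band
   ≈ 50–300 Hz): it is part of the stated chain, and it hard-zeros
   out-of-band leakage the Butterworth weight would only attenuate.
5. **Rectify and average**: magnitudes (not squared powers) are integrated
   over frequency and averaged over frames. "Converted into absolute
   values" reads as rectification; the magnitude convention makes band
   power scale linearly with input amplitude, which keeps the flow–score
   relationship interpretable.
6. **Normalize**: `round(999 · clip((log₁₀P − log₁₀P_min)/(log₁₀P_max −
   log₁₀P_min), 0, 1))`, round half-up. Zero power (silence) maps to 0 by
   convention, not by error.

Three replicates are averaged in the clinical protocol; 1–3 are accepted.

### Calibration

The commercial monitor's normalization constants are not public, so numeric
equality with device scores is not claimable — only rank and behavioral
fidelity. The packaged `default-v1` constants were fitted **once** by
`scripts/calibrate.R`: reference bruits (RI 0.5, HR 75, 20 seeds) at the
extreme flows observed in the packaged verification cohort anchor the map so
that FV 160 mL/min scores ≈ 41 and FV 3025 mL/min saturates at 999,
mirroring that cohort's observed score range (41–999). Every result records
its `calibration_id`. The constants were not revisited afterwards.

## Doppler formulas and units

The printed formulas mix units (cm² with m/s; an integral divided by a
rate). They are implemented in consistent cm units, which reproduces the
physiologic mL/min magnitudes:

* TAV (cm/s) = MTI (cm/beat) × HR (beats/min) / 60 — the standard Doppler
  time-averaged mean velocity;
* FV (mL/min) = area (cm²) × TAV (cm/s) × 60, since cm³/min ≡ mL/min;
* RI = (PSV − lowest diastolic velocity)/PSV, in [0, 1] by construction.

`doppler_measurement(..., velocity_unit = "m/s")` converts machines that
report SI velocities. "Lowest diastolic velocity" is treated as a single
supplied scalar; no distinction from end-diastolic velocity is attempted.

## The generative model

No acoustic generative model of AVF bruits is published; the simulator uses
the simplest construction that yields flow-monotone band power and
resistance-dependent diastolic content:

    x(t) = (FV/1000)^α · e(t) · n(t) + ε(t)

* `(FV/1000)^α` — flow-to-amplitude law, α = 1 by default, so band power is
  proportional to flow (magnitude convention);
* `e(t)` — cardiac-gated envelope with period 60/HR: a squared half-sine
  systolic pulse occupying 35 % of the cycle over a diastolic floor of
  1 − RI. At RI = 1 diastole carries only measurement noise; at RI = 0 the
  bruit is continuous;
* `n(t)` — Gaussian turbulence band-limited to 50–1500 Hz with an
  exponentially decaying spectrum (decay scale 250 Hz; 500 Hz under
  stenosis, shifting the spectral centroid upward as harsher high-frequency
  bruits do);
* `ε(t)` — white measurement noise at `noise_level` (default 0.02 relative
  amplitude).

Everything is deterministic given the scenario seed.

### Synthetic cohorts

`simulate_cohort()` draws the study's structure: controls satisfy the stable
definition (FV lognormal, median 850 mL/min, truncated ≥ 500; RI normal
0.50 ± 0.07 truncated ≤ 0.60), cases are shifted (FV lognormal median
330 mL/min, sd-log 0.40; RI 0.72 ± 0.09). Baseline covariates follow the
study's printed baseline table: age ≈ 70 ± 12 y, 62 % male, 46 % diabetic,
CRP medians 0.10 vs 0.30 mg/dL, prior intervention 57 % vs 85 %, AVF-type
mix differing by group. CRP and prior intervention thus act as genuine
confounders for the matching tests. Doppler primitives (area, MTI, HR, PSV,
EDV) are back-solved per record so that recomputing FV/RI from them
reproduces the stored values exactly.

Effect sizes were chosen once from these distributions; at 1000 + 1000
records the index discriminates FV < 400 mL/min with AUC ≈ 0.96–0.97, inside
the intended 0.85–1.0 regime (the motivating study reports 0.90–0.94 at
n = 202; a synthetic world with cleanly parameterized groups is expected to
sit slightly high).

**Bifurcation masking.** A branch ≥ 2 mm between anastomosis and lesion
carries collateral flow, keeping the bruit louder than the trunk flow alone
would suggest. The simulator raises the *acoustically apparent* flow of
bifurcated **case** records by `compensation × max(0, 800 − FV)` with
compensation 0.5. It applies to cases only: the masking mechanism is defined
relative to a stenotic lesion, which controls do not have (their bifurcation
flag, prevalence 0.15, is anatomical annotation). The compensation factor is
a free design parameter, not an estimate — no quantitative attenuation is
published. This construction makes subgroup attenuation structural:
bifurcated-case AUC is systematically below non-bifurcated AUC, matching the
direction of the reported subgroup analyses.

**Surrogate path.** Statistical tests needing thousands of records use a
fast surrogate: expected band power `p_ref · (FV_eff/1000)^α ·
ē(RI)/ē(0.5)` (with `ē(RI) = 1 − 0.825·RI` the analytic envelope mean),
perturbed by lognormal replicate noise (σ = 0.15) and normalized through the
same calibration as the audio path. The two paths agree to within a few
score units at matched flows; replicate noise σ was chosen so triplicate
score scatter (~±30 units mid-range) resembles plausible repeat-measurement
variability.

### What the simulator does not emulate

Real electronic-stethoscope acoustics (contact pressure, room noise,
device-specific response), arrhythmias, respiratory modulation, graft
acoustics, and the commercial device's actual normalization. A green test on
synthetic cohorts establishes that the *pipeline* behaves correctly in a
world with known ground truth — not that the index achieves any particular
clinical accuracy.

## Diagnostic conventions

* **Orientation**: positive iff score ≤ cutoff (low index = alarm); the
  boundary is positive, consistent with the verification table where a score
  of 122 against cutoff 121 is negative. The orientation is recorded in
  every classification result.
* **ROC/AUC**: empirical sweep over all distinct scores with thresholds at
  midpoints between adjacent values; trapezoid AUC, provably equal to the
  tie-corrected rank statistic (exhaustively tested on all labelings of 8
  records).
* **CI**: DeLong asymptotic variance at ≥ 30 per class, stratified bootstrap
  percentile otherwise. The motivating analysis toolchain defaults to
  DeLong-type intervals; its exact method is unstated.
* **Youden cutoff**: maximizes sens + spec − 1; exact ties break toward
  higher sensitivity (screening should not miss stenosis); the reported
  cutoff is a gap midpoint, so perfectly separated data yield the midpoint
  of the separating gap.
* **Percentages**: rounded half-up to one decimal. Metrics with zero
  denominators are reported absent (`NA`), never 0 or 100.
* On the packaged verification cohort the exhaustive Youden scan against
  FV < 400 gives an optimal cutoff of 161 (any value in [122, 200) attains
  J = 0.941, sens 3/3, spec 16/17): the record scoring 122 is a reduced-flow
  patient, so the optimum lies just above it, not below. The *predefined*
  cutoff 121 evaluated by `verify_cutoff()` is a different quantity — it was
  fixed in advance of that cohort, and its reproduction (66.7/94.1/66.7/94.1,
  concordance 18/20) is the exact acceptance target.

## Matching and adjusted models

Propensity scores come from IRLS logistic regression; complete separation
(deviance ≈ 0) and non-convergence are explicit errors naming the suspect
covariate. Matching is greedy 1:1 nearest-neighbor without replacement on
the logit scale, cases processed in descending propensity order, caliper
0.2 × SD of the logit scores (the common default; unstated in the source),
lowest-id tie-break — fully deterministic and replayed against a brute-force
oracle in the tests. Adjusted odds ratios use Wald 95 % intervals (the
source's CI method is unstated; profile likelihood was considered and not
needed at the tested sizes), with the score scaled per 100 units and AVF
type contrasted against the brachial reference.

The matching covariate list is configurable rather than fixed: the source
matched on "baseline blood data" without enumerating columns.

## Known limitations

* Scores are comparable in rank, not in value, to the commercial device.
* The published 202-patient results (R², AUCs, cutoffs 142/121/104.5,
  adjusted ORs) require the external dataset and are deliberately not
  reproduced; the package covers them with property-based checks
  (directions, monotonicity, subgroup ordering, parameter recovery) on
  synthetic cohorts.
* The Youden objective on realistic mixtures is flat near its optimum;
  cutoff estimates at n ≈ 2000 carry ±15–30 unit variability. The parameter-
  recovery test documents this at a fixed seed.
* The verification cohort's intervention-indication concordance (19/20)
  cannot be recomputed: per-patient ultrasound judgments are not printed.
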