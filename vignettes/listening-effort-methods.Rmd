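---
title: "Methods: listening-effort fNIRS analysis, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: listening-effort fNIRS analysis, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirseffort)
```

## The measurement problem

Listening effort — the cognitive resource allocation needed to understand
speech in noise — can be indexed physiologically by prefrontal cortical
oxygenation. A continuous-wave fNIRS headband measures light attenuation
at 760 and 850 nm over six long (≈3.5 cm emitter–detector separation) and
two short (≈1 cm) channels at 10 Hz. Long channels sample cortex plus
scalp; short channels sample scalp only and serve as nuisance regressors.
The outcome of interest is cerebral oxygen exchange,
`HbDiff = HbO − HbR` (µM), epoched around sentence-sequence events and
compared between two hearing-aid programs (a standard omnidirectional
program and a DNN-based noise-management program) within participants.

This package implements the full chain — preprocessing, event analysis,
behavioural statistics, adaptive SNR-50 staircase, and multilevel
inference — plus a synthetic-data generator with known ground truth, so
that every stage can be validated against programmed answers rather than
against another implementation.

## Preprocessing model and assumptions

The stream runs in a fixed order (permutations are refused, because each
stage's statistical assumptions are prepared by its predecessors):

| stage | parameter | default | role |
|---|---|---|---|
| step removal | `k_sd` | 2 | derivative outlier threshold (SDs above the mean) |
| channel QC | `sci_threshold` | 0.75 | minimum cardiac-band inter-wavelength correlation |
| optical density | — | — | `−ln(I/mean I)`; scale-invariant |
| wavelet correction | `iqr_k` | 0.1 | detail-coefficient outlier band in IQR units |
| Beer–Lambert | `dpf` | 1.0 | differential pathlength factor (see below) |
| band-pass | `band1` | 0.01–1.5 Hz | removes drift and cardiac before regression |
| short-separation GLM | — | — | OLS of long on nearest short channel |
| band-pass | `band2` | 0.01–0.09 Hz | isolates the event-related band |

Assumptions worth stating explicitly:

* **Step removal** assumes the raw derivative is dominated by cardiac
  pulsation, so that genuine signal slopes sit far below the
  `mean + 2·SD` threshold and only contact-loss steps exceed it. The
  stage recomputes the series as `first sample + cumsum(modified
  derivative)`, so a zeroed step leaves the post-step level rejoined to
  the pre-step baseline.
* **SCI** assumes good optode contact registers the heartbeat coherently
  at both wavelengths. It is computed on the whole recording (no
  windowing — the windowed variant used by some toolboxes is not
  implemented, and rejection is all-or-none per channel).
* **Wavelet correction** uses a periodized Daubechies-2 transform with 5
  levels. Before decomposition the series is endpoint-detrended and
  mirrored, making the periodic extension continuous at both junctions;
  otherwise the boundary itself would generate outlier coefficients and
  the thresholding would corrupt the edges. `iqr_k = 0.1` is aggressive
  (it zeroes roughly the outer 45% of coefficients per level); this is
  tolerable for slow event-related designs because the hemodynamic
  content lives almost entirely in the approximation band, and motion
  spikes concentrate in outlying detail coefficients.
* **Short-separation regression** runs on hemoglobin series after the
  wide band-pass, per the stage order; the residual is exactly
  orthogonal to the regressor. If a long channel's nearest short channel
  was rejected, the other short channel substitutes (logged); if both
  are rejected the channel passes through uncorrected (logged).
* **Filters** are 3rd-order Butterworth applied forward–backward
  (zero phase). Inputs are demeaned and odd-reflected at the ends before
  `filtfilt`; without this, the filter rings off the DC intensity level
  and the start-up transient (shared between wavelengths) would both
  distort epochs near the recording edges and spuriously inflate the
  SCI.

### The DPF calibration

The differential pathlength factor scales geometric separation to
effective photon path. The package defaults to `dpf = 1.0`, i.e. the
reported concentrations are *separation-normalized device units*, not
partial-volume-corrected molar concentrations. The reason is
self-consistency: studies in this literature report trial-level HbDiff
values of tens of µM, which under a literal DPF of ~6 would imply
optical-density excursions near 0.7 — intensity swings of ±45% that no
real recording shows, and on which threshold-based artifact stages
misbehave. With `dpf = 1.0` the simulated optics stay in the realistic
regime (OD ≈ 0.1) while the concentration scale matches the published
numbers. The parameter is exposed everywhere (`pipeline_params(dpf = )`,
`simulate_raw_intensity(dpf = )`); any value may be used as long as the
forward model and the inversion agree.

## Event analysis

The response to a sequence event is the mean over
`[onset + 10 s, offset)` minus the mean over the 5-s baseline
`[onset − 5 s, onset)` — the 10-s offset lets the response reach its
peak; both windows are half-open and are taken on the fully filtered
series (the stage order implies a post-filter baseline). Decoy sequences
(1–2 high-context sentences, shorter than the response window) and the
practice block are excluded here, not during preprocessing, so QC sees
all data. Subregions average their two channels, fall back to a single
surviving channel, and are recorded as missing when both are rejected —
the multilevel models tolerate missing rows by construction.

## The synthetic generator: what it emulates, and what not

`make_session_design()` reproduces the session skeleton: one practice
block (standard program) plus `n_blocks` test blocks split evenly
between programs in randomized order; each block holds 6 low-context
sequences of 3–5 sentences (6 s per sentence, hence 18–30 s) and 2
decoys, separated by 30-s baselines. Four test blocks give 12 analysed
trials per condition.

`simulate_hemodynamics()` convolves per-sentence boxcars with a
canonical double-gamma response (peak 6 s, undershoot 16 s, ratio 1/6);
HbR is a −1/3-scaled, 2-s-lagged copy of the HbO shape. The kernel is
normalized so the event-window measure of a reference 24-s sequence
equals the programmed amplitude exactly; 18-s and 30-s sequences land
within a few percent (the window measure is not duration-invariant, and
10% is the generator's stated guarantee for ≥18-s events). The default
truth places the entire condition contrast — +19 µM, standard minus
DNN, at absolute levels +4.2/−14.8 µM — in the left lateral subregion
and zero elsewhere. Per-session participant offsets (SD 3 µM) and a
+13.46 µM right-handedness shift act on all amplitudes, giving the
pooled hierarchy a genuine random intercept and a handedness fixed
effect.

`simulate_raw_intensity()` adds, in hemoglobin space: a shared
superficial component (respiration 0.25 Hz / 0.5 µM, Mayer wave
0.1 Hz / 1.5 µM, random-walk and linear drift) entering short channels
at unit gain and long channels at channel-specific gains (default 0.5);
and per-channel cardiac pulsation (1.1 Hz, 3 µM, random phase). Cardiac
is deliberately the dominant derivative component, as in real
recordings — the step-removal stage depends on it. The hemoglobin sum
maps to OD through the same Beer–Lambert forward model the pipeline
inverts, then white instrument noise (SD 1e-3 OD), contact-loss steps
(2 per session, SD 0.05 OD) and motion spikes (3 per session, 0.15 OD)
are injected per channel × wavelength — the two LED chips of an optode
couple independently, so artifacts need not be common-mode — and
intensities are `i0·exp(−OD)`.

Two noise scales coexist by design. The raw-signal generator above uses
physiologically plausible µM-scale noise, so the pipeline's trial
estimates are clean (condition contrasts recovered within a few percent);
it validates the *signal processing*. The direct trial-table generator
(`simulate_trial_table()`) instead matches the *statistical* scale of
published trial-level data — residual SD 60 µM, between-participant SD
12 µM — chosen so that the programmed −19 µM effect yields a
program-slope standard error near 5 µM at the study's size (26
participants × 12 trials × 2 conditions × 3 subregions), i.e. a clearly
but not trivially detectable effect; it validates the *inference
machinery*. Real recordings sit between these idealizations: passing
tests demonstrate correctness of the implementation under known truth,
not that any particular real dataset will show the effect.

The behavioural model draws 7-point effort ratings as rounded, clipped
normals around condition means 4.02/3.08 with participant (SD 0.85),
condition-within-participant (SD 0.25) and trial (SD 0.8) components,
and correctness as Bernoulli with p = 0.63 (standard) and 0.768 (DNN) —
proportions whose RAU transforms match the published accuracy scale.
Ratings are independent of the simulated hemodynamics unless
`effort_slope_left` couples them; when validating the brain–behaviour
model the program effect is set to zero so the effort-only model is
correctly specified (with both active, the effort slope absorbs part of
the condition contrast — an omitted-variable property of that model, not
an estimator defect).

## Staircase

`run_staircase()` implements the 20-trial adaptive rule: start 8 dB,
SNR down after a correct response and up after an incorrect one, 4-dB
steps for trials 1–5 and 2-dB steps thereafter (the step is chosen by
the index of the trial just answered; the convention for the transition
trial is fixed here and configurable via `staircase_init()`). The
estimate is the mean of ten values — the SNRs presented at trials 12–20
plus the SNR that trial 21 would have used. The three-run protocol
averages runs 2–3 and adds 2 dB. The simulated listener is logistic:
`P(correct | snr) = plogis((snr − snr50)·slope)`. Monte-Carlo tests
bound the estimator bias below 1 dB for slopes ≥ 0.5 dB⁻¹.

## Multilevel inference

Models are fitted by full maximum likelihood (lme4/lmerTest) with a
participant random intercept, at the trial × subregion observation level
(the level consistent with published denominator df near 1775). Dummy
coding uses the study's references: standard program, left-lateral
subregion, left-handedness. Degrees of freedom are Satterthwaite
approximations. Nested models are compared by likelihood ratio
(`χ² = 2·Δloglik`, df = parameter-count difference) and AIC
(`2k − 2·loglik`). Simple slopes are available two ways — refitting with
each subregion as reference, or the equivalent linear combination of
coefficients with Satterthwaite df via `contest1D` — and the test suite
asserts their agreement to 1e-6. The main-effect model contains program
and handedness only; adding subregion and the interaction gives the df=4
comparison. Two pragmatic edge rules: a categorical term with a single
observed level (e.g. an all-right-handed subsample) is dropped rather
than passed to the optimizer, and a zero-variance outcome returns the
trivial all-zero-slope fit directly.

## Numerical choices and problem sizes

* Extinction coefficients: the standard compiled decadic values for
  760/850 nm (cm⁻¹ mM⁻¹), converted to the natural-log convention inside
  the Beer–Lambert inversion; the 2×2 system is solved exactly.
* All randomness flows from one integer seed; sub-seeds are derived by a
  fixed affine hash, and generators restore the caller's RNG state.
* Ties in nearest-short-channel distance break to the lowest channel
  index; events use half-open `[onset, offset)` intervals; the 5-s
  baseline is `[onset − 5, onset)`.
* Validation sizes: parameter recovery uses 10 four-block sessions
  end-to-end plus a pooled mixed model; QC characterization uses 100
  seeded one-block sessions; staircase characterization uses 1000 runs;
  power-style checks on the simple slopes use 100 study-sized trial
  tables. These sizes give Monte-Carlo standard errors comfortably below
  the tolerances they are tested against.

## Known limitations

* The forward model is a linear two-chromophore Beer–Lambert map; no
  photon-transport (Monte-Carlo) modelling, no wavelength-dependent DPF,
  no water/lipid chromophores.
* Optode coordinates are invented to satisfy the geometric invariants
  (two detectors, 3.5 cm long channels, 1 cm short channels, three
  subregions); the vendor publishes no coordinate set, so distances —
  not anatomical positions — are meaningful.
* The SNIRF container writes one data block per wavelength and carries
  the full event annotation in its stimulus table; it is SNIRF-shaped
  rather than a complete implementation of the specification.
* Cardiac, respiratory and Mayer components are fixed-frequency
  sinusoids with random phase; real spectra have bandwidth and
  nonstationarity the generator does not emulate.
* The staircase models sentence scoring as i.i.d. Bernoulli; lexical
  content, list effects and learning are out of scope.
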