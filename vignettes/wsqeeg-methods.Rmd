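---
title: "Quantitative interictal EEG biomarkers: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative interictal EEG biomarkers: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

West syndrome is an infantile epileptic encephalopathy whose EEG hallmark,
hypsarrhythmia, is diagnosed visually with notoriously poor inter-rater
reliability. A promising alternative is to quantify the *interictal* EEG —
stretches free of hypsarrhythmia — with objective signal features and screen
those features statistically. `wsqeeg` implements such a screen end to end
for 19-channel 10–20 scalp recordings sampled at 250 Hz:

1. **Preprocessing** — common average reference (CAR), then a zero-phase
   Hamming-window FIR band-pass to 1–45 Hz.
2. **Linear features** — Welch relative band power per channel and band;
   wavelet-bicoherence cross-frequency coupling aggregated per band pair
   (FIWBIC); magnitude-squared coherence for all 171 channel pairs in three
   bands.
3. **Nonlinear features** — approximate, sample, permutation and wavelet
   entropy per channel.
4. **Statistics** — per-feature pooled-variance t-tests with
   Benjamini–Hochberg FDR control, and ordinary least-squares regression of
   each feature on binary structural and genetic etiology flags within the
   patient group.

Because no clinical recordings ship with the package, a fully seeded
synthetic cohort generator produces 19-channel EEG with controllable band
power, quadratic phase coupling, inter-channel connectivity and signal
regularity, in the effect directions reported for West syndrome (theta and
alpha relative power up, delta and beta down, coupling down, permutation
entropy down, low-frequency coherence up). Every pipeline stage and both
statistical modules are exercised against this generator.

## Estimators

### Relative band power

Welch's method with 2-s Hamming windows and 25% overlap gives a one-sided
PSD on a 0.5 Hz grid. Band power is the *sum* of PSD bins over a half-open
interval $[f_1, f_2)$; relative power is

$$\mathrm{RP}(f_1, f_2) = \frac{P(f_1, f_2)}{P(1, 45)},$$

with bands delta $[1,4)$, theta $[4,8)$, alpha $[8,13)$, beta $[13,30)$ Hz.
Half-open bins prevent boundary bins from being counted twice. Windows are
mean-removed before tapering. Per-channel values are averaged over all
epochs of all segments of a subject; the "global" value is the unweighted
mean over channels (matching the per-channel map structure of the
per-channel reports, rather than a pooled spectrum).

### Wavelet bicoherence and FIWBIC

Quadratic phase coupling between $f_p$ and $f_q$ means the phase at
$f_p + f_q$ is locked to the phase sum. We use a constant-bandwidth complex
wavelet bank (Gaussian spectral kernel, 2 Hz FWHM at every center frequency
1–45 Hz in 1 Hz steps, not constant-Q, because the analysis bandwidth is
fixed in Hz) and form

$$b(f_p, f_q) = \frac{\left|\sum_t W(f_p,t)\,W(f_q,t)\,W^*(f_p{+}f_q,t)\right|}
{\sqrt{\sum_t |W(f_p,t) W(f_q,t)|^2 \sum_t |W(f_p{+}f_q,t)|^2}},$$

which the Cauchy–Schwarz inequality bounds in $[0,1]$. Within one segment
the numerator and both normalizers are accumulated over all 2-s epochs (75%
overlap) before the ratio is taken, so the no-coupling bias shrinks roughly
as $1/K$ with the number of epochs $K$ — a property the test suite checks as
a monotone trend. Coefficients within one envelope e-folding time
($\sqrt{2}\,\sigma_t \approx 0.27$ s) of each epoch edge are excluded.
Entries with $f_p + f_q > 45$ Hz are invalid (`NA`), not zero. In the
per-subject feature path the bank is computed once per segment and the
epoch-wise sums are applied as per-sample coverage weights on a decimated
time grid — legitimate because the 2 Hz-bandwidth coefficients are roughly
60-fold oversampled at 250 Hz and the triple products are near-baseband, so
the accumulated ratios are unchanged to three significant digits.

FIWBIC for a band pair is the **mean** of $b^2$ over the symmetrized
bifrequency region ($f_p \in A, f_q \in B$ and vice versa). The mean, rather
than a raw double sum, keeps values comparable across band pairs whose grid
regions differ in area; the raw sum is available via
`fiwbic.aggregate = "sum"`. Note that absolute FIWBIC magnitudes depend
strongly on the epoch-averaging convention: estimating $b$ from a single 2-s
epoch and averaging $b$ across epochs leaves a large positive bias
(effectively few independent coefficient samples per epoch), while the
accumulated estimator used here drives the floor toward zero. Group
*contrasts* are unaffected; absolute levels are convention-specific.

### Bi-channel coherence

Magnitude-squared coherence
$C_{xy}(f) = |P_{xy}(f)|^2 / (P_x(f) P_y(f))$ is estimated Welch-style on
whole segments using 2-s Hamming windows with the classic 50% overlap, then
averaged over the bins of three bands: delta/theta combined $[1,8)$, alpha
$[8,13)$, beta $[13,30)$. All 171 unordered channel pairs are computed; the
"overall" value is the unweighted pair mean. A per-epoch mode is
deliberately not the default: coherence from a single window is identically
1, so windows must be averaged before the ratio in any case.

### Complexity measures

* **ApEn** — classic definition including self-matches:
  $\Phi_m(r) - \Phi_{m+1}(r)$ with Chebyshev distance, $m = 2$,
  $r = 0.2\,\mathrm{SD}$. `r` is recomputed per 2-s epoch from that epoch's
  SD, since the epoch is the estimation unit.
* **SaEn** — $-\ln(A/B)$ over the $n-m$ templates that exist at both
  lengths, self-matches excluded; undefined (NA, with a warning) when no
  length-$m{+}1$ pair matches. NA epochs are dropped from the subject mean.
* **PeEn** — Shannon entropy (nats) of ordinal patterns of length 3. Ties
  are ranked by order of appearance, which is deterministic. The package
  default pattern lag is **2**, not 1: for signals band-limited to 1–45 Hz
  at 250 Hz, lag-1 order-3 permutation entropy is bounded near 1.47 nats
  even for band-limited white noise (neighboring samples are almost surely
  ordered by the dominant low-pass content), whereas the empirical range
  reported for interictal EEG under this preprocessing (≈1.44–1.55 nats)
  sits above that bound. A lag of 2 moves the ceiling to ≈1.75 nats and
  makes the reported operating range attainable; both order and lag are
  configurable (`ent.peen.order`, `ent.peen.delay`).
* **WaEn** — relative energies of a 5-level dyadic db4 decomposition
  (periodized, orthogonal for dyadic lengths; odd-length levels are padded
  by repeating the last sample) over the 5 detail bands plus the final
  approximation, normalized by $\ln 6$ so the value lies in $[0,1]$. For
  white noise the *dyadic* expected energy split is $(1/2, 1/4, \dots)$, so
  normalized WaEn sits near 0.75 — not near 1; tests assert the value this
  construction actually implies.

### Statistics

Pooled-variance two-sided t-tests compare groups per feature
(`stats.var_equal = FALSE` switches to Welch). BH-FDR is applied within
(measure × band × scope) strata — e.g. the 19 channel-wise theta tests form
one block — because channel maps are screened per measure; a global
correction mode exists. Significance is `q <= alpha`, which reproduces the
BH step-up rejection set exactly (at the boundary, `q < alpha` would drop a
hypothesis the step-up rule rejects). Channel-wise t-maps export zeros for
non-significant channels. Etiology regression fits
`feature ~ 1 + structural + genetic` by OLS within the patient group, with
BH-FDR across features separately per predictor; rank-deficient designs
(e.g. identical flags) are flagged invalid rather than silently fitted.
Dispersion is reported as both SD and SEM, explicitly labelled, since
published "±" values are frequently ambiguous between the two.

## The synthetic cohort generator

Each channel is built in the frequency domain as colored Gaussian noise:
a $1/f$ background plus a narrow Gaussian peak per band (SD 0.3 Hz — i.e.
amplitude-modulated rhythms with sub-hertz envelopes), with per-band power
set by `band_targets`. Per coherence band, a fraction `shared_frac` of the
variance comes from a segment-wide common source seen by each channel with
a random ±1 gain; the random sign is essential, since a spatially uniform
topography would be removed exactly by the common average reference. Six
phase-locked sinusoid triplets (one per band pair, with disjoint addend and
sum frequencies) carry the quadratic phase coupling, scaled by
`qpc_strength`; their addend phases drift in 4-s blocks with the sum phase
drifting consistently, which preserves the coupling within each channel
while preventing deterministic tones from registering as inter-channel
coherence. Finally an order-1 autoregressive smoother (`regularity`) tilts
the spectrum to control permutation entropy. Band weights get per-subject
log-normal jitter (`between_subject_sd`), `regularity` a small additive
jitter, and O1/O2 receive an extra alpha gain for occipital realism.

Calibration: `band_targets` are expressed as *measured* relative-power
targets; a frozen per-group pre-emphasis table inside the generator
compensates the AR tilt so the pipeline-measured group means land on the
configured targets (defaults: the reported WS/control group means, e.g.
theta 0.2145 vs 0.1655), and `regularity` defaults are calibrated so global
lag-2 PeEn lands near 1.44 (WS-like) vs 1.55 (control-like). These were
fixed once against the pipeline and are not adjusted per run; changing
`regularity` far from its defaults shifts the measured spectra and would
need recalibration. Etiology-flag prevalences default to 9/31
causative-structural and 17/31 genetic. An optional planted effect
multiplies the theta weight in genetic-flag carriers, giving the regression
module a known ground truth.

What the generator does *not* emulate: artifacts, non-Gaussian transients
(spikes, sharp waves), age-dependent maturation, volume-conduction
geometry, or hypsarrhythmia itself (the analyzed condition is explicitly
hypsarrhythmia-free EEG). Passing tests on this generator therefore
demonstrate estimator correctness and statistical calibration — not
clinical validity on real recordings.

## Numerical choices and degenerate inputs

* FIR order from the 3.3/Δf Hamming rule (≈ 826 taps at 250 Hz for a 1 Hz
  transition), applied as a single linear-phase pass with exact group-delay
  compensation and reflected edges; the first and last 2 s of every segment
  are additionally excluded from epoching (`epoch.trim_s`).
* Epoch counts follow `floor((N - L)/step) + 1` with
  `step = round(L (1 - overlap))`; trailing partial epochs are dropped.
* All-zero channels yield NA features and are skipped in global means;
  subjects whose files are unreadable or whose montage check fails are
  skipped with a logged reason rather than aborting a run.
* Degenerate t-tests (zero pooled variance, unequal means) drop the feature
  with a warning; equal constant groups return t = 0, p = 1.
* Determinism: cohorts are pure functions of `(config, seed)`; feature
  extraction is deterministic given inputs and config, and analysis tables
  are written with 12 significant digits so reruns are byte-identical.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script cohorts use the full reported group
sizes (31 patient-like, 20 control-like subjects) with one 60-s segment per
subject rather than five 3-min segments — the per-subject duration mainly
tightens within-subject estimator noise, which is already far below the
between-subject spread at 60 s, while keeping the 20-cohort recovery sweeps
tractable on one CPU. Estimator-level checks (entropy oracles, coupling
detection, coherence floors) use 60-s single-channel fixtures and 20 seeds.

## Known limitations

* The EDF reader/writer covers continuous equal-rate recordings without
  annotation channels — sufficient for data exchange, not a general EDF(+)
  implementation.
* Wavelet entropy's dyadic bands are fixed by the sampling rate and do not
  align with the clinical bands; it is a complexity summary, not a band
  measure.
* The bicoherence normalization follows the standard Cauchy–Schwarz form;
  published FIWBIC magnitudes are only comparable across studies when the
  epoch-averaging convention matches (see above).
* Coherence is plain magnitude-squared coherence; volume-conduction-robust
  variants (imaginary coherency, phase-lag index) are out of scope.
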