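---
title: "Heart-rate-variability markers of fetal acidosis: methods and design"
author: "fetalhrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-variability markers of fetal acidosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalhrv)
```

`fetalhrv` implements a complete analysis chain for predicting fetal
acidosis (arterial pH < 7.10) from beat-to-beat fetal heart rate (FHR)
recordings: extraction of 23 FHR / heart-rate-variability (HRV) /
deceleration variables from RR-interval series, and the multivariable
statistics that turn a cohort of such records into a prediction model.
This vignette explains the models, the tunable parameters, the synthetic
data generators, and the design decisions taken where the methodology was
genuinely open.

## The RR series and its windows

All analysis starts from an `rr_series`: beat times in ms and the RR
intervals they close (`rr[i]` ends at `beat_times[i+1]`; the first beat
carries no interval — this convention makes the tachogram unambiguous for
interpolation). Analysis windows are half-open `[start, end)` so a beat on
a boundary is counted exactly once. Two windows matter: the pre-occlusion
*baseline* and the 5-min occlusion-free *stable periods* on which one
feature record each is computed.

No beat-level artefact editing is applied: in this recording setting whole
records of poor signal quality are excluded rather than individual beats
corrected. An optional maximum |ΔRR| sanity filter exists on the
constructor but is off by default.

Uniform resampling (`resample_rr`) interpolates the tachogram linearly
(cubic optional) onto a 4-Hz grid for epoch-based indices and an 8-Hz
grid for spectral analysis and the FSI. Instantaneous FHR is
`60000 / RR`.

## Time-domain indices

* **RMSSD** and **SDNN** are computed over 540 RR intervals — about 3 min
  at a basal FHR of 180 bpm. When a window holds more intervals the most
  recent 540 are used; with fewer, the result is computed on what exists
  and flagged. SDNN uses the population (divide-by-n) denominator; the
  convention is recorded on the result since either is defensible.
* **STV / LTV**: on the 4-Hz series each minute is split into 16
  contiguous 3.75-s epochs aligned to the window start. Per minute, STV is
  the mean *absolute* difference between successive epoch means and LTV
  the range of the 16 means; multi-minute windows average the per-minute
  values. The absolute value is essential: without it the successive
  differences telescope to `(m16 - m1)/15`, which would contradict the
  clinical meaning of short-term variability.
* **Deltas** from baseline default to percentage change, with an absolute
  mode available: published delta summaries mix scales that are only
  mutually consistent if some were absolute differences, so neither mode
  is asserted as canonical and the mode used is recorded on every value.

## Spectral analysis

The fetal LF band is 0.04–0.15 Hz (sympathetic + parasympathetic,
baroreflex) and the HF band 0.15–4 Hz (parasympathetic; the upper edge is
the 8-Hz Nyquist limit). Band powers come from a Daubechies wavelet
decomposition of the mean-removed 8-Hz series to 7 levels. Detail level
*j* covers the dyadic band (fs/2^(j+1), fs/2^j], so levels 1–5 cover
0.125–4 Hz and levels 6–7 cover 0.031–0.125 Hz — the closest dyadic cover
of the nominal band edges; the mapping is returned with every result. The
default transform is the undecimated MODWT for shift invariance (the
decimated DWT is available), the default filter the 4-tap Daubechies
(8-tap optional), and band power is summed coefficient energy divided by
the number of samples. Only ratios and between-window comparisons are
used downstream, so the normalisation constant is documented rather than
critical. Orthonormality is verified by an exact energy-conservation test
and band assignment by an FFT oracle.

`HFnu = HF / (LF + HF)` is returned as `NA` (not 0, not 1) when both
powers vanish.

## The Fetal Stress Index

The FSI scores the magnitude of the HF oscillation of the normalised RR
series on a 0–100 scale:

1. resample at 8 Hz;
2. divide each sample by the trailing 64-s local mean and multiply by 100
   (scale invariance to the absolute RR level; a local rather than global
   mean was chosen for robustness to slow drift — the published
   construction does not specify which, and this is flagged as the main
   deviation risk);
3. zero-phase 4th-order Butterworth high-pass at 0.15 Hz (at 8 Hz this
   retains exactly the 0.15–4 Hz HF band; forward–backward filtering
   preserves envelope timing);
4. once per second, over a trailing 60-s sub-window, measure the mean
   vertical distance between the linear interpolants through the local
   maxima and local minima (envelopes extended flat at the edges; a pure
   sinusoid of amplitude *a* scores ≈ 2a);
5. scale and clamp: `min(100, scale * magnitude)`; average over a
   trailing 4-min window (3-min option, since both averaging spans appear
   in the published description).

The published construction gives no scale constant. The package's
`fsi_default_scale()` (21.08) was calibrated once so that the default
non-acidotic synthetic parameterisation scores ≈ 57.6, the non-acidosis
group mean used throughout the synthetic cohort, and is persisted with
every result. The decision threshold for classifying acidosis defaults to
67.8 (a published rounding of ≈ 68 also circulates; the more precise value
is used).

## Deceleration morphology

Decelerations are maximal runs of the 4-Hz FHR trace below
`baseline − 15` bpm lasting ≥ 10 s; the nadir is the run minimum,
amplitude is baseline-to-nadir, slope is amplitude/duration and the area
is the triangular `½ × duration × amplitude`. Detection thresholds are
parameters, not physiology: occlusion-locked experimental decelerations
are deep (≈ 95 bpm) and the defaults recover them exactly; clinical FIGO
typing is out of scope. The feature table takes duration, amplitude,
slope and area from the *last* deceleration before each stable period
(the documented scope), with a sum-of-areas variant available because
both scopes appear in the published definition of the deceleration area.
When the generator's true baseline is unknown a 10-min rolling-median
baseline is used.

## The synthetic generators

**Sessions.** The RR model is
`RR(t) = 60000/FHR(t) + lf_amp·sin(2π·lf_freq·t) + hf_amp·sin(2π·hf_freq·t) + N(0, noise_sd²)`
with beats placed by integrating the instantaneous RR. Defaults: baseline
180 bpm, LF 15 ms at 0.1 Hz, HF 5 ms at 0.8 Hz, noise 3 ms. The protocol
is one baseline hour, then three 1-h phases with 1-min occlusions every
5/3/2 min; a 5-min stable period ends every 20 min (the first at the end
of the baseline hour). Stable periods are occlusion-free by definition, so
occlusions overlapping one are suppressed while the per-phase *schedule*
(12/20/30 occlusions) is preserved and both are recorded. pH declines
deterministically by 0.01 per delivered occlusion from 7.35 (a stochastic
decline was considered and rejected: only the stopping rule is documented,
and determinism keeps the schedule arithmetic testable); the session
truncates once pH drops below 7.00. Once pH crosses 7.10 the HF amplitude
is multiplied by `acidosis_hf_gain` (default 1.2 ≈ the ratio of the
published group FSI means) — the minimal mechanism consistent with the
central observation that acidosis raises parasympathetic HRV. The
generator does not model baroreflex dynamics, blood-gas kinetics,
accelerations, fetal states or artefacts, so passing signal-level tests
demonstrates correct index arithmetic on clean oscillations, not clinical
performance.

**Cohorts.** The cohort generator draws 101 non-acidosis and 29 acidosis
records with 23-variable marginals matched to the published group
summaries: near-symmetric variables (FSI, HFnu and deltas, FHR summaries,
amplitude) are normal with `sd = IQR/1.349` where only median [IQR] is
printed; positive right-skewed variables (SDNN, RMSSD, band powers,
STV/LTV, durations, slope, deceleration areas) are log-normal solved from
median and IQR. One printed quartile pair is internally inconsistent
(lower quartile above the median) and is used sign-corrected. pH is a
truncated normal strictly on the matching side of 7.10, so the acidosis
label is consistent by construction. A Gaussian copula (on by default)
induces a factor-block correlation structure mirroring the real cohort's
rotated factors — e.g. latent r = 0.9 within the spectral, STV/LTV and
SDNN/RMSSD families, 0.6 between FSI and its delta, and negative
Duration–Slope and FHRmin–Amplitude pairs. The true inter-variable
structure is only partially recoverable from published summaries, so the
targets are configurable (`cohort_default_correlation()`), not asserted;
note that Pearson correlations on the log-normal scale are attenuated
relative to the latent targets.

## Variable reduction and selection

PCA is run on the standardised 23 variables; factors with eigenvalue > 1
are varimax-rotated and a variable is *assigned* to a factor when its
absolute rotated loading exceeds 0.6 on exactly one factor. Within each
factor, variables are walked in a fixed clinical preference order (the
absolute index over its delta; LF over HF, STV over LTV, SDNN over RMSSD,
FHRmax over FHRmean; Duration and the deceleration area over Slope) and
kept unless they correlate above 0.70 with a variable already kept for
that factor — so near-orthogonal variables sharing a factor can both
survive. On the synthetic cohort this typically retains 11–13 variables,
always including FSI and STV; the exact count is data-dependent because
several loadings and correlations sit near their thresholds by design.

Bootstrap stepwise backward selection resamples the rows 500 times; each
resample starts from all candidates and repeatedly drops the predictor
with the largest Wald p-value while it exceeds 0.05 (a likelihood-ratio
criterion was considered; Wald is the documented criterion and is what
the fast per-resample fits provide). Non-convergent or rank-deficient
resample fits are dropped and counted, with a warning above 10 %.
A candidate is selected when retained in ≥ 70 % of successful resamples.
One property of this procedure worth knowing: a noise variable that is by
chance associated with the outcome in the parent sample (|z| ≳ 2.5, which
happens for at least one of 10 noise variables in roughly one cohort in
six at n = 130) is *bootstrap-stable* and will be co-selected; the rule
protects against over-optimism, not against parent-sample chance.
Log-linearity checking by restricted cubic splines is simplified to
documented options to log-transform or median-split a variable.

ROC analysis uses the mid-rank concordance AUC with a DeLong 95 % CI
(bootstrap optional) — verified against an exhaustive pair-concordance
oracle and an independent reference implementation — and acidosis is
called when the score *exceeds* the threshold (higher FSI ⇒ acidosis,
consistent with the group means). Reported rates are rounded half-up to
2 decimals, matching conventional presentation.

## Decision trees

Both trees share one binary node type and exhaustive midpoint threshold
scans. The CHAID-style tree splits on the candidate with the largest 2×2
Pearson chi-square (no Yates correction; the classic Bonferroni
multiplicity adjustment is available but off by default, since the
procedure being reproduced does not describe one) and stops when no split
reaches the 5 % level or children would fall below `min_node_size`. The
CART-style tree maximises Gini impurity decrease with rpart-like defaults
(`minsplit` 20, children ≥ minsplit/3, cp 0.01) and weakest-link
cost-complexity pruning on misclassification risk relative to the root.
Ties in the threshold scan break towards the lower threshold; identical
inputs yield identical trees. Evaluation is resubstitution (training-set)
performance, the convention for small-cohort tree reporting — published
correct-classification counts of this kind are resubstitution counts.

## Problem sizes and numerical tolerances

The test suite runs in about two minutes: sessions of 2–4 h of beats
(~40 k), cohorts of 130 rows (10⁴–10⁵-row cohorts for marginal/copula
recovery), 150–500-resample bootstrap runs, and 500-replicate ROC
simulations. Wavelet energy conservation is asserted to 1e-8, exact
identities (formula oracles, determinism) to 1e-12, filter attenuation at
≥ 40 dB, and stochastic recoveries at 2–4 Monte-Carlo standard errors.
Degenerate inputs are errors, not silent results: empty windows,
non-positive RR, series too short for the level-7 decomposition or the
envelope sub-window, one-class outcomes, constant predictors. Quantities
that can be legitimately undefined (HFnu at zero power, PPV/NPV with an
empty margin, correlations of zero-variance columns) are `NA` with the
reason documented.

## Known limitations

* The FSI scale constant reproduces the published score *level* only for
  the synthetic parameterisation it was calibrated on; absolute FSI values
  on other data depend on that constant (relative and threshold behaviour
  do not, given recalibration).
* The synthetic cohort shifts every variable's marginal independently of
  the others' shifts, so multivariable selection on it keeps more
  variables than a real cohort whose signal concentrates in one marker.
* Resubstitution tree metrics are optimistic by construction; no
  cross-validation is provided because the reproduced procedure reports
  training-set counts.
* Session generation models autonomic oscillations as fixed-frequency
  sinusoids; spectral peaks are therefore sharper than in real recordings.
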