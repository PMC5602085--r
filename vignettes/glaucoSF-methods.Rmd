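---
title: "Structure-function analysis for early glaucoma: methods and design"
author: "glaucoSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function analysis for early glaucoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucoSF)
```

## The problem

Glaucoma damages retinal ganglion cells long before standard automated
perimetry (SAP) shows a reproducible field defect. Two measures promise
earlier detection in the macula: structural thinning of the ganglion
cell-inner plexiform layer (GCIPL) on OCT, and functional loss of
inner-retinal electrical activity on the two-global-flash multifocal ERG
(2F-mfERG). glaucoSF implements a complete analysis chain that compares
these modalities over spatially matched central regions (10 and 15 degrees),
adjusts group comparisons for age and gender, and classifies individual
eyes as abnormal per modality against a control-derived normative database.
Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic cohort generator that reproduces the statistical
structure the analysis assumes, so every stage is testable end to end.

## Stimulation model

The central ~47 degrees are tiled by 103 eccentricity-scaled hexagons
(`buildHexLayout()`): the full hexagonal rings 0-5 plus the 12 ring-6
elements closest to fixation. Each hexagon flickers according to a
maximal-length binary m-sequence of period $2^{13}-1 = 8191$
(`generateMSequence()`), one sequence circularly shifted per hexagon — the
standard multifocal construction. Distinct shifts of an m-sequence are
exactly orthogonal under $\pm 1$ correlation, which is what makes
simultaneous per-hexagon kernel recovery possible; shifts are spread evenly
over the period (about 80 steps apart), far above the 105 ms analysis epoch.

Each m-step spans 6 display frames: the m-frame (hexagons at 100 or
<1 cd/m²), then two full-field global flashes (200 cd/m²) separated by dark
frames (`buildFrameSchedule()`). The display frame rate is not part of the
protocol's printed parameters; we fix the default at 75 Hz because it is the
unique common CRT rate under which the 6-frame step reproduces both printed
timing facts — the ~26 ms between the two global flashes (2 frames =
26.7 ms) and the total recording time ($8191 \times 80\,\mathrm{ms} =
655.3$ s = 10 min 55 s, split into 16 segments). Both frame rate and frame
pattern are configurable.

## Signal chain

`rejectArtifacts()` runs two identical passes over the 16 recording
segments: a segment whose peak amplitude has a leave-one-out z-score above
3 is replaced by the mean of its nearest accepted neighbours in recording
order. The two-pass structure matters: a gross blink artifact inflates the
spread enough to mask a moderate artifact, which is only caught once the
first pass has removed the gross one. The commercial implementation of this
step is proprietary; ours is a parameterised z-score scheme with the same
two-pass behaviour.

`bandpass()` applies a 2nd-order Butterworth 1-200 Hz filter forward and
backward (zero phase). Zero phase is essential because the downstream
features are fixed-window RMS values; a causal filter would shift energy
across window boundaries. The trace is demeaned before filtering so DC
rejection is exact.

`extractFirstOrderKernels()` recovers the per-hexagon first-order kernel as
the cross-correlation of the $\pm1$-recoded, per-hexagon-shifted m-sequence
with the trace, normalised by the number of "on" steps, on a 0-105 ms
epoch after each m-frame onset (time zero = m-frame onset). On noise-free
input this recovers each injected waveform exactly (tested to $10^{-6}$
relative error) with cross-talk below 1% of the own-response RMS.

Amplitudes are summarised as window RMS (`rmsEpoch()`): the direct
component DC at 15-45 ms, and the two induced components IC1 (45-75 ms)
and IC2 (75-105 ms) — the responses to the two global flashes as modulated
by the preceding focal flash, attributed predominantly to the inner retina.
No local baseline is subtracted: the three windows abut, and the 1 Hz
high-pass has already removed offset. Per-hexagon RMS values are averaged
arithmetically over the central 7 hexagons (10 degrees) and the central 19
(15 degrees) (`regionalRMS()`).

## Spatial correspondence

The OCT macular thickness (mT) value is the area-weighted mean of the ETDRS
center + inner-ring sectors (1 + 3 mm circles, ~10 degrees); the GCIPL
value is the mean over an elliptical annulus of 4.0 × 4.8 mm outer diameter
with a 1 mm foveolar exclusion. At the default conversion of 3.3 deg/mm the
annulus corresponds to the central 13.2 × 15.8 degrees, which is why the
mfERG and SAP analyses add a 15-degree region to the 10-degree one. (The
protocol text also quotes "1 mm = 3.5 degrees", which is inconsistent with
3.3 deg/mm; we therefore treat the conversion factor as a configuration
value, default 3.3, and specify the foveolar exclusion in mm.)

SAP sensitivities are converted point-wise from dB to linear units
($10^{dB/10}$) *before* averaging — the mean of 20 and 30 dB in linear
space is 550, not $10^{2.5}$ — giving MS10/MS15; the mean defect MD stays
in dB (positive = loss), matching the convention in which only MS is
reported "(linear)". The central-10-degree point set is chosen after
displacing each test point outward by the ganglion-cell displacement, which
we model piecewise-linearly through the two anchors (1 mm, 0.62 mm) and
(4 mm, 0.12 mm) with constant extension outside; the published displacement
curve is only quoted at those two eccentricities, and the two-anchor
interpolation reproduces every number used without inventing curvature.
The 15-degree set adds exactly four configured points (~13 degrees, one per
quadrant by default); their identity is a shipped, user-overridable
configuration because no point list is published for the adapted G2
pattern.

## Statistics

Group differences use one-way ANOVA with Bonferroni-adjusted pairwise
post-hoc tests. Structure-function association uses linear models of a
functional response (epoch RMS, MS, MD) on a structural predictor (mT,
GCIPL) with age and gender as fixed covariates; when subjects contribute
two eyes a subject random intercept is added (lme4/lmerTest), and with
singleton subjects the model collapses to OLS. All p-values of one run form
a single Benjamini-Hochberg FDR family (the family definition is otherwise
unspecified, so we take the widest one).

Diagnostic performance uses the covariate-adjusted ROC construction: fit a
logistic regression `disease ~ age + gender + marker`, use the predicted
probability as the score, and compute the nonparametric Mann-Whitney AUC of
the scores with ties counted one half; the AUC standard error is the DeLong
variance estimator, and correlated AUCs are compared with the paired DeLong
z-test. On small cohorts with strongly age/gender-confounded groups the
in-sample logistic score borrows a lot of discrimination from the
covariates, so adjusted AUCs sit high and close together; the meaningful,
tested property on the default synthetic cohort is the *ordering* — DC,
IC2 and GCIPL each outperforming mT — not the AUC magnitudes.

## Per-eye classification

An eye is abnormal in the central 15 degrees per modality if:

* **SAP** — at least one central-15 point with a deviation beyond the
  normative 99.5th percentile (probability class < 0.5%);
* **2F-mfERG** — DC, IC1 and/or IC2 regional average outside the 95%
  quantile of controls. We read this one-sided (below the 5th percentile)
  by default, because glaucomatous damage uniformly *reduces* amplitudes; a
  two-sided option exists. The criterion is evaluated on the 15-degree
  averages by default (the criterion is defined for the central 15
  degrees), switchable to 10;
* **OCT** — at least one sector at or below the control 5th percentile
  (yellow) or 1st percentile (red), for mT and GCIPL separately.

All thresholds are empirical quantiles (linear interpolation) of a
control-only normative sample whose size and seed are recorded in the
`NormativeDB` object. Note that the three epoch averages are strongly
correlated within an eye, so the family-wise mfERG false-positive rate on
controls sits between the single-epoch 5% level and the independence bound
$1 - 0.95^3 \approx 14\%$; the calibration test checks both.

`crosstabReport()` tabulates modality agreement with explicit denominators
(all eyes; eyes with GCIPL thinning). `referenceFlagTable()` ships a fixed
26-eye example whose cross-tabulation exercises every category.

## The synthetic cohort generator

`cohortDesign()` encodes the study conditions: 16 control, 6 preperimetric
(PPG) and 20 open-angle glaucoma (POAG) eyes; ages 49.2 ± 7.0, 63 ± 15.9
and 60.6 ± 12.4 years; male fractions 2/16, 5/6 and 17/21 (assigned as
fixed per-group counts, as a demographics table reports them); GCIPL
80.7 ± 4.7, 68.2 ± 10.2 and 65.4 ± 9.3 µm; central mT 308.4 ± 12.7,
302.6 ± 15.8 and 296.5 ± 18.7 µm; mean defect 0.12, −0.08 and 4.7 dB. One
published PPG GCIPL spread is typeset as "102.6", which is physiologically
impossible for a ~68 µm mean; the design interprets it as 10.2 µm
(configurable).

A single latent structural-loss variable per eye, scaled so one unit equals
`gciplLossScale` = 30 µm of GCIPL, drives all modalities:

* **OCT** — GCIPL is drawn around its group mean with the latent carrying
  the within-group variance; mT couples to the same latent at
  `mtLossScale` = 23 µm/unit (the ratio of the printed control-POAG group
  differences), with independent residual noise making up the printed SDs.
* **mfERG** — the latent maps to a per-hexagon integrity field $g$
  (spatially smoothed, SD 0.08) that scales only the inner-retinal terms of
  the focal response template: a biphasic outer-retina waveform (negative
  lobe ~20 ms, positive ~32 ms) plus $g$-scaled adaptive DC enhancement and
  the two induced responses (~57 and ~85 ms). Healthy template epoch RMS
  values are ~0.87/0.55/0.51 µV (DC/IC1/IC2).
* **SAP** — field loss is drawn per group around the printed mean defects;
  it couples to the structural latent only in POAG (8 dB per unit excess
  loss), because preperimetric glaucoma is *defined* by structural damage
  with a normal field. Point-wise loss is weighted toward locations with
  lower local integrity, converted to dB against an eccentricity-linear
  hill of vision with a small age-correction slope (0.1 dB/decade,
  configurable).

Measurement noise: a per-eye log-normal mfERG gain factor (SD 0.045),
white waveform noise (0.05 µV), sector noise (2.5 µm), point noise
(1.2 dB). These levels were fixed once from the separations implied by the
group tables above (e.g. the GCIPL group distributions alone imply a
control-vs-POAG discriminability near 0.9) and are part of the design, not
tuning knobs.

By default the generator emits the per-hexagon response waveforms directly
(plus SAP and OCT data); with `traces = TRUE` it synthesises the full 16
continuous voltage segments by superposing each hexagon's waveform at its
"on" steps (wrapping circularly) under 1/f-plus-white noise, which the
signal chain then processes from scratch. The trace path is validated for
fidelity (noise-free recovery to $10^{-6}$; correlation > 0.95 under
noise); cohort-level statistics run on the waveform path, which keeps
multi-seed suites fast. Problem sizes used by the shipped test suites — a
255-step sequence for trace round-trips, 42-eye cohorts over 50 seeds for
direction-of-effect checks, 1500/2000-eye control samples for specificity
calibration, 100 seeds at n = 200 for slope-recovery coverage — were chosen
as the smallest sizes at which the Monte-Carlo error is clearly below the
asserted margins.

What the generator does **not** emulate: arcuate/hemifield defect shapes,
fixation losses and media opacity, OCT segmentation failure, inter-eye
anatomical asymmetry, device-specific test patterns, or biophysically
realistic ERG waveform diversity. Passing tests therefore demonstrate that
the analysis chain is correct and well calibrated under the assumed
statistical structure — not that the clinical effect sizes themselves are
reproduced from real recordings.

## Numerical choices and degenerate inputs

* Empirical quantiles use R's default linear interpolation (type 7);
  boundary values are inclusive ("at or below the 5th percentile" is
  yellow).
* AUC ties count one half (Mann-Whitney convention); perfect separation in
  the logistic score model is reported with a warning, and the AUC is still
  computed from the scores.
* The DeLong comparison of identical score vectors returns z = 0, p = 1
  rather than 0/0.
* ANOVA on groups with zero between- and within-variance returns F = 0,
  p = 1 rather than NaN.
* A constant predictor in a structure-function fit raises a diagnostic
  error ("singular fit") instead of returning an unstable coefficient.
* Single-class cohorts skip the group-statistics and ROC stages with an
  explicit message; classification still runs.
* All simulation entry points are seed-driven; re-running any pipeline with
  the same seed is bit-identical.

## Known limitations

The 103-hexagon layout is a generic scaled array, not a replication of any
device's proprietary vertex geometry. The displacement model is exact only
at its two anchors. The covariate-adjusted AUC is an in-sample quantity;
with 42 eyes and strong demographic confounding its absolute level is
optimistic, which is why only orderings are asserted. The normative
database is synthetic and self-consistent with the generator; applying the
classifier to real data requires a real control sample in its place.
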