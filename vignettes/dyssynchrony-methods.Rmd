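---
title: "Methods: grading cardiac mechanical dyssynchrony from gated blood-pool series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grading cardiac mechanical dyssynchrony from gated blood-pool series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyssync)
```

## The problem

Equilibrium radionuclide angiography (ERNA) images the Tc-99m-labelled
blood pool over the cardiac cycle: a gated acquisition yields a stack of
`k` count maps (here 16 frames of 64 x 64 pixels, about 300,000 counts per
frame) in which pixel intensity tracks ventricular blood volume. Two kinds
of mechanical dyssynchrony are read from such series: an *interventricular*
(LV-RV) timing offset between right- and left-ventricular contraction, and
an *intraventricular* (iLV) dispersion of contraction timing within the
left ventricle. Severity on both axes is coded on a four-level ordinal
scale — absent (A), mild (M), moderate (Md), severe (S) — and grading it
automatically is the package's purpose: the cascade classifier reproduces a
clinical reading pipeline in which LVEF, QRS and P-R intervals plus
temporal descriptors of the image series are the inputs.

## Descriptors of contraction

### Factor analysis of dynamic structures (FADS)

Arrange the series as the time-activity-curve (TAC) matrix `X` (`P x Q`:
one row per pixel with `p = (i - 1) N + j`, one column per retained frame).
FADS models the TACs as linear mixtures of a few temporal patterns:

    X = Gamma %*% t(C)

with `C` the eigenvectors of the frame-by-frame second-moment matrix
`t(X) X` (the temporal *coefficient curves*) and `Gamma = X C` the spatial
*factor images*. Whether the second-moment matrix should be mean-centred is
a genuinely open choice; the package defaults to **uncentered**, because
only then is the reconstruction identity above exact with no mean term
(`fads_decompose(..., mode = "centered")` is provided for study, storing
the removed column means). An eigenvector's sign is arbitrary, so each
coefficient column is flipped to make its largest-magnitude element
positive; exactly tied eigenvalues (a measure-zero event on real data) are
ordered stably by the first differing coefficient entry. Eigenvalue shares
("contributions", in %) always sum to 100 and, on control-like series, the
three leading factors carry essentially the whole spectrum: factor 1 is
the near-static blood-pool distribution peaking in the ventricles, factor
2 the ventricles-versus-atria stroke pattern peaking in the atria, and
factor 3 small and anatomically unstructured unless contraction is
abnormal. The test suite asserts this localisation on the phantom, and the
acceptance script measures the mean top-3 contribution on a 33-subject
control cohort (about 99.6% under the default generator).

### First-harmonic Fourier phase

Each pixel's TAC is reduced to the angle of the first harmonic of its DFT.
The convention (fixed here because no standard exists): a cosine peaking at
frame 0 has phase 0 degrees, and a TAC delayed by `s` frames gains
`360 s / Q` degrees, so later contraction means larger phase. Pixels whose
first-harmonic amplitude falls below 5% of the image maximum are flagged
invalid — expert-read phase images need no threshold, but an automated
pipeline must suppress background pixels whose phase is noise. Regional
phase histograms are summarised with *circular* statistics (mean, SD, and
the narrowest arc holding 95% of the samples, found by scanning arcs
anchored at each sorted sample); linear statistics would fail near the
0/360 wrap.

One unit subtlety: preprocessing drops the degraded last frame, so the DFT
runs over 15 frames covering 15/16 of the R-R interval, and its phases are
angles *of that window*. `preprocess_frames()` records the covered
fraction and `cycle_fraction()` exposes it; multiplying phase differences
or dispersions by it converts to cardiac-cycle degrees. Without the
conversion a true 80-degree interventricular delay reads as 85.3 degrees.

### Ejection fraction

`compute_lvef()` uses the standard count-based formulation on the LV ROI
TAC: `100 (ED - ES) / (ED - BG)`, with `ED`/`ES` the TAC extrema and `BG`
an optional background term (mean per-pixel background count scaled by the
LV pixel count). It must be applied after `preprocess_frames()` on
acquisitions with a degraded final frame, which would otherwise be read as
end-systole.

## Labels and the classifier

Per-rater ordinal codes are merged by `consensus_label()`: the strictly
most frequent code wins; with no unique mode the ordinal median is used,
and an even panel with a half-integer median rounds toward the less severe
code (clinically conservative; three-rater panels never hit this case).
The cascade works on the coarse 3-class scale `A` / `M` / `MdS` because
distinguishing moderate from severe is not clinically necessary.

Feature vectors concatenate `[lvef, qrs, pr]` with two of the subject's
own FADS coefficient curves: curves 1 and 2 for the iLV axis, curves 2 and
3 for the LV-RV axis — 33 values with the default 15 retained frames. The
exact ordering inside the vector is not fixed by any external constraint;
clinical values first, then the lower-index curve, is the package's
convention. LVEF enters as the 0-100 percentage and everything is then
z-scored per dimension with training-set statistics (population SD;
zero-variance dimensions are centered only). Whether clinical values and
curve samples were scaled jointly or separately in the reference model is
unknown; a single joint z-score is the simplest defensible choice and is
serialized with the model.

Both stages are linear C-SVMs fitted with `e1071` (LibSVM). Stage 1
separates absent from present on all training subjects; stage 2 separates
mild from moderate-severe on the present subjects only, with class weights
defaulting to inverse class frequency because the mild class is heavily
outnumbered. The per-axis hyperparameter defaults are `(gamma, cost) =
(0.15, 65)` for iLV and `(0.05, 10)` for LV-RV; `gamma` is recorded for
fidelity with the reference settings but is inert — the linear kernel has
no gamma. Decision values are extracted as an explicit `(w, b)` pair
oriented so that a nonnegative value means the less severe class,
making boundary ties resolve conservatively and predictions independent of
LibSVM's internal label order.

The cohort split is stratified by the 3-class label (default on): each
class contributes `floor(0.7 n_class)` subjects to training. On a
75-subject cohort with the reference label margins this yields 51 training
and 24 testing subjects with all three classes represented in the test
set, matching the reference test-set compositions (10/4/10 and 11/2/11).
Cross-validation is per stage — folds are drawn over all training
subjects for stage 1 and over the present subset for stage 2, stratified
by class, because how the reference 10-fold procedure interacted with the
stage-2 subset is unstated; per-stage folds keep every fold trainable.
When the smallest class has fewer members than the requested folds the
count is reduced with a warning.

Kendall's coefficient of concordance (`kendall_w()`) uses midranks and the
standard tie correction — the four-level scale guarantees heavy ties, and
the uncorrected form understates agreement — with a seeded permutation
test (each rater's codes permuted independently) as the primary p-value
and the chi-square approximation as secondary. Note the null scale: for
`m` raters `W = ((m - 1) rho + 1) / m` with `rho` the mean pairwise rank
correlation, so uninformative panels concentrate near `1/m` (0.33 for
three raters), not near 0.

## The synthetic cohort generator

No imaging data are distributed with the package; `generate_cohort()`
builds cohorts with the statistical structure the analysis assumes, with
known ground truth.

* **Phantom**: elliptical LV and RV side by side in the lower field of
  view, two atrial ellipses above, uniform background elsewhere, on a
  64 x 64 grid.
* **Kinetics**: ventricular pixels follow `ED (1 - ef * s(theta - phi))`
  where `s` is a raised cosine over a systolic fraction of the cycle
  (default 0.625 = 10/16, so the 16-frame sampling hits end-systole
  exactly and the injected ejection fraction is recoverable to better
  than 0.5 percentage points); atria fill in anti-phase (`1 - s`) at 65%
  brightness with a 0.35 emptying fraction; the background pool carries
  the complement of the chamber displacement, so every frame's expected
  total is exactly `counts_per_frame` — tracer conservation in the field
  of view, and the property that makes frame totals Poisson-concentrated
  around 300,000.
* **Dyssynchrony**: the RV waveform is delayed by `lvrv_delay_deg`; LV
  pixels receive a spatially smooth random linear phase gradient rescaled
  to SD `ilv_spread_deg`. Ground-truth labels come from monotone
  thresholds on these magnitudes, defaulting to 20/40/60 degrees (LV-RV)
  and 10/25/40 degrees (iLV spread). The delay magnitudes drawn for each
  severity class sit inside bands clear of the cut points (e.g. mild
  LV-RV delays on 24-36 degrees) so labels are stable under noise.
* **Clinical covariates**: truncated normals per group with the reference
  means/SDs (controls: LVEF 59.7 +/- 5.8%, QRS 80 ms, P-R 140 ms with
  nominal normal-population SDs; four heart-failure groups split by
  ischemic etiology and QRS width). All HF draws are capped below 35%
  LVEF, the population's inclusion criterion. Severity classes are
  assigned by deterministic per-group quotas (largest-remainder rounding
  of per-group probabilities), with wide-QRS groups skewed severe — this
  quota table is the knob coupling QRS to severity. With the default
  33 + 11/10/10/11 composition the label margins are 33/11/31 (LV-RV) and
  34/6/35 (iLV), including one iLV-absent HF subject.
* **Noise and artifacts**: per-pixel, per-frame Poisson counts; the last
  frame's expectation is attenuated by 0.7 to emulate beat-window
  degradation, which is what the drop-last-frame preprocessing rule
  exercises. Any factor below 1 would do; 0.7 is a visible but not
  extreme loss.
* **Determinism**: one master seed derives all per-subject seeds; the
  same spec reproduces a cohort bit for bit.

What the generator does **not** emulate: attenuation and scatter, overlap
of chambers in projection, anatomical variability of chamber shapes,
arrhythmic gating errors beyond the single degraded frame, regional
scar/akinesis, and any correlation structure between FADS curve shapes and
clinical covariates beyond what the kinetics imply. Consequently, passing
recovery tests here shows the pipeline is correct and well-calibrated on
data satisfying its own assumptions — not that the reported clinical hit
rates would be reproduced on patients.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by choice, at the study's
own scale: 75-subject cohorts (33 controls, 42 HF), 16-frame 64 x 64
series at 300,000 counts per frame, 5-10 seeds per property; the full
suite completes in well under a minute on one core. Tolerances: the
reconstruction identity and SVD-oracle agreement are asserted at 1e-8
(double-precision eigendecompositions of 15 x 15 matrices are accurate to
~1e-12); delay recovery at +/- 5 degrees; ejection-fraction recovery at
0.5 percentage points; dispersion recovery at +/- 30% (sampling plus
Poisson phase noise). Degenerate inputs are defined rather than left to
chance: an all-zero spectrum errors on contribution queries, a constant
series yields an all-invalid phase image, ED equal to background is an
error, and empty cohort specs produce empty cohorts.

## Known limitations

* The severity thresholds that map delay magnitudes to expert codes are
  simulator defaults, not estimates of any expert's criteria; no data
  exist to calibrate them.
* The generator's group-to-severity coupling is deliberately strong
  enough for the cascade to succeed when the pipeline is correct; weaker
  coupling degrades stage-2 accuracy first, as the mild class is smallest.
* `gamma` is carried but unused (linear kernel); models serialized by
  this package record it for comparability only.
* Phase statistics assume a single dominant harmonic; severely abnormal
  TACs violate this, which is precisely the regime where FADS descriptors
  are the more robust input.
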