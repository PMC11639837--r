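---
title: "Methods: hyperspectral defect detection with learned band selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral defect detection with learned band selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Blood-related surface defects on poultry carcass breasts — congestion
(CBC), blisters (CBB) and dried blood residue (CBBR) — are all
blood-dominated and look nearly identical to an RGB camera. They do
differ in composition: hemoglobin content (absorbing in the
420–600 nm range, with sub-bands near 430, 545 and 576 nm) and
moisture (water absorption near 960 nm). A visible/NIR hyperspectral
line camera resolves those differences, at the cost of hundreds of
highly redundant bands.

`hsdefect` implements the complete workflow: reflectance calibration,
selection of a small informative band subset by a firefly metaheuristic
whose objective is a 1-D CNN spectral classifier, pseudo-color
synthesis from the selected bands, object detection on the pseudo-color
image, and a spectral–spatial fusion stage that re-classifies each
detected region from its mean spectrum.

## Reflectance calibration

Raw intensity `I` is converted to relative reflectance with dark (`B`)
and white (`W`) references: `R = (I − B) / (W − B)`. Values are stored
as fractions in `[0, 1]`; the conventional ×100% display scaling is
applied only when formatting. Elements where `W − B ≤ 0` raise an
error that reports the element count. Out-of-range results (specular
outliers, noise) are clipped to `[0, 1]` rather than raised as errors:
clipping is common hyperspectral practice and keeps downstream training
inputs bounded. Calibration is exactly invariant under a common
positive rescaling of `I`, `B`, `W`, which the tests assert.

## The synthetic world

No public dataset accompanies the application that motivated this
package, so every stage is exercised on synthetic data whose *structure*
mirrors the real measurement:

* **Grids.** The faithful grid has 360 bands from 382.3 nm at 1.8 nm
  spacing; a 60-band "desk" grid spans the same range for fast tests.
* **Spectra.** Each class is a flat baseline minus Gaussian absorption
  features. Defect classes share hemoglobin features at 430/545/576 nm
  — depth ordered CBC > CBBR > CBB, following blood content — and a
  water feature at 962 nm whose depth orders near-960 nm reflectance
  CBC > CBB > CBBR. (The qualitative literature description of the
  water band conflicts with its own moisture reasoning; we follow the
  printed curve ordering and expose every depth as a parameter.)
  Background is a brighter featureless baseline. Per-band Gaussian
  noise (default sd 0.02, roughly 2% reflectance) is added and values
  are clipped to `[0, 1]`.
* **Scenes.** Defects are elliptical stamps inscribed in non-overlapping
  annotation boxes (default 10–18 px in 64×64 scenes, 1–3 per scene),
  on the background texture. Everything is seeded and bit-reproducible.
* **Planted-band spectra** (`planted_profiles()`) confine all class
  signal to three windows (420–445, 565–590, 950–975 nm). Each window
  separates exactly *one* class — the other two share its depth — so a
  classifier restricted to a single window is capped near 2/3 accuracy
  and good band combinations must cover at least two windows. Feature
  sigma is chosen so the FWHM equals the window width, which gives the
  selection objective a usable gradient at window edges.
* **Spectrally-twin scenes** (`spectral_twin_profiles()`) make all
  classes render identically in designated pseudo-color bands (a shared
  absorption feature near 700 nm) while differing in class-specific
  windows elsewhere. They operationalize the claim that 2-D-only models
  must confuse the classes while spectral fusion can resolve them.

What the generator does **not** emulate: illumination fields, specular
highlights, carcass geometry, correlated (non-white) noise, and real
hemoglobin line shapes. A green test therefore establishes that the
algorithms are implemented correctly and behave as designed on
well-posed inputs — not that the published real-data accuracies are
reproduced.

## The 1-D CNN spectral classifier

The classifier is a stack of 1-D convolution blocks (kernel 3, ReLU)
with stride-2 max pooling, followed by two fully-connected layers and
softmax. The *faithful* preset uses the VGG-like plan 2-2-3-3-3
convolutions (widths 64, 128, 256, 512, 512): exactly 13 convolutional
layers, 5 pooling layers and 2 fully-connected layers, which the test
suite audits. Training at that scale is not a desk-size job, so a
*scaled* preset (three single-conv blocks, widths 8/16/32) serves the
60-band grid; it reaches the required validation accuracy in seconds.

Numerical choices: Adam (lr 1e-3, batch 32 by default), stratified
seeded 80/20 calibration/validation split, single-threaded and fully
seeded so training is bit-reproducible. The engine (conv/pool/dense
forward and backward passes, softmax cross-entropy, Adam) is written in
vectorized base R because no deep-learning framework is available in
the target environment; every analytic gradient is checked against
central finite differences in the test suite.

Band subsets are fed as **zero-masked full-length spectra** rather than
truncated 3-vectors: a 13-conv/5-pool network cannot ingest length-3
input, and masking keeps one architecture valid for every band
combination.

## Firefly band selection

Each firefly is a set of `k = 3` distinct band indices; its luminance
is the validation score (accuracy by default, macro-F1 selectable) of
the spectral classifier retrained on spectra masked to those bands.
Defaults follow the conventional small-population setup: n = 5,
β0 = 0.5, γ = 0.8, α = 0.6, 100 iterations.

The movement rule is the canonical one — attraction
`β = β0·exp(−γ·d²)` plus a uniform step `α(u − 0.5)` — applied in
band-index coordinates **normalized by the band count**. On raw indices
(spans of 60–360) the exponential underflows for any distinct pair and
the unit-scale α step rounds away, freezing the search; the canonical
formulation assumes an O(1) search domain. After the continuous update,
positions are repaired discretely: rounded, clamped to the grid, and
duplicate indices re-drawn uniformly from unused bands. The globally
brightest firefly takes a pure random step, a standard stagnation
guard.

Per-evaluation classifier seeds are derived from the global seed and
the band combination, so identical combinations always score
identically; scores are memoized and the cache statistics let tests
assert that the number of trainings equals the number of distinct
combinations. The default objective network is deliberately small (two
blocks, batch 64) because it is retrained for every distinct
combination. Whether the production objective should score accuracy,
F1 or mAP is genuinely open; accuracy is the default and the choice is
a parameter. Results report both the final population and the
best-ever combination, since "the selected combinations" could mean
either.

## Detectors and spectral fusion

Both detectors share a compact convolutional backbone (three conv3×3
blocks, max-pooling after the first two — overall stride 4). Compact
stacks, not full CSPDarknet53/VGG16 re-creations, are the point: the
contribution being exercised is the spectral-extraction + fusion
arrangement, and the single retained detection scale mirrors keeping
only the largest head branch of the one-stage reference design.

* **One-stage:** a 1×1 conv head over the final feature map emits, per
  anchor (3 sizes × 3 aspect ratios per cell), an objectness logit,
  four box-coordinate adjustments and class scores. Anchors with IoU ≥
  0.5 to a truth (plus each truth's best anchor) are positives;
  anchors below 0.45 are negatives; the thin band between is ignored.
  The objectness loss uses 3:1 hard-negative mining — averaging over
  all negatives lets a few confidently-wrong anchors persist — and the
  box loss is smooth-L1 on standard center/log-size deltas, weighted
  ×2.
* **Two-stage:** a class-agnostic region-proposal head (objectness +
  coordinate adjustments — the two decision branches) followed by a
  small fully-connected classification head, including a background
  class, on 2×2 ROI-average-pooled backbone features of the surviving
  proposals. No second box-refinement regression is attached; the
  coordinate adjustment lives in the proposal head.
* **Fusion:** the spectral branch extracts each detected box's mean
  spectrum (masked to the selected bands by default; full-spectrum
  selectable), runs the trained 1-D CNN and takes its penultimate
  fully-connected activations. These are concatenated with the box's
  pooled 2-D features and a small fusion head produces the final class
  probabilities, which **replace** the 2-D-only class decision. With
  no stated combination rule, concatenation + replacement is the
  minimal reading of "introduce spectral information to fix 2-D
  misclassification", and it is switchable.

Training is staged for reproducibility: spectral branch first (on
jittered ground-truth box spectra), then backbone + anchor/proposal
head (Adam, one scene per step), then the ROI heads on the frozen
backbone. At inference, duplicate boxes are suppressed
class-agnostically inside `detect()` — duplicates of one object often
carry *different* 2-D class labels, the very failure fusion fixes —
while the exported `nms()` keeps the conventional per-class contract.
The evaluation confidence threshold defaults to 0.5, fixed by the
reference protocol; the NMS IoU threshold defaults to 0.5.

## Metrics

IoU uses half-open pixel-area arithmetic (0-based, half-open boxes
make areas exact integers). Matching is greedy by confidence: each
prediction takes the highest-IoU unmatched truth of its class at IoU ≥
0.5. Precision and recall follow their standard count definitions. F1
is the harmonic mean: the reference text *describes* F1 as a PR-curve
area, but its printed values match the harmonic mean in 10 of 12
cells, so the harmonic mean is implemented (the non-matching cells are
excluded from acceptance, as is one printed mAP that is not the mean
of its own per-class APs). AP integrates the monotone
(all-point-interpolated) precision envelope over recall — the closest
discrete realization of the integral definition — with the 11-point
variant behind a flag. mAP is the plain mean of per-class APs. mIoU
averages matched IoUs within each image and then across images (a
global-mean flag exists). Report tables round half-up to 3 decimals.

## Known limitations

* Real-data accuracies (mAP ≈ 0.9+ on carcass imagery) are not
  reproducible here: the dataset is not public, and the compact
  backbones are intentionally small.
* The pure-R engine is single-threaded and desk-scale; the faithful
  13-layer preset instantiates and is audited but is not trained in
  tests.
* The synthetic localization task is easier than real imagery
  (high-contrast ellipses on homogeneous background); precision of the
  small detectors is the weakest metric and mIoU sits well below the
  published values.
* The firefly search inherits the usual metaheuristic caveat: with a
  desk-scale evaluation budget its advantage over random search is
  modest and is asserted as a median over 10 seeds, not per-run.
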