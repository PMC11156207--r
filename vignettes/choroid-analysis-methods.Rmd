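---
title: "Choroidal segmentation and morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroidal segmentation and morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The choroid is the vascular layer between the retinal pigment epithelium
(RPE) and the sclera. On an OCT B-scan it appears as a bright stromal band
(interstitial tissue) interleaved with dark, irregular vessel lumina.
Quantifying it means answering three questions per scan: where is the
choroidal *region* (between the RPE-choroid junction above and the
choroid-sclera junction below), which pixels inside it are *vessels*, and
where is the *fovea*, since standard morphometry is reported on a
fovea-centred region of interest. From these, three clinically used numbers
follow: choroidal thickness (µm), choroidal area (mm²), and the choroidal
vascularity index (CVI), the vessel fraction of the choroid.

`choroidseg` implements this pipeline end to end: a classical
quantization-based vessel segmenter (MMCQ) with a perturbation-ensemble
majority vote for building vessel labels, a Niblack local-thresholding
baseline, a depth-7 multi-task U-Net that predicts region, vessels and
fovea jointly, the fovea-target construction and read-out, and the
ETDRS-grid morphometry. Because no imaging data ship with the package, a
seeded synthetic B-scan generator with exact ground truth underpins every
test.

All images are numeric matrices in `[0, 1]`; row 1 is the top of the scan
(vitreous side) and indices are 1-based throughout.

# Synthetic B-scans

`generate_bscan()` renders: a retina-like layered complex with a Gaussian
foveal pit; a stromal band whose per-column integer thickness profile is a
slow sinusoid around `choroid_mean_thickness` (default 350 µm, a typical
healthy macular value); dark elliptical vessels whose radii grow toward the
scleral side, mimicking the Sattler-to-Haller size stratification; and
multiplicative log-normal speckle (OCT-like, mean-one, clipped). The masks
record the exact pre-noise geometry, and the generator keeps its per-column
thickness profile and a per-ellipse rasterised area tally so geometric truth
can be read back in tests.

Default conditions: 768×768 px at 11.72 µm/px laterally (a 9-mm, 30-degree
macular line scan over 768 columns) and 3.87 µm/px axially; vessel count 150,
radii 25-140 µm, intensities 0.2 (vessel) on 0.8 (stroma); speckle sigma
0.05. With these settings the planted vessel fraction — hence the phantom
CVI — lands at ≈ 0.52, inside the physiological 0.5-0.65 band. Tests use the
same conditions at a reduced 256×256 field of view (and a thinner,
180-µm-choroid variant at 128×128 for training runs) so the whole suite runs
on a laptop-class CPU.

What the generator does *not* emulate: physically derived speckle statistics
and depth attenuation, curved retinal geometry, the suprachoroidal space,
segmentation-grade boundary ambiguity. Passing tests therefore demonstrate
correctness of the algorithms under controlled geometry, not clinical-grade
accuracy on real scans.

# Vessel ground truth: MMCQ and the 25-variant vote

`median_cut()` recursively splits the bucket with the widest intensity range
at its median until `2^bits` buckets exist. `enhance_multiscale()` tiles the
region's bounding box with patches at several scales, quantizes each patch's
region pixels and histogram-equalizes the quantized values through the
empirical CDF, then averages the per-scale maps. `segment_vessels_mmcq()`
runs one more global median cut over the enhanced region pixels and labels
the darkest clusters vessel.

Two constants deserve comment, since the method's reference description
leaves them to code:

* **Patch sizes** (default `{192, 96, 48}` px). A patch must be larger than
  a vessel lumen: when a patch falls entirely inside a vessel, equalization
  maps its interior across the whole unit interval and destroys the global
  dark-vessel signal. With 25-140 µm radius vessels (up to ~70 px axially)
  the 48-px finest scale is the smallest safe choice; the calibration on
  phantoms (speckle σ = 0.05) gives single-pass Dice ≈ 0.94 and noise-free
  Dice ≈ 0.99.
* **Cluster selection** (default 4 darkest of 8). Median-cut buckets have
  data-dependent populations, so a fixed *count* of clusters can badly
  under- or over-shoot on strongly tied (noise-free) data. Selection
  therefore proceeds dark-to-bright until the cumulative pixel count best
  approaches `n_vessel_clusters / n_global_clusters` of the region — a
  local-quantile prior of 0.5 by default — which reduces to the fixed-count
  rule when clusters are balanced.

`ensemble_majority_vote()` reruns MMCQ on 25 brightness/contrast variants
(five gamma-corrected target means linearly spaced in `[0.2, 0.5]` × five
contrast factors in `[0.5, 3]`) and keeps pixels with at least
`vote_threshold` votes. The default 15/25 reads the "3:2 majority" as a 60%
vote ratio; a simple majority (13/25) is one flag away. The vote is monotone
by construction.

Gamma correction solves `mean(image^g) = target` by bisection on `log g`
over `[1e-3, 1e3]` (tolerance 1e-4 on the mean); images consisting solely of
0s and 1s are fixed points of the transform and are returned at the closest
achievable mean.

# Niblack baseline

`segment_vessels_niblack()` thresholds at `T = m + k·s` over a centred
window (defaults 51 px and k = −0.05, the standard choroidal-vessel
parameters), labelling pixels strictly below `T` inside the region. Local
moments come from integral images centred on the global mean (so constant
regions yield exactly zero variance), with reflection padding; population
(n-denominator) standard deviation, matching the classical formulation.

# Fovea target and read-out

A point target is almost invisible to a pixel-wise loss, so training uses a
smoothed 51×19 target: the fovea pixel is 1.0, its column 0.95, columns at
distance `d` get `0.95 − 0.1·d`, and everything else is 0.01 (one-sided
label smoothing). Read-out sums columns, filters with a normalized 21-tap
symmetric triangular kernel (zero padding) and takes the argmax, ties to the
lowest index. The round trip is exact for columns at least 10 px from the
border; within the clipped border zone the asymmetric window can pull the
argmax one column inward, which the tests assert as such. Row extraction
applies the same filter to row sums; this is a documented package choice, as
the reference procedure for the row is unspecified.

# The multi-task U-Net

The network is a depth-7 U-Net: encoder channel widths `[8, 32, 64, 64, 64,
64, 64]` (the reference pins 8 and 64 as the endpoints of the first three
blocks; 32 is the geometric midpoint), blocks of two 3×3 convolutions each
followed by BatchNorm and ReLU, 2×2 max-pooling between levels, up-blocks of
a 1×1 channel-reduction convolution plus bilinear ×2 interpolation,
concatenative skips, a constant-64-channel decoder, and a 1×1 head emitting
three sigmoid channels (region, vessel, fovea). Inputs must be divisible by
64 (`predict_scan()` reflect-pads and crops otherwise).

No deep-learning framework is involved: the network, its backpropagation,
AdamW and gradient clipping are implemented natively in RcppArmadillo with
float32 arithmetic, convolutions as im2col + SGEMM. The backward pass was
verified against central finite differences layer by layer.

Training follows the stated recipe: per-pixel binary cross-entropy averaged
over the three channels, AdamW (lr 5e-4, weight decay 1e-8), global gradient
norm clamped to 3 before each step, 40 epochs by default. BatchNorm uses
batch statistics during training (batch size 1 by default; larger batches
accumulate gradients) and running statistics at inference. Augmentations are
applied in random order per sample: horizontal flip (p = 0.5), independent
brightness/contrast factors U(0.5, 1.5) (p = 0.95 each), rotation U(−25, 25)°
with shear U(−15, 15)° (p = 1/3), scale U(0.8, 1.2) (p = 1/3); geometric
transforms warp image and targets identically (nearest neighbour for binary
channels, bilinear for the fovea channel) and move the fovea coordinate
through the same affine map. Peripapillary-aspect samples (width = 2 ×
height) are cropped to a square at a random multiple-of-192 offset per
epoch.

At desk scale, 150 epochs on eight 128×128 synthetic scans (≈ 6 minutes on
one CPU core) reach training region Dice ≥ 0.99 and sub-pixel median fovea
error; the test suite asserts Dice ≥ 0.9 and fovea error ≤ 5 px for at
least two of three seeds, with clipped gradient norms never above 3 + 1e-6.

# Morphometry

`extract_boundaries()` keeps the largest connected component and traces the
junctions with a half-pixel convention (`upper = top row − 0.5`,
`lower = bottom row + 0.5`), so a flat band of `t` rows measures exactly
`t·scale_y` µm. The ETDRS ROI spans 3000 µm temporally and nasally of the
fovea (`round(3000/scale_x)` columns, half away from zero, clipped to the
image; volume scans centre at the middle column). Thickness is measured at
the ROI's two edges and centre: the upper-boundary tangent comes from a
linear fit over ±15 columns of a 15-column moving-average trace *in micron
space*, and the inward normal ray is intersected with the linearly
interpolated (and, beyond its span, linearly extrapolated) lower boundary —
on sheared phantom bands up to 25° this recovers perpendicular truth within
2%, including ROI locations clipped to the image edge. Area is pixel
counting times the physical pixel area. CVI divides vessel pixels by total
choroid pixels (bounded by 1; the literal vessel:nonvessel ratio is
available via `literal = TRUE`), and the soft CVI is
`sum(p_vessel · p_region) / sum(p_region)`, chosen so that it reduces
exactly to the hard index on binary maps. Peripapillary scans get masks only
(vessel threshold 0.25 instead of 0.5), as no fovea-centred ROI exists
there.

Degenerate inputs are defined rather than left to chance: empty masks raise
errors; a region column with no pixels is excluded from the traces; a
thickness ray that never meets the lower boundary yields NA with a warning;
a zero-height location yields 0 µm.

# Agreement statistics

`dice_score()` (both-empty defined as 1), midrank Mann-Whitney
`auc_score()`, and `agreement_stats()` with Pearson/Spearman correlations,
mean and median absolute error, Bland-Altman mean difference ± 1.96 SD, and
ICC(2,1) — two-way random effects, absolute agreement, single measurement,
computed from the two-way ANOVA mean squares and cross-checked against an
independent implementation. The ICC variant is a documented choice; the
reference reports "ICC" without specifying one.

# Numerical and testing choices

* Problem sizes in the test suite: 256×256 phantoms for segmentation and
  morphometry, 128×128 for training, 10-seed batteries for stochastic
  checks. These sizes keep the full suite within tens of minutes on one
  core while leaving every algorithmic path exercised.
* Brute-force oracles (windowed moments, recursive median splits,
  exhaustive AUC pair counting) live in the test helpers and are compared
  at 1e-10 or exactly.
* All randomness is funnelled through explicit seeds; the generator, the
  training loop and the pipeline are byte-reproducible given a seed.
* Known limitations: the MMCQ constants are calibrated to the phantom, not
  to any clinical dataset; the fovea-row rule is a package choice; Topcon
  crop sides default to symmetric (16 px left and right) as the reference
  does not state the side; proprietary scanner containers (E2E/VOL/FDA,
  DICOM) are out of scope — PNG/TIFF plus a manifest CSV carry the
  metadata.
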