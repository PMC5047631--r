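---
title: "Methods: models, parameters and numerical choices in npreflect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in npreflect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npreflect)
```

## The problem

Metal-oxide nanoparticles (NPs) reflect light strongly, so reflectance
confocal microscopy (RCM) and reflectance structured illumination microscopy
(R-SIM) can image NP uptake in cells without any label. Two things make the
quantification non-trivial. First, untreated cells reflect light too: every
detection decision has to be made relative to a negative-control baseline,
not an absolute threshold. Second, the two modalities see the same scene at
very different resolutions — RCM at roughly 345 nm lateral / 1077 nm axial
FWHM, R-SIM at roughly 115 nm / 685 nm — so voxel-wise comparisons between
them are meaningless and all cross-modality statements must be made at the
level of detected objects.

`npreflect` implements the full chain — simulation, segmentation,
quantification, resolution measurement, registration — and validates every
quantitative claim against a synthetic generator whose ground truth is known
exactly.

## The forward model

A scene (`generate_ground_truth()`) is an ellipsoidal cell (semi-axes 45% of
the grid extent) containing one or two nuclei and a set of NP clusters with
continuous physical centres, peak amplitudes and Gaussian radii. Rendering
(`render_scene()`) evaluates, per cluster, an anisotropic Gaussian with
per-axis sigma $\sqrt{\sigma_\mathrm{PSF}^2 + r^2}$ (PSF width and cluster
radius combined in quadrature), on voxel centres, preserving the peak
amplitude. The PSF presets store FWHM values; $\sigma = \mathrm{FWHM} /
(2\sqrt{2\ln 2})$.

Three deliberate simplifications:

* **Cellular background.** The inherent reflectance of untreated cells is
  modelled as uniform noise smoothed with a 3-voxel sigma and rescaled
  inside the cell mask to 0.5–1.5 times `background_level`, which defaults
  to 10% of the smallest cluster amplitude (so the texture spans 5–15% of
  it). Nothing is known about the true spatial statistics of cellular
  reflectance; this texture is a pragmatic stand-in with the right amplitude
  relative to NP signal, and its level is configurable.
* **Noise.** Poisson shot noise on the scaled intensity followed by additive
  Gaussian read noise (`noise_params()`). Simple, standard, and sufficient
  for recovery experiments; no attempt is made to model detector-specific
  behaviour.
* **R-SIM axial window.** Structured-illumination reconstruction only
  retains high-contrast in-focus signal, so the R-SIM rendering zeroes each
  cluster's contribution beyond one axial FWHM (±685 nm) from the cluster
  plane. A hard window was chosen because no published attenuation profile
  exists; its only observable consequences (shorter axial persistence,
  missing deep particles) do not depend on the window's exact shape.

TEM-like serial sections (`render_tem_sections()`) integrate each cluster's
axial Gaussian mass over consecutive physical slabs and draw dark spots on a
bright background at ≤10 nm pixels — enough to test slab membership,
min-projections and cross-scale registration, with no pretence of
electron-optics realism.

Conventions throughout: arrays are indexed `(z, y, x)`, voxel `i` (1-based)
sits at physical coordinate `(i − 1) · voxel_size_nm`, and all lengths are
nanometres. Every stochastic function takes a seed and restores the caller's
RNG state, so identical `(parameters, seed)` pairs give bit-identical
output.

## Segmentation

Cells and nuclei are segmented by Gaussian smoothing followed by two-cluster
k-means on voxel intensities, keeping the higher-mean cluster. k-means is
seeded deterministically at evenly spaced quantiles with no random restarts,
so segmentation involves no RNG at all; a constant image raises an explicit
degenerate-input error. On inputs above ~400k voxels the centers are fitted
on a deterministic stride subsample and every voxel is then assigned to its
nearest center (in 1D this is a midpoint threshold rule), which changes
nothing qualitatively and keeps large stacks fast.

NP detection (`segment_np()`) follows the control-normalised recipe:

1. treated and control volumes are pooled and jointly min–max normalised —
   *jointly*, because the treated-vs-control intensity ordering is exactly
   the information the method depends on;
2. each volume is smoothed (default sigma 0.7 voxels for reflectance,
   1 voxel for stains);
3. k-means with `k = 3` (background / cellular reflectance / NP signal)
   clusters the pooled intensities and the highest-mean cluster is kept;
4. voxels must additionally exceed `median + m · MAD` (default `m = 3`) of
   the control images' cellular-reflectance voxels — the control voxels
   assigned to the non-background clusters. Median and scaled MAD were
   chosen as the "robust foreground statistics" because the control
   foreground distribution is skewed by its own upper tail, which mean/SD
   would track too eagerly.

Whether thresholding precedes or follows clustering, and the value of `m`,
are genuinely open in the source methodology; both are exposed as
configuration, and the defaults above are what the validation suite runs.
Increasing `m` can only shrink the mask (a tested invariant), and across
seeded control scenes the detected false-positive volume stays below 0.1% of
the cell volume.

## Quantification

`connected_components()` labels 2D/3D masks under face (6/4-neighbour) or
full (26/8-neighbour, the default, matching the common component-labelling
convention) connectivity; adjacency edges are built vectorised and resolved
with `igraph`. The test suite checks it against an independent brute-force
flood fill on a thousand random masks.

Cross-modality co-occurrence (`cooccurrence()`) counts *components*, not
voxels: a component of mask A co-occurs if at least one of its voxels lies
in mask B's foreground (the voxel-wise product of the binary images). One
shared voxel suffices, and each source component counts once however many
product fragments touch it, so a big RCM blob containing several R-SIM spots
contributes one co-occurring RCM component and several co-occurring R-SIM
components. Centroid-distance matching was deliberately avoided: the product
rule is parameter-free and symmetric in implementation.

The paired-modality experiment (`cooccurrence_experiment()`) compares masks
over a common central z-window of the two stacks. This emulates the
imperfect volume matching of paired real acquisitions and is what produces
the observed asymmetry direction: a particle just outside the compared
window still bleeds into the RCM mask (whose axial response exceeds the
detection threshold out to roughly ±0.9 µm) but is cut from the R-SIM mask
by the reconstruction's hard ±685 nm window, while RCM additionally merges
close cluster pairs that R-SIM separates. The package asserts only the
direction of the asymmetry — the percentages themselves depend on cluster
density, amplitudes and the window size.

`axial_persistence()` reports, per 3D component, the longest run of
consecutive occupied z-slices. A z-gap cannot occur in a 3D-connected
component (any path steps at most one slice), but label arrays imported from
per-slice 2D segmentation can have one; such regions are flagged with a
warning rather than silently truncated.

Group comparisons use the pooled-variance two-sided Student t-test
(`two_sample_ttest()`, delegating to `stats::t.test`; Welch optional).

## Resolution measurement

`line_profile()` samples the image along one axis through a physical centre
at the voxel pitch. Sample positions are snapped to the voxel lattice along
the profile axis, so on-axis samples are exact grid values and only the
transverse coordinates are interpolated (for a separable Gaussian the
transverse interpolation scales the profile without widening it). Sampling
instead at `centre + k · pitch` would low-pass the profile through the
interpolation tent kernel and inflate the estimated width by up to ~10% at
Nyquist pitch — measurable with the package itself by comparing against the
closed form.

`fwhm_from_profile()` takes the half-maximum level as
`baseline + (peak − baseline)/2` and locates the two crossings by linear
interpolation between bracketing samples. Two numerical choices matter at
coarse sampling:

* **Peak refinement.** The raw maximum sample underestimates an off-grid
  peak, which lowers the half-max level and widens the estimate. A parabola
  through the maximum sample and its neighbours (standard sub-sample peak
  interpolation) removes most of this bias; it is on by default.
* **Baseline.** The default is the profile minimum, which is robust when
  residual background is present. The recovery experiments instead measure
  on background-subtracted images with `baseline = "zero"`, because the
  minimum of a noisy window is a downward-biased estimator and inflates the
  width. `subtract_background()` (image minus its own large-sigma blur,
  clipped at zero; default sigma 6 voxels against a detection sigma of 0.7)
  removes both the diffuse cellular reflectance and the texture pedestal
  under each spot.

With those choices the estimator's residual bias at 60 nm pixels is about
−3% for the RCM preset and +8% for the R-SIM preset (whose 115 nm width is
right at the sampling limit — 2 × 57.5 nm); both are intrinsic to
linear-crossing estimation at that pitch and are well inside the ±10%
validation bands. Profiles whose segment leaves the grid, whose peak sits on
the boundary, or which never fall to half maximum are skipped and logged,
never fatal. `split_at_minima()` handles the two-peak case (two structures
one line scan crosses) by cutting at the interior minimum between
consecutive local maxima.

`summarize_fwhm()` reports the sample mean, sample SD (n−1) and a fitted
normal density (the distribution summary conventionally plotted with
resolution histograms), plus a kernel density estimate as a non-parametric
alternative.

## Registration

All transforms are 2D affine maps in physical nanometres, mapping moving to
fixed coordinates; images are resampled by pulling through the inverse map
with bilinear interpolation. Rigid means rotation (times an optional
positive scale) plus translation; reflections are rejected.

* `estimate_from_points()`: orthogonal Procrustes (rigid) or normal
  equations (affine) on known correspondences; exact to machine precision on
  consistent pairs, with collinear affine configurations rejected.
* `register_intensity()`: optional preprocessing (smooth + background
  subtract — without it, differing background offsets dominate the metric
  and registration fails, which the test suite demonstrates), then an FFT
  cross-correlation translation sweep over a coarse rotation grid, then
  Nelder-Mead refinement. Normalised cross-correlation within a modality,
  32-bin mutual information across modalities.
* `cpd_register()`: Coherent Point Drift for correspondence-free point sets
  (e.g. nuclear centroids across light and electron microscopy, where
  shrinkage breaks rigid assumptions). EM on a Gaussian mixture with a
  uniform outlier component; defaults `w = 0.1`, `tol = 1e-8` on the
  variance change, `max_iter = 200`, initialisation at the identity with
  variance set to the mean pairwise squared distance — fully deterministic.
  With `w = 0` and clean equal-size sets it converges to the Procrustes
  solution, which the tests assert to 0.1% relative rotation error. Rigid
  scale estimation is off by default and available for shrinkage
  compensation; the affine variant is provided alongside.

3D registration is out of scope: matched 2D planes (or projections) are
aligned, which is how correlative overlays are actually assembled.

## Validation experiment sizes

The packaged experiments are sized to be decisive but quick on one CPU:

* Lateral recovery: 100 (RCM) / 125 (R-SIM) point reflectors, 20–25 per
  scene on 14 × 320 × 320 grids at (200, 60, 60) nm voxels, SNR 20.
* Axial recovery: ≥20 regions on 36 × 192 × 192 grids.
* Reflectors are placed with an anisotropic exclusion ellipsoid of 2.2 ×
  FWHM per axis so neighbours neither merge into one component nor
  contaminate each other's profiles.
* Co-occurrence asymmetry: 10 seeded paired scenes, 15 clusters each
  (radii 40–120 nm, amplitudes 800–1200), compared over the central 10 of
  22 slices.

## What passing tests do and do not show

The generator produces Gaussian spots, smooth texture and well-separated
cells. Passing recovery tests therefore demonstrates that the analysis chain
is unbiased and correctly calibrated *under its own model assumptions*. Real
reflectance data add effects the generator does not emulate: angle-dependent
reflectance of irregular agglomerates (which shifts perceived spot centres
between illumination geometries), SIM reconstruction artefacts, sample tilt,
photobleaching of companion fluorescence channels, and touching cells. The
control-baseline design and the object-level comparisons are exactly the
mitigations for those effects, but their efficacy on real data cannot be
established synthetically.

## Reproducibility

`run_pipeline()` derives every stage's RNG stream from one master seed and
stamps each report with an MD5 hash of its configuration; re-running with
the same configuration and seed reproduces the report byte for byte.
`scripts/acceptance.R` recomputes the four resolution-recovery means from
scratch for any seed.
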