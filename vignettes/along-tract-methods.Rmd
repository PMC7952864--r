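---
title: "Along-tract tractometry: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract tractometry: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science implemented by `aftract`: what the
spectral along-tract parameterization computes and assumes, how the
normative model turns healthy-control (HC) profiles into abnormality
calls, what the synthetic phantom does and does not emulate, and the
numerical and design choices a maintainer would want spelled out.

## 1. The along-tract coordinate

A probabilistic tractography result for a bundle such as the arcuate
fasciculus (AF) is a *density* (visitation) volume. After thresholding
at a fraction of its maximum (default 0.10, `threshold_density()`), the
binary tract volume is treated as a graph: voxels are nodes, and edges
connect voxels adjacent under a chosen 3-D neighborhood
(`build_voxel_graph()`, default 26-connectivity; 6 and 18 available).

On this graph the combinatorial Laplacian is L = D − A. Its smallest
eigenvalue is 0 with a constant eigenvector, which carries no spatial
information; the eigenvector of the *smallest non-zero* eigenvalue —
the Fiedler vector — is the smoothest non-constant function on the
graph and, for an elongated body, varies monotonically from one end to
the other. It is the natural discrete realization of a "geodetic
trajectory" coordinate for a voxelized tract. Two choices here were
genuinely open:

* **Voxel graph, not a surface mesh.** A triangulated mesh of the
  thresholded volume followed by a mesh Laplacian is an alternative
  realization. The voxel-adjacency graph needs no meshing step, is
  exactly reproducible, and its Fiedler vector recovers the arc-length
  ordering of the test phantoms to Spearman ρ > 0.999, so the simpler
  object is used. Connectivity is configuration, not conviction.
* **Combinatorial (unnormalized) Laplacian.** For near-uniform tube
  cross-sections the combinatorial and random-walk normalized variants
  give nearly identical orderings; the unnormalized form is the
  simplest consistent choice.

The eigenvector is computed densely (LAPACK) for graphs up to 1,500
nodes and otherwise by shift-and-invert power iteration on a sparse
Cholesky factor with deflation of the constant vector; both paths must
meet the eigen-residual bound ‖Lv − λv‖ ≤ 10⁻⁸ (unit-norm v), and they
agree with each other and with path-graph closed forms to 10⁻⁶ in the
test suite.

Sign and scale of an eigenvector are arbitrary, so
`orient_and_normalize()` fixes them anatomically: with the default
`anchor = "frontal"`, the decile of voxels with the smallest raw
coordinate must lie more anterior (greater mean y in the volume's mm
frame) than the opposite decile, so t = 0 is the frontal end; the
coordinate is then min–max rescaled to [0, 1]. Equal anterior means
abort with a request for an explicit anchor rather than guessing.

`segment_labels()` cuts t into K equal-*width* bins (label = ⌊tK⌋ + 1,
t = 1 → K; default K = 15). Equal-width intervals are the literal
reading of "equally spaced"; equal-count quantile binning would
equalize voxel counts instead (the ends of a tube accumulate more
voxels per unit t because the Fiedler coordinate flattens there, a
cosine-like boundary effect) and can be had by transforming t before
labeling.

**Core restriction.** Real bundles fan out toward the cortex, where
intersubject variability dominates. `restrict_core()` trims voxels
anterior to `y_max_mm` or inferior to `z_min_mm` in the volume's mm
frame before graph construction. Published values for such limits are
acquisition- and template-specific (and ambiguous between mm and voxel
indices), so both limits are pure configuration and disabled by
default; the synthetic tube has no branching to trim.

**Disconnected masks.** Thresholding can leave satellite islands.
`parameterize_tract()` keeps the largest connected component, warning
with the discarded fraction, and errors if that component holds less
than half the mask — at that point the "tract" is not one object and no
1-D coordinate is meaningful.

## 2. Tract profiles and the normative model

`segment_medians()` reduces each DTI map (FA dimensionless; MD, AD, RD
in 10⁻³ mm²/s) to K per-segment medians; medians rather than means
because single-voxel artifacts (CSF partial volume, registration
edges) should not move the summary, and non-finite voxels are excluded
because registration padding produces NaN borders in real data.

`build_normative()` then, per parameter and hemisphere:

1. de-medians the HC matrix per segment (x_{s,k} − m_k), putting all
   segments of one parameter on a common, zero-centered scale;
2. pools the de-medianed values of all segments into one distribution
   (the segment-wise n is small — tens of controls — so per-segment
   variance estimates would be noisy; pooling assumes segment-wise
   dispersion is homogeneous after de-medianing);
3. removes outliers beyond `factor` (default 3) times the **mean**
   absolute deviation about the median. This is the literal mean of
   |v − median|, not the conventional median-based MAD; the
   median-based variant is available (`robust = TRUE`). For Gaussian
   data the cut sits at 3·√(2/π) σ ≈ 2.39 σ and removes ≈ 1.7% of
   values;
4. estimates the 2.5th–97.5th percentile interval *from the standard
   deviation* of the kept values: halfwidth h = 1.959964 σ, interval
   [m_k − h, m_k + h]. σ is the ordinary SD about the mean of the kept
   values (centering on their median instead is a one-line change and
   differs negligibly).

Classification (`classify_segments()`) uses strict inequalities —
boundary values are normal — and applies **no** outlier removal to
patients: out-of-range values are the signal, not noise. Counts are
directional (`summarize_subjects()`): decreased FA and AD, increased
MD and RD, the directions expected for vasogenic edema and tumor
infiltration; the two-sided count is also reported.

**Calibration, honestly stated.** Because trimming shrinks σ to
≈ 0.943 of the untrimmed value, h ≈ 1.85 σ_true, and the interval
covers ≈ 93.5% of the *full* Gaussian HC distribution but ≈ 95.1%
(93.5/98.3) of the *outlier-cleaned* distribution whose percentiles it
estimates. The test suite asserts both: ≈ 95% (±2%) coverage of HC
values surviving the MAD filter, and > 90% raw coverage. On null
patients the directional false-positive rate is correspondingly ≈ 3%
per segment (≈ 0.5 of 15 segments), and lesions of ≥ 3 h amplitude are
detected with per-segment sensitivity ≥ 0.95.

## 3. The synthetic phantom

`phantom_spec()` + `make_dti_cohort()` generate everything downstream
stages consume, with known ground truth:

* **Geometry.** A C-shaped centerline in a sagittal plane (7 control
  points, interpolated by a chord-length-parameterized natural cubic
  spline), rasterized as a tube of radius 4 mm with Gaussian density
  falloff (scale 2 mm) on a 64³ grid of 2 mm isotropic voxels — the
  smallest grid on which all 15 segments hold ≥ 20 voxels. The affine
  is RAS with the grid centered at the origin, so "left hemisphere"
  is unambiguously x < 0. Each in-tube voxel records the arc-length
  fraction of its nearest centerline sample: the ground-truth t.
* **DTI cohorts.** Baselines default to realistic healthy AF medians
  (FA 0.43, AD 0.88, RD 0.44; all configurable). MD is always derived
  as (AD + 2 RD)/3, so generated maps satisfy the tensor identity
  exactly — including the MD lesion offset, which follows from the AD
  and RD deltas. Per subject, each drawn parameter gets a scalar
  offset (SD = 0.8 × `subject_sd`) plus a smooth spatial field (white
  Gaussian noise, FFT-smoothed with a 2-voxel kernel, rescaled to
  0.6 × `subject_sd`), so the per-voxel across-subject SD equals
  `subject_sd` (0.8² + 0.6² = 1) while maps remain spatially smooth.
  Patients additionally receive additive `lesion_deltas` (default
  FA −0.06, AD −0.06, RD +0.18, scaled per patient) on voxels whose
  ground-truth segment is lesioned; values are clamped to physical
  ranges with a warning. Defaults were chosen once to sit between the
  low-grade and high-grade patient ranges of published AF tractometry
  and are configuration, not constants.
* **Activation maps.** `make_zmap()` places suprathreshold voxels in
  disjoint left/right ROI masks so the realized (L−R)/(L+R) matches a
  target laterality index up to 1/total rounding (< 0.01 at the
  default budget of 400 active voxels), with all other voxels strictly
  below threshold.

What the phantom does **not** emulate: raw diffusion-weighted signals
and tensor fitting, EPI distortion, registration error, tumor
mass-effect deformation of the tract, realistic fMRI time series, or
spatially structured (non-stationary) noise. Passing tests therefore
demonstrate that the *analysis* recovers known truth from idealized
inputs — not that acquisition and preprocessing artifacts are
handled.

## 4. Statistics

With four versus five patients, large-sample approximations are not
defensible, so `mann_whitney_exact()` evaluates the exact permutation
null of the mid-rank U statistic — enumerated by dynamic programming
over doubled mid-rank sums, which is identical to enumerating all
C(n₁+n₂, n₁) group assignments (and is verified against that brute
force in the tests) but remains feasible to a combined n of 25. The
two-sided p is 2·min(P(U ≤ u), P(U ≥ u)) capped at 1, which yields
exactly p = 1 for a centered U. `bh_adjust()` is the standard
Benjamini–Hochberg step-up adjustment (via `stats::p.adjust`), applied
across the full measure battery, with significance declared at
FDR < 0.1 — an adaptive threshold appropriate for cohorts under 20
subjects. `spearman_rho()` computes ρ on mid-ranks with either an
exact permutation p (n ≤ 8) or the Student-t approximation used by
mainstream statistics software; the approximation is the reporting
default for comparability, and the method used is recorded in the
output.

## 5. Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → parameterize → profile → normative
→ classify → laterality → compare, writes every stage product
(NIfTI volumes, TSV tables) plus a JSON manifest with a configuration
hash, seed, versions and stage wall-times, and is byte-reproducible
under a fixed seed. All randomness flows from the single seed in
`run_config()`.

Default sizes were chosen to keep examples and the test suite fast
while preserving the regime of interest: the bundled pipeline tests
run 8–16 controls and 4 patients on 32³–64³ grids (the phantom tube
has ~800 voxels, comfortably above the ~50 per segment needed for
stable medians); calibration and recovery properties are evaluated at
the profile level (32 controls × 15 segments, 100 Monte-Carlo
cohorts), where the normative arithmetic — not volume handling — is
what is under test.

## 6. Known limitations

* The Fiedler coordinate compresses near the tract ends, so end
  segments hold more voxels than central ones; segment *counts* are
  comparable across subjects (same geometry after registration) but
  not across segments.
* The normative interval is symmetric and Gaussian-calibrated; heavy
  asymmetric tails in real HC data would make the nominal 95% only
  approximate (the outlier filter mitigates, but the package does not
  model skewness).
* One hemisphere is simulated by default; bilateral analyses simply
  run the machinery per hemisphere, but no interhemispheric coupling
  is modeled.
* The laterality index inherits its threshold dependence: LI is
  defined on voxel counts above Z = 3.1 and can shift with that
  threshold; the strictness of the inequality is configurable but a
  convention must be fixed (strict ">" here).
* `correlate_with_li()` reports grid-wide BH-adjusted q-values; with
  ~10 subjects only very strong correlations survive, and unadjusted
  p-values should be treated as exploratory.
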