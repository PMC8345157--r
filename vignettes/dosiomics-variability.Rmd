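---
title: "Dose-distribution texture features and their variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-distribution texture features and their variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosetex)
```

# Scope

`dosetex` evaluates how texture ("dosiomic") features extracted from 3D
radiotherapy dose distributions behave across cohorts of plans: how
reproducible they are under near-identical planning conditions, how stable
across machines of the same family, and how sensitive to genuinely
different techniques and dose-grid resolutions. This vignette documents
the model, the parameters that matter, the numerical conventions, and the
boundaries of what the synthetic test bed can and cannot show.

# The feature panel

The dose grid is treated as an image whose voxel value is absolute dose in
Gy. Per ROI:

* **STAT (17)** — intensity statistics computed on raw dose, with
  population (1/n) moment conventions. Kurtosis is excess kurtosis.
  "Median absolute deviation" is the *mean* absolute deviation about the
  median, and the robust mean absolute deviation restricts to values
  within the 10th–90th percentile band, following the radiomics
  standardisation conventions. Percentiles use R's default (type 7)
  quantile; at cohort sizes of thousands of voxels per ROI the choice is
  immaterial, and it is stated here because it is a convention, not a
  result.
* **GLCM (100)** — grey-level co-occurrence at Chebyshev distance 1,
  symmetrised. 25 features under four aggregations: per-slice
  per-direction averaged (`2D_avg`), per-slice direction-merged then
  slice-averaged (`2D_merge`), full-volume per-direction averaged over the
  13 unique 3D directions (`3D_avg`), and all directions merged
  (`3D_merge`).
* **GLRLM (64 − 1 = 63)** — maximal runs of equal level, truncated at the
  mask boundary, 16 features under the same four aggregations. The panel
  totals 63, not 64: one (feature, aggregation) entry is excluded by
  configuration. The default drops `run_entropy` under `2D_avg`; the
  binding constraint is the family count, and `default_registry()` lets a
  user drop a different entry. Run percentage uses the voxel count of the
  matrix's domain, multiplied by the number of merged directions when
  matrices are merged.
* **GLSZM (32)** — zones are connected components of equal level
  (26-connectivity in 3D, 8-connectivity within slices), 16 features under
  two aggregations (all per-slice matrices merged; single 3D matrix).

Morphological/shape features are deliberately absent: the analysis
concerns the dose texture, not the (fixed, shared) contours.

**Discretisation.** Texture families operate on `G = 100` grey levels from
zero to the maximum dose: `level(d) = min(G, floor(d / d_max * G) + 1)`;
bins are left-closed/right-open with the top level closed, so `d = 0` maps
to level 1 and `d = d_max` to level 100 deterministically. `d_max` is the
ROI maximum by default (`range_mode = "roi_max"`), which keeps level
occupancy comparable between a 66 Gy target and a 2 Gy organ at risk and
makes all texture features invariant under positive rescaling of dose. A
`global_max` mode is provided because either reading of "zero to max dose"
is defensible; the mode used is recorded in every provenance attribute.

**Undefined values.** Degenerate inputs produce flagged `NA`s rather than
arbitrary numbers: skewness/kurtosis of a constant ROI, correlation-type
GLCM features of a single-level matrix. Aggregation averages skip `NA`
components; downstream CV analysis drops them pairwise and reports
`n_used`.

# Cohort variation analysis

For each feature, across the plans of one cohort,
`CV = sd / |mean|` with the *sample* (n − 1) standard deviation — cohorts
have 4–11 plans, where the denominator convention is material, so it is
recorded in every report manifest. A zero mean flags the CV undefined.

Thresholds follow the study protocol: stable features have `CV < 0.3` in
the reproducibility/stability cohorts, sensitive features `CV > 1`
(secondary threshold `CV > 0.8`) in the sensitivity cohorts, with strict
inequalities in both directions. Selection percentages always use the full
registry size (212) as denominator, never the defined-CV subset; the
number of defined CVs is reported alongside. The two sensitivity
resolutions are analysed separately and intersected.

ICC (two-way random effects, absolute agreement, single rater) is provided
as a secondary metric with ROIs as subjects and plans as raters, in three
conventional groups (all / high-dose / low-dose ROIs). Variance components
come from the ANOVA mean squares and are truncated at zero. Because the
ROIs carry very different dose levels, between-subject heterogeneity can
inflate the ICC; `icc_study()` attaches that caution to its output, and CV
remains the primary metric.

# The synthetic phantom and plan generator

No public multi-centre dose dataset accompanies this problem, so the
package generates its own study conditions. The phantom is an analytic
cylinder (PMMA-like, radius 100 mm, length 160 mm at scale 1) with four
rectangular density inserts (lung 0.30, bone 1.50, muscle 1.05, adipose
0.95 relative electron density). Seven ROIs emulate a mono-lateral
head-and-neck geometry: an ellipsoidal PTV offset to one side and abutting
the right parotid, a mirrored left parotid far from the target, a
posterior spinal-canal cylinder with its 4 mm PRV expansion, a central
trachea cylinder, and a RING built by Euclidean expansion of the PTV
cropped at its surface. This reproduces the qualitative dose-geometry
relationships that drive feature behaviour: RING and right parotid live in
the gradient region, spinal canal/trachea/left parotid in low dose, the
PTV on a plateau.

The dose model is a sum of separable smooth fields, not beam transport:

* prescription plateau inside the PTV (66 Gy, with a small
  technique-specific heterogeneity pattern and a ~1% boost);
* exponential fall-off outside with technique-specific length scale
  `gradient_scale_mm` (6–14 mm across the built-in technique kernels) and
  a penumbra offset, evaluated analytically at any grid resolution;
* multiplicative organ-sparing attenuation bumps around the OARs,
  applied outside the PTV only (emulating optimiser objectives);
* spatially correlated Gaussian noise: white noise smoothed to
  `texture_corr_len_mm` (default 6 mm) and rescaled to `noise_sd_Gy`, with
  a dose-proportional envelope, then clipped at zero. Smoothing in mm
  makes the perturbation statistics grid-resolution independent.

Only the statistical structure of the dose — plateau, gradient, correlated
texture — matters for feature-variability testing, which is why beam/arc
geometry, MLC sequences and dose-engine physics are out of scope.

**Cohort regimes.** `generate_cohort()` renders

* *reproducibility*: 4 plans, one technique, ±2% fall-off jitter, 0.4 Gy
  noise — different centres replicating one protocol on one machine model;
* *stability*: 8 plans — the 4 reproducibility plans (nested, as in a
  multi-centre design where the reproducibility subset is drawn from the
  stability pool) plus 4 with ±10% fall-off jitter and 0.8 Gy noise —
  same technique on different machines;
* *sensitivity*: 11 plans cycling through 6 technique kernels (±5%
  jitter, 1.0 Gy noise), each rendered at a fine and a coarse grid — 22
  dose grids. The fine/coarse pair defaults to the reference spacing and
  twice it; at the default test scale that is 3 mm / 6 mm, standing in
  for the 1 mm / 2 mm clinical design (tables are tagged
  `sensitivity_fine` / `sensitivity_coarse` rather than misnaming the
  spacings).

Noise levels and jitters were fixed once, ordered so that the intended
contrast (reproducibility < stability < sensitivity variation) is built
into the generator; they are conditions, not tuning knobs.

Every generated plan is checked against the planning protocol
(`check_constraints()`): PTV D98% > 95% of prescription and V105% < 10%,
Dmax < 45 Gy for spinal canal and PRV, RING Dmax < 95% of prescription,
Dmean < 50/25 Gy for trachea/parotids. D98% is the inverse-ECDF (type 1)
2% quantile; V105% the fraction of voxels at or above 1.05 × prescription.
When the dose grid differs from the reference grid, QA is evaluated on the
*dose calculation grid* with the structures rebuilt there from the
analytic geometry — resampling a coarse dose onto the fine mask grid blurs
the PTV boundary and corrupts D98% with a pure partial-volume artifact,
which is also how planning systems evaluate DVHs. Feature extraction, by
contrast, always resamples dose (trilinearly) onto the fixed mask grid and
never interpolates masks, mirroring an analysis with centrally contoured,
shared structures; interpolating masks would invent texture.

**Determinism.** Every generator output is a pure function of its
specification and seed; per-plan seeds expand from one base seed via a
counter, and the RNG state of the caller is never disturbed. Two
extraction runs on the same input are bit-identical, which is the
package's software-reproducibility check (424 compared values per plan
pair at two resolutions).

# Numerical and I/O choices

* Arrays are stored `values[x, y, z]` (column-major, the natural R
  layout) with spacing/origin as `c(x, y, z)` in mm, voxel-centre
  convention; this matches the DICOM pixel ordering (columns fastest)
  without any transposition.
* Euclidean dilation (PRV, RING) thresholds an exact anisotropic
  ellipsoidal structuring element, implemented by FFT convolution;
  "isotropic 4 mm" means 4 mm in every physical direction regardless of
  voxel shape.
* Trilinear resampling is exact for affine fields; voxels outside the
  source extent become 0 Gy and are counted in a coverage attribute.
* Contour rasterisation uses voxel-centre inclusion under the even-odd
  rule (winding-order invariant, holes supported); mask-to-contour export
  traces the 0.5 level set per slice. A mask survives the
  mask → contours → mask round trip up to the one-voxel boundary shell.
* DICOM I/O is a minimal explicit-VR little-endian codec for RT-Dose and
  RT Structure Set: 32-bit dose pixels with scaling chosen for ≤ 0.001 Gy
  quantisation error, axis-aligned orientations only; unsupported
  dialects (tilted orientations, non-uniform frame offsets, non-Gy units)
  are rejected loudly rather than approximated.
* The internal array format (gzip doubles + JSON geometry sidecar) round
  trips exactly and is used for cohort archives.

# What the test bed does and does not show

The synthetic cohorts emulate the *statistical* situation of a
multi-centre phantom study: one shared geometry, common constraints,
controlled technique/noise variation, two grid resolutions. Tests that
pass on them demonstrate that the pipeline's bookkeeping (212 features ×
6 ROIs × 4/8/22 plans), its determinism, its matrix algebra (verified
against brute-force enumeration oracles) and its CV/selection logic are
correct, and that the expected ordering of variation
(reproducibility ≤ stability ≤ sensitivity medians) emerges from the
generator's conditions.

They do not show how real TPS dose engines differ, nor reproduce any
clinical cohort's CV tables or common-feature percentages — the synthetic
plans have no beam physics, no optimiser convergence noise, and no
machine-specific penumbra shapes. Absolute CV values from this package's
synthetic runs characterise the generator, not any clinic.

One discretisation property deserves emphasis: on a near-constant dose
plateau (the PTV), ROI-max binning stretches a tiny dose range over 100
levels, so at *low* noise the texture is a coarsely quantised noise
pattern and feature CVs between plans can be large, shrinking as noise
grows and fills more levels. The median CV over the full six-ROI output
increases with the generator's noise level, but a plateau ROI considered
alone need not — worth remembering when interpreting target-region
dosiomics on any absolute-dose binning.

# Problem sizes

The default study scale (`phantom_spec()`: 3 mm grid, scale factor 0.5,
≈ 45k voxels, ROI sizes from ~80 voxels for a parotid to ~3.3k for the
RING) runs the complete three-design study — 30 dose distributions, 38,160
feature values, CV/selection analysis and QA — in about a minute on one
CPU. Unit tests use a smaller phantom (4 mm, scale 0.35) via the same
`scale_factor` mechanism that exists precisely so the geometry can shrink
without changing the model. The brute-force oracle suites run on ≤ 4³
arrays where exhaustive enumeration is trivially correct.

# Known limitations

* The phantom geometry is plausible but uncalibrated: no public reference
  states the original phantom's ROI volumes, so absolute volumes (and
  hence zone-size scales) are package choices.
* The dose model's sparing bumps and penumbra are phenomenological; OAR
  DVH shapes are only qualitatively realistic.
* `simulate_plan()` requires the analytic phantom geometry; it does not
  synthesise dose onto arbitrary imported structure sets.
* The DICOM codec reads the dialect it writes plus well-behaved
  axis-aligned exports; it is not a general-purpose DICOM library.
* The exact membership of the 212-feature panel (which run-length entry
  is dropped; whether STAT includes histogram-entropy variants) is a
  registry configuration with a documented default; the family counts
  17/100/63/32 are the binding contract.
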