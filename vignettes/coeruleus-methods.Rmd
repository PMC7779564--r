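---
title: "Methods: threshold-based LC mapping, atlas construction and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based LC mapping, atlas construction and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coeruleus)
```

This vignette is the package's own account of its models, conventions and
design choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The locus coeruleus (LC) is hyperintense on magnetisation-transfer (MT)
weighted images because its MTR is low relative to the surrounding pontine
tegmentum. The pipeline consumes spatially normalised, axis-aligned NIfTI
volumes on a common 0.5 mm isotropic grid (registration is out of scope and
assumed done) and proceeds in five stages.

1. **Repeat averaging.** MT-on acquisitions are repeated (default 3) and
   averaged voxelwise. For independent additive noise, averaging *m* repeats
   raises region SNR by √m; the test suite verifies the √3 gain empirically
   over 200 Monte-Carlo draws.

2. **Reference statistics and threshold.** A reference region supplies
   `Mean_REF` and `SD_REF` (sample SD, denominator n − 1 — the estimator is
   a package choice, as either convention is defensible and the unbiased
   variance is the statistics default). The segmentation threshold is
   `T = Mean_REF + k·SD_REF` with default `k = 5`, the stringent choice
   appropriate to high-SNR data; `k = 4` reproduces the more liberal
   variant of earlier 3 T pipelines. Membership is strict (`> T`): a voxel
   must exceed the reference mean *by more than* k SDs, so ties at `T` are
   excluded.

3. **Searching-area segmentation.** Candidate voxels are restricted to a
   bilateral searching area: a stack of 2.5 mm-diameter discs, one per
   axial slice, spanning template slices 86–112. Slice numbers follow the
   anchor convention `z = −16 + 0.5·(slice − 112)` mm (slice 112 at the SCP
   decussation, slice 86 at the 4th-ventricle recess; 27 slices = 13.5 mm);
   the anchor is configurable because slice numbering drifts across
   templates. Disc membership is center-within-closed-radius: on the 0.5 mm
   grid a 2.5 mm disc centered on a voxel-center covers 21 voxels, and the
   27-slice stack 567 voxels = 70.875 mm³ (printed as 70.88) — the only
   membership rule consistent with volume-matching against the
   4 × 4 × 4.5 mm³ = 72 mm³ reference cube. Cubes use a half-open rule
   (center in `[c − d/2, c + d/2)` per axis) so a 4 × 4 × 4.5 mm box covers
   exactly 8 × 8 × 9 = 576 voxels. Hemispheres split at world x = 0; midline
   voxels (x = 0 exactly) belong to neither, keeping assignment
   deterministic.

4. **Probabilistic atlas.** Individual binary masks are added and averaged;
   each nonzero atlas value is an exact multiple of 1/n. Thresholding is
   *inclusive* (`≥ p`; the >/≥ choice is undocumented in the protocols this
   mirrors, so ≥ is fixed here and documented): with n = 53, the 5%
   template keeps voxels segmented in at least 3 subjects. Slice profiles
   (mean/median/max probability) are computed over nonzero-probability
   voxels only, per hemisphere; the median uses lower interpolation
   (`quantile(type = 1)`) so it stays on the discrete k/n grid.

5. **CNR extraction.** `CNR = (V − Mean_REF)/SD_REF` on the averaged MT-on
   image — noise estimated by the SD, not the mean, so a voxel at the k-SD
   threshold has CNR exactly k (an algebraic identity the tests exercise on
   random stats). Contrast is summarised two ways: per-slice *peak* CNR
   over segmented voxels (peak ties broken deterministically by lowest
   voxel index in x-then-y scan order; slices with no suprathreshold voxel
   yield explicit missing records, never imputations), and mean CNR inside
   the fixed 5%/25% atlas templates. The atlas route is the volumetric-bias
   control: because the mask is identical across subjects, a subject with
   focal signal loss cannot compensate by segmenting a smaller, brighter
   volume. The ablation test (caudal half of the nucleus erased in one of
   two otherwise identical subjects) shows the atlas-based mean dropping
   while the segmentation-restricted mean barely moves.

MTR maps are computed from a *single* MT-on repeat paired with the MT-off
scan, while CNR uses the repeat average — the two quantities deliberately
follow distinct pipelines. MTR voxels with near-zero MT-off denominators
(≤ 1e-6 × the volume maximum by default) are flagged missing rather than
returned infinite.

### Reference-region evaluation

Six candidates are scored per subject: central/dorsal/left/right pontine
tegmentum (4 × 4 × 4.5 mm cubes) and left/right SCP (clones of the
searching-area geometry, translated to the SCP roots, hence exactly
volume-matched). The selection rule formalises the qualitative protocol
"high SNR, high MTR, no lateralised baseline": paired two-sided t-tests
(α = 0.05, uncorrected — a documented limitation, matching common practice
for half a dozen planned contrasts) compare left vs right mean signal for
each bilateral pair; bilateral candidates failing the gate are excluded
unless the LC itself is lateralised (in which case ipsilateral referencing
becomes admissible and is flagged); survivors are ranked by cohort mean
SNR, then MTR, then candidate order. In the phantom, the PT cubes all
sample statistically identical tissue, so which of them wins is decided by
sampling noise — the rule is still fully exercised, but the phantom cannot
reproduce an in-vivo preference for one PT subregion over another.

## The phantom cohort

`phantom_config()` defines the synthetic study the package validates
itself on. Defaults and what they encode:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 53 | cohort size |
| `grid` | 48³ voxels, 0.5 mm, origin (−12, −12, −34) mm | pons-sized field; slices 86–112 interior with margin; x = 0 on a voxel-center column |
| `tissue_mtr` | pons 0.45, SCP 0.55, LC 0.25, ventricle 0.02 | MT saturation per tissue; LC < pons is what makes the nucleus bright on MT-on |
| `mt_off_intensity` | pons/SCP/LC 1000, ventricle 600, background 100 | baseline signal |
| `lc_x_mm`, `lc_y_mm` | ±4, 2 | mean tube centerline |
| `lc_radius_mm` | 1.25 central → 0.6 at both ends | rod-shaped width taper |
| `lc_amplitude` | 1 central → 0.6 at both ends | contrast gradient rising rostral→central and falling central→caudal; the end value is a package choice (no published per-slice amplitude exists to fit), set once so end-slice CNR stays detectable but clearly weaker |
| `jitter_sd_mm` | 0.25 central → 0.6 caudal | per-slice center jitter; reproduces the caudally increasing between-subject scatter |
| `noise_sd` | 27.5 | additive Gaussian noise per repeat, making single-repeat pontine SNR ≈ 20 |
| `n_repeats` | 3 | MT-on repeats |
| `age_range`, `male_fraction` | 52–84, 29/53 | cohort table |
| `right_intensity_factor` | 1 | set to 1.05 to inject a +5% right-hemisphere bias for asymmetry power tests |

The signal model is exact: noiseless MT-off is the baseline map, noiseless
MT-on is `MT-off × (1 − MTR)`, and LC voxels blend the pontine MTR toward
the LC MTR by the *exact* in-plane disc/voxel overlap fraction (piecewise
closed-form circle–rectangle integration, validated in tests against the
πr² identity), scaled by the slice amplitude. Ground truth keeps voxels
with overlap fraction ≥ 0.5. Noise is Gaussian, not Rician: the analysis
averages magnitude images whose SNR ≫ 3, where the Rician correction is
negligible, and no noise model is prescribed by the protocols this
emulates. Per-subject RNG streams are derived deterministically from the
top-level seed, so cohorts are bit-reproducible and subjects independent.

A bright low-MTR stripe medial to the tubes stands in for the 4th
ventricle, so searching-area placement must avoid contaminated voxels just
as it must in vivo. A geometric subtlety the phantom surfaced: with the
half-open cube rule, a cube whose boundary crosses a tissue edge clips it
asymmetrically between hemispheres; the left/right PT cubes are therefore
placed at (±4, −5.5) mm where they sample pure pontine tissue, keeping the
symmetric cohort genuinely symmetric.

What the phantom does **not** emulate: bias fields, B1 inhomogeneity,
motion, physiological noise, Rician magnitude statistics, registration
error, and any real anatomical variation beyond per-slice center jitter.
Passing recovery tests therefore demonstrates correctness of the
*analysis* under its stated assumptions, not robustness to acquisition
artefacts.

### The flat-top tube and peak localisation

The tube is flat-topped by construction (contrast varies only through
partial volume at the rim and the per-slice amplitude), which makes all
core voxels on a slice equal in expectation; the per-slice peak-CNR voxel
is then noise-random among them. Peak *localisation* is consequently
assessed discretely: a peak counts as recovered when the peak voxel lies in
the 3 × 3 in-plane neighbourhood of the voxel containing the true jittered
center. Sub-voxel peak agreement is not a meaningful target under this
signal model. The same effect compresses the caudal-vs-central peak-scatter
ratio: the flat core adds a roughly uniform within-disc pick variance
everywhere, and the wider central disc adds more of it centrally, partially
offsetting the configured jitter gradient — the gradient survives (the
tests assert caudal > central) but is flatter than the 0.6/0.25 jitter
ratio alone would suggest.

## Numerical and degenerate-input conventions

* Grid compatibility is exact (shape, voxel size, origin within 1e-6 mm);
  nothing resamples. Oblique affines (off-diagonal > 1e-3 relative) are
  rejected at read time.
* Disc membership uses a 1e-12 slack on the squared radius so exact-tie
  voxel centers (the worked 21-voxel example) are included regardless of
  floating-point representation; atlas thresholds use a 1e-12 slack on
  `≥ p` for the same reason.
* Zero-variance reference regions, empty searching areas, two-empty-mask
  Dice, and all-flagged MTR maps raise typed errors rather than NaNs.
* Missing peaks propagate as `NA` through SD profiles (slices with < 2
  observations report `NA`) and as available-case means into the cohort
  table; nothing is imputed.
* Age regressions are plain OLS (`lm`), reported with F(df1, df2) where
  df2 = n − 2; sex tests are pooled-variance t-tests (df = n − 2).

## Problem sizes used in validation

The shipped tests run the full pipeline on a 20-subject default-parameter
cohort (recovery Dice, volume ratio, peak tracking, scatter gradient,
atlas properties), a 53-subject cohort in the acceptance script, 250
subjects for jitter-SD calibration, 200 Monte-Carlo draws for the √3
averaging gain, and 500 simulated null cohorts of n = 53 for the type-I
calibration of the age regression. The type-I simulation draws (age, CNR)
pairs from the cohort model directly rather than regenerating full image
volumes per replicate — under the null the regression consumes only the
cohort table, so the image stages would add cost without information.
These sizes are the package's validation design; `phantom_config()` scales
all of them.

## Known limitations

* Only axis-aligned grids; no resampling, no oblique or DICOM input.
* The asymmetry gate tests are uncorrected for multiplicity.
* The suitability rule (gate, then SNR-then-MTR ranking) is one
  formalisation of a qualitative protocol; alternatives (e.g. weighted
  scores) would need only `evaluate_references()` to change.
* Atlas probabilities are comparable across cohorts only at equal n, since
  the probability grid is k/n.
* Bayesian model comparison and canonical correlation analyses sometimes
  reported alongside these pipelines are out of scope; the report JSON
  reserves fields (`bayes_factors`, `cca`) so they could be added without a
  schema change.
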