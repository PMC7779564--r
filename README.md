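# coeruleus

Threshold-based mapping of the locus coeruleus (LC) from
magnetisation-transfer (MT) weighted MRI: semi-automated segmentation,
population probabilistic atlas construction, and volumetrically unbiased
contrast-to-noise (CNR) extraction — with a synthetic phantom cohort that
lets the whole pipeline be tested end to end against known ground truth.

## The problem

The LC is a small (~1–2.5 mm wide, ~13.5 mm long) noradrenergic nucleus in
the dorsal pons. Its neuromelanin-rich tissue has a relatively low
magnetisation-transfer ratio (MTR), so it appears hyperintense on MT-on
images. Manual delineation of so small a structure is unreliable, and
contrast estimates averaged over each subject's own segmentation are
inflated by between-subject volume differences. This package implements the
standard remedy as reusable, tested R functions operating on spatially
normalised NIfTI volumes (0.5 mm isotropic, axis-aligned):

* **Reference statistics** — for a candidate reference region,
  `Mean_REF`, sample SD `SD_REF`, and `SNR = Mean/SD`.
* **MTR map** — `MTR(%) = (MToff − MTon)/MToff × 100`.
* **Segmentation threshold** — `T = Mean_REF + k·SD_REF` with the stringent
  default `k = 5` (a 4-SD variant is selectable); voxels inside a
  geometrically constrained bilateral *searching area* (stacked 2.5 mm
  discs spanning template slices 86–112, i.e. z = −29…−16 mm) whose MT-on
  intensity strictly exceeds `T` are classified as LC.
* **CNR map** — `CNR = (V − Mean_REF)/SD_REF`, so a voxel exactly at the
  5-SD threshold has CNR exactly 5.
* **Probabilistic atlas** — voxelwise average of the individual binary
  masks; thresholded at 5% (sensitive) or 25% (specific) into templates
  within which mean CNR is extracted over a *fixed* volume for every
  subject.
* **Reference evaluation** — paired left/right asymmetry t-tests plus
  SNR/MTR ranking to justify the reference-region choice.
* **Cohort statistics** — slice-wise voxel counts and peak-coordinate SD
  profiles, OLS age regressions (with `tidy()`/`glance()` methods), and
  pooled-variance sex t-tests.
* **Mask agreement** — Dice similarity coefficient
  `DSC = 2|I∩S|/(|I|+|S|)`.

Because the raw in-vivo scans behind such studies are typically available
only on request, the package ships a first-class synthetic cohort generator
(`phantom_config()`, `generate_cohort()`) that emulates the statistical
structure the analysis assumes: rod-shaped low-MTR nuclei with rostrocaudal
amplitude/width gradients, caudally increasing spatial jitter, a bright
4th-ventricle midline stripe, SCP tissue, repeat acquisitions with additive
Gaussian noise, and a cohort table (default 53 subjects, ages 52–84,
3 MT-on repeats each).

## Worked example

```r
library(coeruleus)

cfg <- phantom_config(n_subjects = 8, seed = 42)
rep <- run_recovery_experiment(cfg)
rep
#> <recovery_report> n = 8, seed = 42, reference 'right_pt'
#>   mean Dice 0.925, volume ratio 0.937, atlas max p 100.00%
#>   checks: 7/7 passed
```

Mean Dice 0.925 says the thresholded segmentations overlap the generator's
ground-truth masks well; volume ratio 0.937 means total segmented volume is
within 7% of truth. Under the hood, one subject looks like this:

```r
subj <- generate_subject(cfg, 1)
avg  <- average_repeats(subj$mt_on_repeats)
ref  <- build_reference_roi(phantom_reference_specs(cfg)$central_pt, cfg$grid)
(st  <- region_stats(avg, ref, name = "central_pt"))
#> <reference_stats> central_pt: mean 550.5, SD 15.8, SNR 34.84 (n = 576)
segmentation_threshold(st)
#> [1] 629.5466
seg <- segment_lc(avg, build_searching_area(phantom_search_spec(cfg), cfg$grid),
                  segmentation_threshold(st), cnr_map(avg, st),
                  subject_id = "sub001")
seg
#> <segmentation_result> sub001: 540 voxels (L 276 / R 264) above T = 629.5
head(slice_profiles(seg), 3)
#> # A tibble: 3 × 8
#>   subject_id slice hemisphere count peak_x peak_y peak_z peak_cnr
#> 1 sub001        86 left           3   -4        2  -29       9.60
#> 2 sub001        87 left           4   -3.5      2  -28.5     8.99
#> 3 sub001        88 left           4   -3.5      2  -28       7.89
```

The reference mean 550.5 and SD 15.8 give the 5-SD threshold 629.5; the
peak records are the per-slice maximal-CNR voxels used for the spatial
variability profile. Cohort-level inference is broom-friendly:

```r
glance(age_regression(rep$subjects, "peak_cnr"))
#> # A tibble: 1 × 10
#>   response     n min_age f_statistic   df1   df2 p_value r_squared  slope
#> 1 peak_cnr     8      NA       0.937     1     6   0.371     0.135 0.0132
```

As expected for a phantom whose contrast is independent of age, the age
effect is null (p = 0.371). `autoplot()` on the atlas, and
`plot_slice_counts()` / `plot_spatial_sd()` / `plot_age_effect()` on the
report tables, produce the standard slice-wise figures.

Geometry conventions worth knowing: voxel indices are 0-based, world
coordinates are voxel-center based (RAS), disc membership is
center-within-closed-radius (a 2.5 mm disc on the 0.5 mm grid covers
21 voxels per slice; the 27-slice searching area is 567 voxels = 70.88 mm³,
volume-matched to the 4 × 4 × 4.5 mm = 72 mm³ reference cube), atlas
thresholding is inclusive (`≥ p`), and hemispheres split at world x = 0.

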