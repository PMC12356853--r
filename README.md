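# fcdmaps

Voxel-based detection of focal cortical dysplasia (FCD) type II on
T1-weighted MRI, with a normative-template z-scoring framework, an
automated post-resection-cavity detector, and a DICE / percent-overlay /
ROC evaluation layer — validated end-to-end on synthetic head phantoms.

## Who this is for

FCD type II is the leading cause of drug-resistant pediatric epilepsy, and
its lesions — blurring of the gray–white matter junction, focal cortical
thickening, abnormal gray-matter signal — are subtle enough that 15–30% are
missed on visual reading. Morphometric post-processing helps: per-subject
feature maps are compared voxel-wise against healthy-control templates, and
suprathreshold clusters become detection candidates. `fcdmaps` implements
that stack as a self-contained R package for method developers and imaging
scientists: no external neuroimaging pipelines are wrapped, every stage is
testable, and a seeded phantom generator provides ground truth.

## The method

For a subject's T1 volume (mean-normalized within the brain mask) and a
three-class tissue segmentation (CSF/GM/WM Gaussian mixture fitted by
deterministic EM), three feature maps are computed:

* **Junction** — voxels whose intensity lies in the ambiguous band
  `[mean_GM + 0.5·SD_GM, mean_WM − 0.5·SD_WM]` form a binary image that is
  smoothed with a 3D Gaussian kernel (FWHM 6 mm). High values mark spatial
  concentrations of blurred GM–WM transitions.
* **Extension** — the smoothed GM probability map restricted to cortex, a
  VBM-style gray-matter density image.
* **Thickness** — a cortical-width surrogate in mm from a dual Euclidean
  distance transform on the segmentation labels (distance to WM plus
  distance to CSF/background at each GM voxel).

Control cohorts yield voxel-wise normative templates `(μ, σ)` (optionally
with a per-voxel linear age model), and each patient map is scored as

    z = (patient − μ) / max(σ, σ_floor),

thresholded (z > 1.96, the two-sided p = 0.05 Gaussian cutoff; z > 2 for
overlap evaluation), and decomposed into connected clusters. Ground truth
for evaluation is the post-resection cavity (PRC), recovered automatically
from a co-registered pre/post-operative pair by smoothed subtraction.
Agreement is quantified by DICE (`2|A∩B|/(|A|+|B|)`), percent overlay
(`100·|A∩B|/|PRC|`), per-cluster overlap counts, and voxel-level ROC/AUC
with TPR measured inside the reference and FPR over the brain excluding it.

## Worked example

A lesion phantom, a 20-control template, and the junction pipeline:

```r
library(fcdmaps)

base   <- phantom_spec(noise_sd = 0.02 * 130)        # 64^3, 1 mm, 2% noise
cohort <- make_cohort(20, base, jitter = 0.02, seed = 120)

junction_of <- function(p) {
  t1n <- normalize_by_mean(p$t1, p$brain_mask)
  seg <- segment_tissues(t1n, p$brain_mask)
  junction_map(t1n, seg$stats, p$brain_mask)         # FWHM 6 mm
}
tpl <- build_template(lapply(cohort, junction_of))

pat <- make_head_phantom(phantom_spec(noise_sd = 0.02 * 130, seed = 121))
les <- insert_fcd_lesion(pat, lesion_spec(pat$center + c(0, 0, 15),
                                          radius_mm = 8, "junction_blur",
                                          ramp_mm = 4))

zm  <- zmap(junction_of(les$phantom), tpl)
cl  <- threshold_clusters(zm, z_threshold = 2,
                          exclusion = binary_mask(1 - pat$brain_mask$data,
                                                  pat$t1$spacing))
tidy(cl)
#> # A tibble: 1 × 7
#>      id n_voxels volume_mm3 peak_z     x     y     z
#>   <int>    <int>      <dbl>  <dbl> <int> <int> <int>
#> 1     1     1626       1626   18.8    34    35    45

roc_curve(zm, les$lesion_mask, pat$brain_mask)
#> <roc_result> AUC 0.9984 over 200 thresholds
```

A single cluster survives z > 2 (peak z ≈ 19, 1626 mm³), and it sits at
the planted lesion (centered 15 mm above the phantom center, i.e. grid
slice z ≈ 47). The z-map ranks lesion voxels almost perfectly (AUC 0.998
against the lesion mask).

Cavity detection and its evaluation work the same way:

```r
post <- carve_resection(pat, pat$center, radius_mm = 10)
prc  <- detect_prc(pat$t1, post, pat$brain_mask)
prc
#> <prc_result> cavity 4127 mm^3 (largest of 1 candidate cluster(s),
#>              diff > 0.05, mass_preserving)
overlap_report(prc$mask, sphere_mask(pat$t1, pat$center, 10))
#> # A tibble: 1 × 5
#>   vol_a_mm3 vol_b_mm3 overlap_mm3 percent_overlay  dice
#>       <dbl>     <dbl>       <dbl>           <dbl> <dbl>
#> 1      4127      4224        4127            97.7 0.988
```

4127 mm³ recovered against an analytic (4/3)π·10³ ≈ 4189 mm³ — a 1.5%
volume error, with DICE 0.99 against the rasterized carving sphere.

`fcd_cohort_volumes()` ships the reference table of PRR (radiological
lesion), PRC, and overlap volumes for a 23-subject surgical cohort used by
the worked-example tests; `run_detection()` / `run_evaluation()`
orchestrate whole studies, and `inst/cli/fcdmaps.R` exposes the stages as
shell subcommands (`simulate`, `segment`, `features`, `build-template`,
`detect`, `detect-prc`, `evaluate`).

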