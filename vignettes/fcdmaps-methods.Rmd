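---
title: "Morphometric FCD detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric FCD detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fcdmaps)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter and why they default where they do, what
the phantom generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## The detection model

Focal cortical dysplasia type II expresses itself on T1-weighted MRI as
*increases* in three morphometric quantities: blurring of the gray–white
junction, gray-matter density extending into white matter, and cortical
thickness. The package scores each quantity per voxel against a normative
control cohort and flags one-sided deviations.

For a subject volume $Y$ (mean-normalized within the brain mask so that
segmentation statistics and voxel values share a scale):

1. **Segmentation.** In-mask intensities are modeled as a three-component
   Gaussian mixture; components are assigned to CSF, GM, and WM in
   increasing order of fitted mean, the intensity ordering of T1 images.
   The EM fit is deterministic: initialization is the best of three fixed
   Lloyd k-means starts (25/50/75 and 10/50/90 percentile seeds, plus an
   equal-spaced seed over the intensity range). A single quantile-seeded
   start can collapse two components onto one narrow intensity mode when
   class proportions are skewed, which is why the multi-start is used.
   The M-step floors each component SD at $10^{-8}$ of the overall SD —
   a constrained maximization, so the likelihood-ascent property of EM is
   preserved (and asserted at every iteration) even for noiseless,
   delta-like classes. Convergence: relative log-likelihood change below
   $10^{-8}$, at most 500 iterations. Tissue statistics (MeanGM, S.D.GM,
   MeanWM, S.D.WM) are computed over voxels with posterior probability
   above 0.5, excluding partial-volume voxels that would pull the class
   means together.

2. **Junction map.** Voxels inside the band
   $[\mathrm{MeanGM} + 0.5\,\mathrm{S.D.GM},\;
     \mathrm{MeanWM} - 0.5\,\mathrm{S.D.WM}]$
   within the brain mask are set to 1 and the binary image is smoothed
   with a 3D Gaussian kernel. Masking precedes smoothing (the order is
   configurable); masking first keeps out-of-brain voxels from
   contributing mass to the cortical rim.

3. **Extension map.** The GM probability map restricted to the cortical
   mask and smoothed: a gray-matter density image in the voxel-based
   morphometry sense. It is defined on probabilities rather than raw T1
   intensities so the map is already intensity-calibrated and bounded in
   $[0,1]$.

4. **Thickness surrogate.** For each GM voxel, the Euclidean distance to
   the nearest WM voxel plus the distance to the nearest CSF/background
   voxel, minus one mean voxel spacing. The subtraction converts two
   center-to-center distances into a distance between the two tissue
   interfaces (each interface lies half a voxel beyond the neighboring
   voxel center); a flat 6-voxel slab on a 1 mm grid then measures
   exactly 6 mm. This replaces surface-reconstruction thickness
   estimation: it preserves the quantity's meaning (local cortical width
   in mm) and feeds the same z-scoring stage, at the cost of voxel-level
   quantization (see Limitations).

5. **Normative scoring.** Control maps give voxel-wise mean $\mu$ and
   sample SD $\sigma$ ($n-1$); the patient score is
   $z = (y - \mu) / \max(\sigma, \sigma_{\mathrm{floor}})$. With control
   ages, a per-voxel ordinary-least-squares line $\beta_0 + \beta_1\,
   \mathrm{age}$ with residual SD on $n-2$ degrees of freedom supports
   age-adjusted scoring — a single-subject analogue of a
   different-offset, different-slope group design (a two-group GLM
   contrast is not meaningful at $n=1$ and is not attempted).

6. **Clusters.** Voxels with $z$ strictly above the threshold, outside an
   optional exclusion mask, are grouped into 26-connected components,
   filtered by minimum volume, and ranked by peak $z$.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Smoothing FWHM | 6 | mm | The morphometry-standard kernel for these maps; interpreted as FWHM ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2}) \approx 2.548$ mm). Whether the kernel is quoted as FWHM or SD is a convention choice, so it is a config knob, not a constant. |
| z threshold | 1.96 | – | Two-sided Gaussian $p = 0.05$ cutoff; overlap evaluation conventionally binarizes at 2. Both appear in practice; 1.96 is the default, 2 is passed explicitly where DICE-style outputs are produced. |
| One-sided testing | $z > t$ | – | All three modalities encode pathology as increases; deviations below the mean are not flagged. |
| $\sigma$ floor | 1% of median positive $\sigma$ | map units | Phantom templates contain exactly-zero-SD voxels; the floor keeps z finite. An absolute guard of $10^{-9}$ covers numerically degenerate cohorts. |
| Connectivity | 26 | – | Face/edge/corner adjacency, the permissive common choice; 6 and 18 available. |
| Minimum cluster volume | 0 | mm³ | No minimum is imposed by default. |
| Tissue probability cutoff | 0.5 | – | Excludes partial-volume voxels from MeanGM/MeanWM. |
| Cavity difference threshold | 0.05 | – | The subtraction scale is unitless after normalization; strictly positive keeps smoothed noise out of the candidate set. The methodological reference point ("positive difference") leaves the value open; 0.05 is recorded as a default, not inferred. |
| ROC sweep | 200 thresholds | – | Evenly spaced between the in-brain min and max score; 200 points keep the trapezoid AUC within $5\times10^{-3}$ of the rank-based value (checked against a Mann–Whitney oracle in the tests at $10^4$ thresholds). |

## Post-resection cavity detection

Pre- and post-operative volumes are smoothed and subtracted; positive
difference marks removed tissue. Two numerical choices deviate from the
naive formulation, both made after quantifying their effect on carved
phantom spheres:

* **Intensity calibration by the median post/pre ratio.** Dividing each
  volume by its own in-brain mean biases the difference map: a large
  cavity lowers the post-operative mean, giving every unchanged voxel a
  spurious offset (and making the subtraction detect "tissue gain"
  everywhere when the volumes are swapped). Dividing by the in-brain
  median fails similarly once the cavity makes CSF the majority class.
  The calibration used is therefore: anchor the pre volume by its mean,
  and scale the post volume by the median voxel-wise post/pre ratio over
  the brain — a statistic dominated by unchanged tissue for any cavity
  smaller than half the brain. Unchanged tissue then subtracts to noise
  around zero, and a pure intensity loss yields no detection in the
  swapped direction.
* **Mass-preserving delineation.** The suprathreshold component at a low
  threshold over-extends by the smoothing skirt (+35% to +230% volume on
  spheres of 6–12 mm radius), and the common half-maximum contour
  under-extends on convex objects by a curvature-dependent margin
  (−30% to −45% measured). Because Gaussian smoothing conserves the
  integral, the cavity volume equals the background-corrected difference
  mass divided by its peak amplitude; the returned mask is the level set
  of that volume around the peak. Measured recovery error across radii
  6–12 mm: within about ±12%. `delineation = "threshold"` restores the
  raw component for users who want the literal suprathreshold region.

Cluster retention ("the cluster corresponding to the cavity") is
operationalized as largest-component selection, with an optional
nearest-to-seed-point rule, since the underlying choice is made manually
in practice.

## The phantom generator

`make_head_phantom()` emulates the aspects of a T1 head volume that the
detection logic actually consumes: nested background / CSF shell / GM
ribbon / WM core regions on an ellipsoid (shell thicknesses in metric mm,
carved by a distance transform from the outer surface), the CSF < GM < WM
intensity ordering (defaults 30/80/130), and additive Gaussian voxel
noise (default SD 2, about 1.5% of the WM mean; end-to-end detection
tests use 2% of WM). Defaults: a 64³ grid at 1 mm, semi-axes
25×22×20 mm, 3 mm CSF shell, 4 mm ribbon — tissue fractions of roughly a
third each, and a ribbon on the generous side of true cortex so that it
spans several voxels. Lesions are spheres intersecting the ribbon:
`junction_blur` replaces the GM→WM step by a linear ramp (default width
4 mm) across the interface; `thickening` relabels the WM band within
`delta_mm` (default 3) below the interface as GM. `carve_resection()`
sets a sphere to CSF intensity, re-applying the phantom's own noise
field so the carving is the only difference. Cohorts jitter the geometry
multiplicatively (default 2% SD) and can grow the ribbon linearly with
age for age-model recovery tests.

What the phantom does **not** emulate — and what passing tests therefore
do not demonstrate about real data: gyrification and partial-volume
effects at a folded cortical surface, bias fields and other intensity
non-stationarities, Rician noise (immaterial at phantom SNR, and Gaussian
noise keeps the model analytically checkable), registration error
(phantoms are generated aligned; real data must be co-registered
upstream), and true anatomical variability beyond smooth geometric
jitter. Results on phantoms validate the *mechanics* of the pipeline —
thresholds, scoring, cluster logic, volume recovery — not clinical
sensitivity or specificity.

## Numerical choices

* **Smoothing** is separable with per-axis $\sigma$ in voxels
  ($\sigma_{mm}$/spacing), a sampled kernel truncated at $6\sigma$, and a
  renormalized (mass-preserving) boundary: constants stay exactly
  constant, no rim artifacts enter the junction maps, and interior mass
  is conserved to $10^{-6}$ relative. The impulse response matches the
  analytic separable Gaussian to $10^{-6}$ absolute.
* **Distance transforms** are the exact Euclidean
  Felzenszwalb–Huttenlocher algorithm with anisotropic spacing, in C++;
  connected components are breadth-first search at 6/18/26 connectivity.
  No installed R package provides either in 3D.
* **Ties and order.** Cluster extraction uses strict inequality
  ($z > t$), matching the ROC detection predicate; clusters are sorted by
  peak z with first-touch tie-breaking; component labels are relabeled
  1..K after sorting so downstream code can rely on label 1 being the top
  cluster.
* **Degenerate inputs.** Volumes containing NaN/Inf are rejected at read
  time with the affected voxel count, never propagated. Empty reference
  masks make percent overlay (and empty mask pairs make DICE) `NA` with a
  warning, never 0. Constant score maps yield the degenerate
  (0,0)–(1,1) ROC with AUC 0.5 and a warning. Zero-variance paired
  differences report $t = 0, p = 1$ with a warning.
* **Coordinates.** Voxel indices are R-native 1-based everywhere (peak
  coordinates, slices); world coordinates in mm follow the affine.
  Grids are never resampled silently; every cross-volume operation
  checks grid identity within a relative tolerance of $10^{-6}$.

## Design choices where the methodology was open

* The full morphometric stack normally leans on external pipelines
  (unified segmentation with atlas priors; surface reconstruction;
  nonlinear template normalization). All three are deliberately replaced
  by self-contained equivalents — mixture segmentation, the dual
  distance-transform thickness surrogate, and a common-grid assumption
  with an optional center-of-mass pre-alignment — so that the package is
  fully testable without wrapped binaries. Externally produced
  probability maps can be injected via `accept_external_probmaps()`.
* The anatomical exclusion mask (amygdala, hippocampus, orbitofrontal
  cortex, anterior commissure region in clinical use) is an *input*:
  its composition is anatomical knowledge, not algorithm. Phantom runs
  use the complement of the brain mask, which also suppresses the rim of
  floored-σ voxels just outside the brain where z-scores are
  meaningless.
* Holm–Šídák is implemented directly (step-down
  $1-(1-p_{(i)})^{m-i+1}$ with a running maximum) because `p.adjust`
  offers no step-down Šídák; the paired t-test wraps `stats::t.test`.

## Known limitations

* **Null clusters are not small.** A z-field smoothed at FWHM 6 mm has
  suprathreshold excursions of order $10^2$–$10^3$ mm³ even in
  lesion-free phantoms: at $z > 2$ roughly 2–3% of the brain exceeds
  threshold across ~10 smooth blobs, so individual null clusters
  routinely pass 100 mm³ (and held-out subjects with coherently
  deviating geometry can produce much larger ones). A minimum-cluster-
  size filter is therefore *not* a reliable specificity device at these
  smoothness levels; what separates lesions from null structure in the
  phantom experiments is peak z (tens vs. just-above-threshold), and the
  tests assert that separation rather than an absence of sizable null
  clusters.
* The thickness surrogate is quantized at the voxel scale; sub-voxel
  thickness changes are detectable only through dithering by anatomical
  variability (the age-slope recovery test works exactly this way, and
  recovers a 0.05 mm/year slope to within ±30% at n = 30, not better).
* Percent overlay and DICE against a resection cavity are bounded by the
  physiology of the comparison: cavities include tissue far beyond any
  cortical abnormality, so even a perfect cortical detector scores low.
  DICE values must be compared between methods, not read as absolute
  quality.
* Problem sizes in tests and the acceptance script (64³ grids, cohorts
  of 20–30, four cavity radii) are the package's validation scale,
  chosen so the full suite runs in minutes; the algorithms themselves
  are resolution-independent.
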