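#' Per-subject morphometric feature maps
#'
#' A `feature_map` bundles a scored [volume3d()] with its modality
#' (`"junction"`, `"extension"`, or `"thickness"`) and the parameters used to
#' produce it. Junction and extension scores are dimensionless in \[0, 1\];
#' thickness is in mm and zero outside gray matter.
#'
#' @param volume A `volume3d` with the scores.
#' @param modality One of `"junction"`, `"extension"`, `"thickness"`.
#' @param params Named list of parameters recorded for provenance.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(volume, modality, params = list()) {
  stopifnot(is_volume3d(volume))
  modality <- match.arg(modality, c("junction", "extension", "thickness"))
  structure(list(volume = volume, modality = modality, params = params),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map: %s> ", x$modality))
  print(x$volume)
  invisible(x)
}

#' Junction band thresholds from tissue statistics
#'
#' The gray-white junction band is the intensity interval
#' `[mean_gm + 0.5 * sd_gm, mean_wm - 0.5 * sd_wm]`: intensities too bright
#' for typical GM yet too dark for typical WM, the signature of a blurred
#' GM-WM transition.
#'
#' @param stats A [tissue_stats()] object.
#' @return A `junction_thresholds` object with fields `lower`, `upper`.
#' @examples
#' st <- structure(list(mean_gm = 100, sd_gm = 10, mean_wm = 150, sd_wm = 8),
#'                 class = "tissue_stats")
#' junction_thresholds(st) # lower 105, upper 146
#' @export
junction_thresholds <- function(stats) {
  stopifnot(inherits(stats, "tissue_stats"))
  lower <- stats$mean_gm + 0.5 * stats$sd_gm
  upper <- stats$mean_wm - 0.5 * stats$sd_wm
  if (lower >= upper) {
    stopf("degenerate GM-WM band: lower threshold %.6g >= upper %.6g",
          lower, upper)
  }
  structure(list(lower = lower, upper = upper), class = "junction_thresholds")
}

#' @export
print.junction_thresholds <- function(x, ...) {
  cat(sprintf("<junction_thresholds> [%.6g, %.6g]\n", x$lower, x$upper))
  invisible(x)
}

#' Junction (gray-white blurring) feature map
#'
#' Voxels inside the brain mask whose intensity lies within the junction band
#' are set to 1, producing a binary image of ambiguous GM/WM intensities;
#' smoothing with a 3D Gaussian kernel (default FWHM 6 mm) then turns
#' isolated band crossings into low scores and spatial concentrations of
#' blurring into high scores. Masking precedes smoothing. The volume passed
#' here should be on the same intensity scale as the one `stats` was
#' computed from (the pipeline uses the mean-normalized T1 for both).
#'
#' @param vol The T1 `volume3d`.
#' @param stats A [tissue_stats()] for the same intensity scale.
#' @param brain_mask `binary_mask` restricting the band image.
#' @param spec Smoothing kernel ([smoothing_spec()] or FWHM in mm).
#' @return A `feature_map` with modality `"junction"`, values in \[0, 1\].
#' @export
junction_map <- function(vol, stats, brain_mask, spec = smoothing_spec(6)) {
  stopifnot(is_volume3d(vol), is_binary_mask(brain_mask))
  assert_same_grid(vol, brain_mask)
  spec <- as_smoothing_spec(spec)
  thr <- junction_thresholds(stats)
  binary <- vol
  binary$data <- (vol$data >= thr$lower & vol$data <= thr$upper &
                    brain_mask$data > 0) * 1
  sm <- smooth_gaussian(binary, spec)
  feature_map(sm, "junction",
              params = list(lower = thr$lower, upper = thr$upper,
                            fwhm_mm = spec$fwhm_mm))
}

#' Extension (gray-matter density) feature map
#'
#' Smoothed GM probability restricted to the cortical mask: a VBM-style
#' gray-matter density image in which abnormally intense or displaced gray
#' matter (e.g. GM extending into white matter) shows up as local excess
#' density. Non-cortical structures (basal ganglia, brainstem, cerebellum)
#' are excluded by the mask, which for real data is a predefined anatomical
#' input and for phantoms is the generator's ground-truth cortical ribbon.
#'
#' @param seg A `tissue_seg`.
#' @param cortical_mask `binary_mask` of cortex (non-empty).
#' @param spec Smoothing kernel.
#' @return A `feature_map` with modality `"extension"`, values in \[0, 1\].
#' @export
extension_map <- function(seg, cortical_mask, spec = smoothing_spec(6)) {
  stopifnot(inherits(seg, "tissue_seg"), is_binary_mask(cortical_mask))
  spec <- as_smoothing_spec(spec)
  if (!identical(dim(seg$labels), dim(cortical_mask$data))) {
    stopf("segmentation and cortical mask are not on the same grid")
  }
  if (!any(cortical_mask$data > 0)) stopf("empty cortical mask")
  gm <- volume3d(seg$prob_gm * cortical_mask$data,
                 spacing = seg$spacing, affine = seg$affine,
                 space = seg$space)
  sm <- smooth_gaussian(gm, spec)
  feature_map(sm, "extension", params = list(fwhm_mm = spec$fwhm_mm))
}

#' Cortical thickness surrogate map
#'
#' Local cortical width in mm, computed on the segmentation labels by a dual
#' Euclidean distance transform: for every GM voxel, the distance to the
#' nearest WM voxel plus the distance to the nearest outer (CSF or
#' background) voxel, minus one mean voxel spacing so that the two
#' center-to-center distances measure to the tissue interfaces rather than
#' to the neighboring voxel centers. Zero outside GM. This surrogate
#' replaces surface-reconstruction thickness estimation while preserving the
#' quantity's meaning, and feeds the same normative z-scoring stage.
#'
#' @param seg A `tissue_seg` with GM, WM, and CSF/background all present.
#' @return A `feature_map` with modality `"thickness"` (mm).
#' @export
thickness_map <- function(seg) {
  stopifnot(inherits(seg, "tissue_seg"))
  lab <- seg$labels
  d <- dim(lab)
  gm <- lab == 2L
  wm <- lab == 3L
  outer <- lab == 1L | lab == 0L
  if (!any(wm)) stopf("no WM voxels: thickness undefined")
  if (!any(outer)) stopf("no CSF/background voxels: thickness undefined")
  vol <- volume3d(array(0, d), spacing = seg$spacing, affine = seg$affine,
                  space = seg$space)
  if (!any(gm)) {
    warnf("no GM voxels: thickness map is identically zero")
    return(feature_map(vol, "thickness", params = list(note = "no GM")))
  }
  d_in <- .edt3d(c(wm), dim(lab), seg$spacing)
  d_out <- .edt3d(c(outer), dim(lab), seg$spacing)
  thick <- pmax(d_in + d_out - mean(seg$spacing), 0)
  a <- array(0, d)
  a[gm] <- thick[c(gm)]
  vol$data <- a
  feature_map(vol, "thickness", params = list())
}
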