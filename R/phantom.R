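#' Specification of a synthetic T1 head phantom
#'
#' The phantom emulates the data model of a T1-weighted head scan at the
#' level the detection pipelines care about: nested background / CSF shell /
#' cortical GM ribbon / WM core regions on an ellipsoidal "brain", the
#' canonical T1 intensity ordering CSF < GM < WM, additive Gaussian voxel
#' noise, and exact ground-truth tissue masks. Geometry is ellipsoidal
#' rather than folded; gyrification is irrelevant to the thresholding and
#' z-scoring logic under test. Shells of uniform metric thickness are carved
#' by a Euclidean distance transform from the outer surface, so ribbon
#' thickness is controlled in mm regardless of grid anisotropy.
#'
#' @param shape Grid dimensions (default 64^3).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param semi_axes Outer brain ellipsoid semi-axes in mm.
#' @param csf_mm Thickness of the outer CSF shell (mm).
#' @param ribbon_mm Cortical GM ribbon thickness (mm).
#' @param intensities Named tissue mean intensities, `csf < gm < wm`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         semi_axes = c(25, 22, 20), csf_mm = 3,
                         ribbon_mm = 4,
                         intensities = c(csf = 30, gm = 80, wm = 130),
                         noise_sd = 2, seed = 1) {
  stopifnot(length(shape) == 3, length(spacing) == 3, length(semi_axes) == 3)
  if (!(intensities["csf"] < intensities["gm"] &&
        intensities["gm"] < intensities["wm"])) {
    stopf("tissue intensities must satisfy CSF < GM < WM")
  }
  if (csf_mm + ribbon_mm >= min(semi_axes)) {
    stopf("CSF shell + ribbon (%.3g mm) must be thinner than the smallest semi-axis (%.3g mm)",
          csf_mm + ribbon_mm, min(semi_axes))
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes), csf_mm = csf_mm,
                 ribbon_mm = ribbon_mm, intensities = intensities,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# world (mm) coordinates of all voxel centers, n x 3
voxel_world_coords <- function(shape, spacing) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  sweep(idx - 1, 2, spacing, `*`)
}

#' Generate a synthetic head phantom
#'
#' Rasterizes the nested tissue regions of a [phantom_spec()] and adds
#' seeded Gaussian noise. The same seed gives bit-identical output.
#'
#' @param spec A `phantom_spec`.
#' @return A `head_phantom`: `t1` (noisy `volume3d`), `t1_clean` (noiseless
#'   array), ground-truth `labels` (0 background, 1 CSF, 2 GM, 3 WM),
#'   `depth` (mm below the outer brain surface), `brain_mask`,
#'   `cortical_mask` (the GM ribbon), `center` (mm), and `spec`.
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  center <- (d - 1) / 2 * spec$spacing
  w <- voxel_world_coords(d, spec$spacing)
  rho2 <- ((w[, 1] - center[1]) / spec$semi_axes[1])^2 +
    ((w[, 2] - center[2]) / spec$semi_axes[2])^2 +
    ((w[, 3] - center[3]) / spec$semi_axes[3])^2
  inside <- rho2 <= 1

  # metric depth below the outer surface: distance to the nearest outside
  # voxel center, shifted by half a voxel to approximate the interface
  depth <- array(0, d)
  dist_out <- .edt3d(!inside, d, spec$spacing)
  depth[inside] <- pmax(dist_out[inside] - mean(spec$spacing) / 2, 0)

  lab <- array(0L, d)
  lab[inside & depth <= spec$csf_mm] <- 1L
  lab[inside & depth > spec$csf_mm &
        depth <= spec$csf_mm + spec$ribbon_mm] <- 2L
  lab[inside & depth > spec$csf_mm + spec$ribbon_mm] <- 3L

  clean <- array(0, d)
  means <- spec$intensities
  clean[lab == 1L] <- means[["csf"]]
  clean[lab == 2L] <- means[["gm"]]
  clean[lab == 3L] <- means[["wm"]]

  noise <- with_seed(spec$seed, array(stats::rnorm(prod(d), 0, max(spec$noise_sd, 0)), d))
  if (spec$noise_sd == 0) noise <- array(0, d)

  aff <- diag(c(spec$spacing, 1))
  structure(list(
    t1 = volume3d(clean + noise, spec$spacing, aff, "phantom"),
    t1_clean = clean,
    labels = lab,
    depth = depth,
    brain_mask = binary_mask(lab > 0, spec$spacing, aff, "phantom"),
    cortical_mask = binary_mask(lab == 2L, spec$spacing, aff, "phantom"),
    center = center,
    spec = spec), class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  cat(sprintf(
    "<head_phantom> %s voxels, ribbon %.3g mm, noise SD %.3g, seed %d\n",
    paste(dim(x$labels), collapse = "x"), x$spec$ribbon_mm,
    x$spec$noise_sd, x$spec$seed))
  invisible(x)
}

#' Ground-truth tissue segmentation of a phantom
#'
#' Wraps the generator's true labels as a one-hot `tissue_seg`, with
#' intensity statistics computed from the noisy T1.
#'
#' @param phantom A `head_phantom`.
#' @return A `tissue_seg`.
#' @export
phantom_segmentation <- function(phantom) {
  stopifnot(inherits(phantom, "head_phantom"))
  lab <- phantom$labels
  seg <- structure(list(labels = lab,
                        prob_csf = (lab == 1L) * 1,
                        prob_gm = (lab == 2L) * 1,
                        prob_wm = (lab == 3L) * 1,
                        mixture = NULL, loglik = NULL, converged = NA,
                        spacing = phantom$t1$spacing,
                        affine = phantom$t1$affine,
                        space = phantom$t1$space),
                   class = "tissue_seg")
  seg$stats <- tissue_stats(phantom$t1, seg)
  seg
}

#' Specification of an FCD-like lesion
#'
#' Models the two imaging signatures the detectors target: blurring of the
#' gray-white junction (the sharp GM-to-WM intensity step is replaced by a
#' linear ramp) and focal cortical thickening (the GM ribbon is locally
#' extended into WM), inside a sphere intersecting the cortical ribbon.
#'
#' @param center Lesion center in world mm.
#' @param radius_mm Sphere radius (> 0 for a non-empty lesion).
#' @param type `"junction_blur"`, `"thickening"`, or `"both"`.
#' @param ramp_mm Width of the blurred-transition ramp (mm).
#' @param delta_mm Local thickening of the ribbon (mm).
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(center, radius_mm,
                        type = c("junction_blur", "thickening", "both"),
                        ramp_mm = 4, delta_mm = 3) {
  type <- match.arg(type)
  stopifnot(length(center) == 3, radius_mm >= 0, ramp_mm > 0, delta_mm > 0)
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 type = type, ramp_mm = ramp_mm, delta_mm = delta_mm),
            class = "lesion_spec")
}

sphere_indicator <- function(shape, spacing, center, radius) {
  w <- voxel_world_coords(shape, spacing)
  r2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
    (w[, 3] - center[3])^2
  array(r2 <= radius^2, shape)
}

#' Spherical mask on a volume's grid
#'
#' @param vol A `volume3d` supplying the grid.
#' @param center_mm Sphere center in world mm.
#' @param radius_mm Sphere radius in mm.
#' @return A `binary_mask`.
#' @export
sphere_mask <- function(vol, center_mm, radius_mm) {
  stopifnot(is_volume3d(vol))
  binary_mask(sphere_indicator(dim(vol$data), vol$spacing, center_mm,
                               radius_mm),
              vol$spacing, vol$affine, vol$space)
}

#' Insert an FCD-like lesion into a phantom
#'
#' The noiseless tissue image is modified inside the lesion sphere and the
#' phantom's original noise field is re-applied, so the lesion is the only
#' difference from the unmodified phantom. `junction_blur` replaces the
#' GM-to-WM step by a linear intensity ramp of width `ramp_mm` centered on
#' the GM/WM interface; `thickening` relabels the WM band within `delta_mm`
#' below the interface as GM. The returned mask marks every modified voxel.
#'
#' @param phantom A `head_phantom`.
#' @param lesion A [lesion_spec()] whose sphere intersects the ribbon.
#' @return A list: `phantom` (modified copy) and `lesion_mask`
#'   (`binary_mask`).
#' @export
insert_fcd_lesion <- function(phantom, lesion) {
  stopifnot(inherits(phantom, "head_phantom"), inherits(lesion, "lesion_spec"))
  spec <- phantom$spec
  d <- spec$shape
  sph <- sphere_indicator(d, spec$spacing, lesion$center, lesion$radius_mm)
  if (lesion$radius_mm > 0 && !any(sph & phantom$labels == 2L)) {
    stopf("lesion sphere does not intersect the cortical ribbon")
  }
  clean <- phantom$t1_clean
  lab <- phantom$labels
  depth <- phantom$depth
  means <- spec$intensities
  d0 <- spec$csf_mm + spec$ribbon_mm # GM/WM interface depth

  if (lesion$type %in% c("junction_blur", "both")) {
    w <- lesion$ramp_mm
    band <- sph & (lab == 2L | lab == 3L) &
      depth > d0 - w / 2 & depth <= d0 + w / 2
    frac <- pmin(pmax((depth[band] - (d0 - w / 2)) / w, 0), 1)
    clean[band] <- means[["gm"]] + (means[["wm"]] - means[["gm"]]) * frac
  }
  if (lesion$type %in% c("thickening", "both")) {
    grow <- sph & lab == 3L & depth <= d0 + lesion$delta_mm
    clean[grow] <- means[["gm"]]
    lab[grow] <- 2L
  }

  changed <- abs(clean - phantom$t1_clean) > 1e-9
  noise <- phantom$t1$data - phantom$t1_clean
  out <- phantom
  out$t1_clean <- clean
  out$labels <- lab
  out$t1$data <- clean + noise
  out$cortical_mask <- binary_mask(lab == 2L, spec$spacing,
                                   phantom$t1$affine, "phantom")
  list(phantom = out,
       lesion_mask = binary_mask(changed, spec$spacing, phantom$t1$affine,
                                 "phantom"))
}

#' Carve a spherical resection cavity
#'
#' Produces the post-operative volume: voxels inside the sphere are set to
#' CSF intensity (the cavity fills with fluid), the phantom's noise field is
#' re-applied, and everything outside the sphere is untouched bit-exactly.
#'
#' @param phantom A `head_phantom` (the pre-operative state).
#' @param center Cavity center in world mm; the sphere must lie inside the
#'   brain.
#' @param radius_mm Cavity radius in mm.
#' @return The post-operative T1 `volume3d`.
#' @export
carve_resection <- function(phantom, center, radius_mm) {
  stopifnot(inherits(phantom, "head_phantom"), radius_mm >= 0)
  spec <- phantom$spec
  sph <- sphere_indicator(spec$shape, spec$spacing, center, radius_mm)
  if (any(sph & phantom$brain_mask$data == 0)) {
    stopf("resection sphere extends outside the brain")
  }
  clean <- phantom$t1_clean
  clean[sph] <- spec$intensities[["csf"]]
  noise <- phantom$t1$data - phantom$t1_clean
  post <- phantom$t1
  post$data <- clean + noise
  post
}

#' Generate a control cohort of phantoms
#'
#' Per-subject geometry (semi-axes and ribbon thickness) is jittered
#' multiplicatively to emulate anatomical variability; when ages are given
#' the ribbon thickness follows `base + slope * age` before jitter, enabling
#' recovery tests of the template age model. Each subject consumes its own
#' derived seed, so the cohort is reproducible as a whole and per member.
#'
#' @param n Cohort size (>= 2).
#' @param spec Base [phantom_spec()].
#' @param jitter Fractional SD of the multiplicative geometry jitter
#'   (default 0.02).
#' @param ages Optional ages in years (length n).
#' @param age_thickness_slope Ribbon growth per year (mm/year, default 0).
#' @param seed Cohort seed (defaults to `spec$seed`).
#' @return A list of `head_phantom`s.
#' @export
make_cohort <- function(n, spec, jitter = 0.02, ages = NULL,
                        age_thickness_slope = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 2) stopf("a cohort needs n >= 2 subjects, got %d", n)
  if (!is.null(ages) && length(ages) != n) {
    stopf("ages has length %d but n = %d", length(ages), n)
  }
  jit <- with_seed(seed, matrix(stats::rnorm(n * 4, 0, jitter), n, 4))
  lapply(seq_len(n), function(i) {
    ribbon <- spec$ribbon_mm
    if (!is.null(ages)) ribbon <- ribbon + age_thickness_slope * ages[i]
    si <- phantom_spec(shape = spec$shape, spacing = spec$spacing,
                       semi_axes = spec$semi_axes * (1 + jit[i, 1:3]),
                       csf_mm = spec$csf_mm,
                       ribbon_mm = ribbon * (1 + jit[i, 4]),
                       intensities = spec$intensities,
                       noise_sd = spec$noise_sd,
                       seed = seed + i)
    make_head_phantom(si)
  })
}
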