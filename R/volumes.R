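#' 3D scalar volumes on a regular grid
#'
#' `volume3d()` is the carrier type for every image, map, and mask in the
#' package: a 3D numeric array plus per-axis voxel spacing (mm) and a 4x4
#' voxel-to-world affine. All pipelines require their inputs to live on one
#' common grid (see [check_same_grid()]); nothing is ever resampled silently.
#'
#' @param data A 3D numeric array. `NA`/`NaN`/`Inf` values are rejected.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a scaled
#'   identity built from `spacing`.
#' @param space Free-text grid identifier.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(1, c(4, 4, 4)), spacing = c(1, 0.5, 0.5))
#' voxel_volume(v) # 0.25 mm^3
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL,
                     space = "scanner") {
  if (!is.array(data) || length(dim(data)) != 3) {
    stopf("expected 3D volume, got %s dimensions",
          if (is.array(data)) length(dim(data)) else "no")
  }
  storage.mode(data) <- "double"
  bad <- sum(!is.finite(data))
  if (bad > 0) stopf("volume contains %d non-finite voxel(s)", bad)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing must be 3 strictly positive values")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stopf("affine must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 space = space),
            class = "volume3d")
}

#' @rdname volume3d
#' @param x Object to test or convert.
#' @export
is_volume3d <- function(x) inherits(x, "volume3d")

#' @rdname volume3d
#' @param reference A `volume3d` providing grid metadata when converting a
#'   bare array.
#' @export
as_volume3d <- function(x, reference = NULL) {
  if (is_volume3d(x)) return(x)
  if (is.array(x) && !is.null(reference)) {
    return(volume3d(x, spacing = reference$spacing, affine = reference$affine,
                    space = reference$space))
  }
  stopf("cannot convert object of class '%s' to volume3d", class(x)[1])
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, voxel volume %.4g mm^3\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              voxel_volume(x)))
  cat(sprintf("  range [%.4g, %.4g], space '%s'\n",
              min(x$data), max(x$data), x$space))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param vol A `volume3d`.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Binary masks
#'
#' A `binary_mask` is a `volume3d` whose voxels are exactly 0 or 1; logical
#' input is accepted. Used for brain masks, exclusion masks, resection
#' cavities, and lesion ground truth.
#'
#' @inheritParams volume3d
#' @return An object of class `binary_mask` (also a `volume3d`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        space = "scanner") {
  if (is.logical(data)) {
    storage.mode(data) <- "double"
  }
  v <- volume3d(data, spacing = spacing, affine = affine, space = space)
  if (!all(v$data %in% c(0, 1))) stopf("mask values must be 0 or 1")
  class(v) <- c("binary_mask", "volume3d")
  v
}

#' @rdname binary_mask
#' @param x Object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @rdname binary_mask
#' @param vol A `volume3d` to binarize (values must already be 0/1 or
#'   logical).
#' @export
as_binary_mask <- function(vol) {
  if (is_binary_mask(vol)) return(vol)
  binary_mask(vol$data, vol$spacing, vol$affine, vol$space)
}

#' Physical volume of a mask
#'
#' Number of foreground voxels times the voxel volume, exactly.
#'
#' @param mask A `binary_mask`.
#' @return Volume in mm^3.
#' @examples
#' m <- binary_mask(array(c(rep(1, 100), rep(0, 412)), c(8, 8, 8)),
#'                  spacing = c(1, 0.5, 0.5))
#' mask_volume(m) # 25 mm^3
#' @export
mask_volume <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$data) * voxel_volume(mask)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads `.nii`/`.nii.gz`, checks that the image is 3D and finite, and
#' promotes integer-coded data to double. Non-finite voxels are rejected at
#' read time rather than propagated.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stopf("expected 3D volume, got %dD image in %s", length(dim(img)), path)
  }
  data <- array(as.numeric(img), dim = dim(img))
  bad <- sum(!is.finite(data))
  if (bad > 0) stopf("%s contains %d non-finite voxel(s); refusing to read",
                     path, bad)
  volume3d(data, spacing = RNifti::pixdim(img)[1:3],
           affine = unclass(RNifti::xform(img))[1:4, 1:4],
           space = basename(path))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$data %in% c(0, 1))) {
    stopf("%s is not binary (values other than 0/1 present)", path)
  }
  as_binary_mask(v)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as unsigned 8-bit integers, other volumes as
#' double-precision floats by default (`datatype = "float"` gives compact
#' 32-bit maps).
#'
#' @param vol A `volume3d` or `binary_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type for non-mask volumes.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("double", "float")) {
  stopifnot(is_volume3d(vol))
  datatype <- if (is_binary_mask(vol)) "uint8" else match.arg(datatype)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

grid_signature <- function(vol) {
  list(dim = dim(vol$data), spacing = vol$spacing, affine = vol$affine)
}

#' Check that volumes share one grid
#'
#' All pipelines assume co-registered inputs on a common grid; this predicate
#' verifies equal array shapes and spacing/affine agreement within a relative
#' tolerance. Registration itself is out of scope: real data must be
#' co-registered upstream, phantoms are generated aligned.
#'
#' @param volumes A list of `volume3d` objects (masks included).
#' @param tol Relative tolerance for spacing/affine comparison.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(volumes, tol = 1e-6) {
  if (!is.list(volumes) || length(volumes) == 0) {
    stopf("check_same_grid needs a non-empty list of volumes")
  }
  ref <- grid_signature(volumes[[1]])
  sc <- max(abs(ref$affine)) + max(ref$spacing)
  for (v in volumes[-1]) {
    g <- grid_signature(v)
    if (!identical(unname(ref$dim), unname(g$dim))) return(FALSE)
    if (max(abs(g$spacing - ref$spacing)) > tol * sc) return(FALSE)
    if (max(abs(g$affine - ref$affine)) > tol * sc) return(FALSE)
  }
  TRUE
}

assert_same_grid <- function(..., what = "volumes") {
  vols <- list(...)
  if (!check_same_grid(vols)) stopf("%s are not on the same grid", what)
  invisible(TRUE)
}

#' Normalize a volume by its mean intensity within a mask
#'
#' Divides the whole volume by a single constant, the mean intensity inside
#' `mask`, so that the in-mask mean of the result is exactly 1. Computing the
#' constant inside the brain mask (rather than the full field of view) keeps
#' air voxels from diluting it.
#'
#' @param vol A `volume3d`.
#' @param mask A non-empty `binary_mask` on the same grid.
#' @return The rescaled `volume3d`.
#' @export
normalize_by_mean <- function(vol, mask) {
  stopifnot(is_volume3d(vol), is_binary_mask(mask))
  assert_same_grid(vol, mask)
  inside <- mask$data > 0
  if (!any(inside)) stopf("empty mask: nothing to normalize over")
  m <- mean(vol$data[inside])
  if (abs(m) < .Machine$double.eps) stopf("zero mean intensity inside mask")
  out <- vol
  out$data <- vol$data / m
  out
}

#' Gaussian smoothing kernel specification
#'
#' The kernel size is given as full width at half maximum (FWHM) in mm, the
#' convention of the morphometry literature; the corresponding standard
#' deviation is `fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm_mm Kernel FWHM in mm (default 6, the package-wide smoothing
#'   used by the junction, extension, and cavity pipelines).
#' @return An object of class `smoothing_spec` with fields `fwhm_mm`,
#'   `sigma_mm`.
#' @examples
#' smoothing_spec(6)$sigma_mm # 2.5479...
#' @export
smoothing_spec <- function(fwhm_mm = 6) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0) {
    stopf("fwhm_mm must be a single positive number")
  }
  structure(list(fwhm_mm = fwhm_mm,
                 sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "smoothing_spec")
}

as_smoothing_spec <- function(spec) {
  if (inherits(spec, "smoothing_spec")) return(spec)
  if (is.numeric(spec) && length(spec) == 1) return(smoothing_spec(spec))
  stopf("spec must be a smoothing_spec or a single FWHM in mm")
}

# sampled, truncated (6 sigma), unit-sum 1D Gaussian kernel in voxel units;
# the wide truncation keeps interior mass conservation below 1e-6 relative
gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(6 * sigma_vox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# row-normalized dense convolution operator along one axis of length n;
# truncation at the volume edge is renormalized so constants are preserved
conv_operator_1d <- function(n, sigma_vox) {
  k <- gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- seq_len(n) + o
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- k[o + r + 1L]
  }
  K / rowSums(K)
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves the volume with an anisotropy-aware separable Gaussian kernel
#' (per-axis sigma in voxels = sigma_mm / spacing). Boundaries use a
#' renormalized (mass-preserving) truncated kernel, so constant volumes stay
#' exactly constant and no rim artifacts are introduced into junction maps.
#'
#' @param vol A `volume3d`.
#' @param spec A [smoothing_spec()] or a single FWHM in mm.
#' @return The smoothed `volume3d`.
#' @export
smooth_gaussian <- function(vol, spec = smoothing_spec(6)) {
  stopifnot(is_volume3d(vol))
  spec <- as_smoothing_spec(spec)
  d <- dim(vol$data)
  x <- vol$data
  sig <- spec$sigma_mm / vol$spacing

  # axis 1
  K <- conv_operator_1d(d[1], sig[1])
  x <- array(K %*% matrix(x, d[1]), d)
  # axis 2
  K <- conv_operator_1d(d[2], sig[2])
  x <- aperm(array(K %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  K <- conv_operator_1d(d[3], sig[3])
  x <- array(matrix(x, d[1] * d[2]) %*% t(K), d)

  out <- vol
  out$data <- x
  out
}

#' Center-of-mass pre-alignment
#'
#' Optional convenience for roughly centering two volumes before grid
#' checks: translates `vol` by the integer voxel shift that moves its
#' intensity center of mass onto that of `reference`. This is not a
#' registration; rigid/nonlinear alignment must happen upstream.
#'
#' @param vol,reference `volume3d` objects on equally-shaped grids.
#' @return `vol` translated by an integer voxel shift (edges zero-filled).
#' @export
align_center_of_mass <- function(vol, reference) {
  stopifnot(is_volume3d(vol), is_volume3d(reference))
  if (!identical(dim(vol$data), dim(reference$data))) {
    stopf("shapes differ; cannot align")
  }
  com <- function(a) {
    w <- as.numeric(pmax(a, 0))
    s <- sum(w)
    if (s == 0) return(c(0, 0, 0))
    idx <- arrayInd(seq_along(a), dim(a))
    colSums(idx * w) / s
  }
  shift <- round(com(reference$data) - com(vol$data))
  d <- dim(vol$data)
  out <- array(0, d)
  src <- lapply(1:3, function(i) {
    s <- seq_len(d[i]) - shift[i]
    s
  })
  ok <- lapply(1:3, function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    vol$data[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  res <- vol
  res$data <- out
  res
}
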