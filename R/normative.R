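#' Build a voxel-wise normative template from a control cohort
#'
#' Averages the processed feature maps of a control cohort into voxel-wise
#' mean (`mu`) and sample standard deviation (`sigma`, n-1 denominator)
#' maps. If control ages are supplied, a per-voxel linear age model
#' (offset + slope * age, ordinary least squares) is fitted alongside, with
#' residual SD on n-2 degrees of freedom; this supports single-subject
#' age-adjusted scoring in the spirit of a different-offset/different-slope
#' design.
#'
#' @param maps List (n >= 2) of [feature_map()]s of one modality on one grid.
#' @param ages Optional numeric ages in years, one per map.
#' @return A `normative_template` with fields `mu`, `sigma` (both
#'   `volume3d`), `n`, `modality`, and optionally `age_model`.
#' @export
build_template <- function(maps, ages = NULL) {
  if (!is.list(maps) || length(maps) < 2) {
    stopf("need at least 2 maps to build a template, got %d", length(maps))
  }
  stopifnot(all(vapply(maps, inherits, logical(1), "feature_map")))
  modality <- maps[[1]]$modality
  if (!all(vapply(maps, function(m) m$modality, character(1)) == modality)) {
    stopf("mixed modalities in template cohort")
  }
  vols <- lapply(maps, function(m) m$volume)
  if (!check_same_grid(vols)) stopf("cohort maps are not on the same grid")
  n <- length(maps)
  if (!is.null(ages) && length(ages) != n) {
    stopf("ages has length %d but cohort has %d maps", length(ages), n)
  }

  d <- dim(vols[[1]]$data)
  Y <- vapply(vols, function(v) c(v$data), numeric(prod(d)))
  mu <- rowMeans(Y)
  sigma <- sqrt(rowSums((Y - mu)^2) / (n - 1))

  ref <- vols[[1]]
  as_vol <- function(x) volume3d(array(x, d), spacing = ref$spacing,
                                 affine = ref$affine, space = ref$space)
  tpl <- structure(list(mu = as_vol(mu), sigma = as_vol(sigma), n = n,
                        modality = modality, age_model = NULL),
                   class = "normative_template")

  if (!is.null(ages)) {
    a <- as.numeric(ages)
    abar <- mean(a)
    sxx <- sum((a - abar)^2)
    if (sxx <= 0) stopf("ages must not all be equal for an age model")
    slope <- c((Y %*% (a - abar)) / sxx)
    offset <- mu - slope * abar
    fitted_ss <- slope^2 * sxx
    total_ss <- rowSums((Y - mu)^2)
    resid_sd <- sqrt(pmax(total_ss - fitted_ss, 0) / (n - 2))
    tpl$age_model <- list(offset = array(offset, d),
                          slope = array(slope, d),
                          resid_sd = array(resid_sd, d),
                          ages = a)
  }
  tpl
}

#' @export
print.normative_template <- function(x, ...) {
  cat(sprintf("<normative_template: %s> n = %d%s\n", x$modality, x$n,
              if (is.null(x$age_model)) "" else
                sprintf(", age model over %.3g-%.3g y",
                        min(x$age_model$ages), max(x$age_model$ages))))
  print(x$mu)
  invisible(x)
}

# default SD floor: 1% of the robust (median positive) sigma, so that
# exactly-zero-SD voxels (common in phantom templates) cannot blow up z
default_sigma_floor <- function(sigma_data) {
  pos <- sigma_data[sigma_data > 0]
  if (length(pos) == 0) return(1e-6)
  # absolute guard keeps degenerate (numerically-zero-SD) cohorts usable
  max(0.01 * stats::median(pos), 1e-9)
}

#' Voxel-wise z-score map against a normative template
#'
#' `z = (patient - mu) / max(sigma, sigma_floor)`, voxel-wise. The SD floor
#' guarantees a finite map everywhere.
#'
#' @param patient A `feature_map` matching the template's modality and grid.
#' @param template A [build_template()] result.
#' @param sigma_floor SD floor; default 1% of the median positive sigma.
#' @return A `zscore_map` with fields `z` (`volume3d`), `modality`,
#'   `sigma_floor`.
#' @export
zmap <- function(patient, template, sigma_floor = NULL) {
  stopifnot(inherits(patient, "feature_map"),
            inherits(template, "normative_template"))
  if (patient$modality != template$modality) {
    stopf("modality mismatch: patient '%s' vs template '%s'",
          patient$modality, template$modality)
  }
  assert_same_grid(patient$volume, template$mu,
                   what = "patient map and template")
  floor_used <- sigma_floor %||% default_sigma_floor(template$sigma$data)
  z <- patient$volume
  z$data <- (patient$volume$data - template$mu$data) /
    pmax(template$sigma$data, floor_used)
  structure(list(z = z, modality = patient$modality,
                 sigma_floor = floor_used, n = template$n,
                 age_adjusted = FALSE),
            class = "zscore_map")
}

#' Age-adjusted z-score map
#'
#' Scores a patient against the per-voxel age regression of the template
#' cohort: `z = (patient - (offset + slope * age)) / max(resid_sd, floor)`.
#' A patient age more than 2 years outside the control age range triggers an
#' extrapolation warning.
#'
#' @param patient A `feature_map`.
#' @param age Patient age in years.
#' @param template A template built with `ages`.
#' @param sigma_floor Residual-SD floor; default 1% of the median positive
#'   residual SD.
#' @return A `zscore_map`.
#' @export
age_adjusted_zmap <- function(patient, age, template, sigma_floor = NULL) {
  stopifnot(inherits(patient, "feature_map"),
            inherits(template, "normative_template"))
  if (is.null(template$age_model)) {
    stopf("template has no age model; rebuild with ages")
  }
  if (patient$modality != template$modality) {
    stopf("modality mismatch: patient '%s' vs template '%s'",
          patient$modality, template$modality)
  }
  assert_same_grid(patient$volume, template$mu,
                   what = "patient map and template")
  am <- template$age_model
  if (age < min(am$ages) - 2 || age > max(am$ages) + 2) {
    warnf("patient age %.3g y is outside the control range %.3g-%.3g y (+/-2): extrapolating",
          age, min(am$ages), max(am$ages))
  }
  floor_used <- sigma_floor %||% default_sigma_floor(am$resid_sd)
  pred <- am$offset + am$slope * age
  z <- patient$volume
  z$data <- (patient$volume$data - pred) / pmax(am$resid_sd, floor_used)
  structure(list(z = z, modality = patient$modality,
                 sigma_floor = floor_used, n = template$n,
                 age_adjusted = TRUE, age = age),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("<zscore_map: %s>%s sigma_floor %.4g\n", x$modality,
              if (isTRUE(x$age_adjusted)) " (age-adjusted)" else "",
              x$sigma_floor))
  print(x$z)
  invisible(x)
}

#' Template subtraction map
#'
#' The simple patient-minus-template-mean difference map, the thresholdable
#' companion of the z-map.
#'
#' @inheritParams zmap
#' @return A `feature_map` of the same modality holding `patient - mu`.
#' @export
subtraction_map <- function(patient, template) {
  stopifnot(inherits(patient, "feature_map"),
            inherits(template, "normative_template"))
  assert_same_grid(patient$volume, template$mu,
                   what = "patient map and template")
  out <- patient$volume
  out$data <- patient$volume$data - template$mu$data
  feature_map(out, patient$modality,
              params = c(patient$params, list(subtracted = TRUE)))
}

#' Threshold a z-map into candidate clusters
#'
#' Voxels with `z > z_threshold` (strictly greater, one-sided: all three
#' modalities encode pathology as increases) and outside the optional
#' exclusion mask are grouped into connected components. Components smaller
#' than `min_cluster_mm3` are dropped; survivors are sorted by peak z
#' descending and relabeled 1..K.
#'
#' @param zm A `zscore_map`, or any `volume3d` score map.
#' @param z_threshold Score cutoff (default 1.96, the two-sided p = 0.05
#'   Gaussian cutoff; overlap evaluation conventionally uses 2).
#' @param connectivity 6, 18, or 26 (default 26).
#' @param min_cluster_mm3 Minimum cluster volume retained (default 0).
#' @param exclusion Optional `binary_mask` of regions to ignore.
#' @return A `cluster_set`: integer `label_map`, a tibble `clusters` with
#'   columns `id`, `n_voxels`, `volume_mm3`, `peak_z`, `x`, `y`, `z`
#'   (1-based voxel indices of the peak), plus the parameters used.
#' @export
threshold_clusters <- function(zm, z_threshold = 1.96, connectivity = 26,
                               min_cluster_mm3 = 0, exclusion = NULL) {
  score <- if (inherits(zm, "zscore_map")) zm$z else zm
  stopifnot(is_volume3d(score))
  if (!is.finite(z_threshold)) stopf("z_threshold must be finite")
  if (!connectivity %in% c(6, 18, 26)) {
    stopf("connectivity must be 6, 18, or 26")
  }
  keep <- score$data > z_threshold
  if (!is.null(exclusion)) {
    stopifnot(is_binary_mask(exclusion))
    assert_same_grid(score, exclusion, what = "z-map and exclusion mask")
    keep <- keep & exclusion$data == 0
  }
  d <- dim(score$data)
  vv <- voxel_volume(score)
  lab <- array(.label3d(c(keep), d, as.integer(connectivity)), d)
  k <- max(lab)

  rows <- NULL
  out_lab <- array(0L, d)
  if (k > 0) {
    counts <- tabulate(lab[lab > 0], k)
    keep_ids <- which(counts > 0 & counts * vv >= min_cluster_mm3)
    if (length(keep_ids) > 0) {
      peaks <- vapply(keep_ids, function(id) {
        idx <- which(lab == id)
        best <- idx[which.max(score$data[idx])]
        c(score$data[best], best)
      }, numeric(2))
      ord <- order(peaks[1, ], decreasing = TRUE)
      keep_ids <- keep_ids[ord]
      peaks <- peaks[, ord, drop = FALSE]
      coord <- arrayInd(as.integer(peaks[2, ]), d)
      rows <- tibble::tibble(id = seq_along(keep_ids),
                             n_voxels = counts[keep_ids],
                             volume_mm3 = counts[keep_ids] * vv,
                             peak_z = peaks[1, ],
                             x = coord[, 1], y = coord[, 2], z = coord[, 3])
      relabel <- integer(k)
      relabel[keep_ids] <- seq_along(keep_ids)
      sel <- lab > 0
      out_lab[sel] <- relabel[lab[sel]]
    }
  }
  if (is.null(rows)) {
    rows <- tibble::tibble(id = integer(), n_voxels = integer(),
                           volume_mm3 = numeric(), peak_z = numeric(),
                           x = integer(), y = integer(), z = integer())
  }
  structure(list(label_map = out_lab, clusters = rows,
                 threshold = z_threshold, connectivity = connectivity,
                 min_cluster_mm3 = min_cluster_mm3,
                 spacing = score$spacing, affine = score$affine),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at z > %.4g, %d-connectivity\n",
              nrow(x$clusters), x$threshold, x$connectivity))
  print(x$clusters)
  invisible(x)
}

#' Save / load a normative template
#'
#' A template is persisted as a pair of NIfTI volumes (`<prefix>_mu.nii.gz`,
#' `<prefix>_sigma.nii.gz`), age-model volumes when present, and a JSON
#' manifest with modality, cohort size, and ages.
#'
#' @param template A `normative_template`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default the modality).
#' @return `save_template()` the manifest path; `load_template()` the
#'   template.
#' @export
save_template <- function(template, dir, prefix = template$modality) {
  stopifnot(inherits(template, "normative_template"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(part) file.path(dir, sprintf("%s_%s.nii.gz", prefix, part))
  write_volume(template$mu, p("mu"))
  write_volume(template$sigma, p("sigma"))
  manifest <- list(modality = template$modality, n = template$n,
                   prefix = prefix, has_age_model = !is.null(template$age_model))
  if (!is.null(template$age_model)) {
    am <- template$age_model
    ref <- template$mu
    write_volume(as_volume3d(am$offset, ref), p("age_offset"))
    write_volume(as_volume3d(am$slope, ref), p("age_slope"))
    write_volume(as_volume3d(am$resid_sd, ref), p("age_resid_sd"))
    manifest$ages <- am$ages
  }
  mp <- file.path(dir, sprintf("%s_template.json", prefix))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname save_template
#' @param manifest_path Path to the `*_template.json` manifest.
#' @export
load_template <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stopf("template manifest not found: %s", manifest_path)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  p <- function(part) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", man$prefix, part))
    if (!file.exists(f)) stopf("missing template volume: %s", f)
    f
  }
  tpl <- structure(list(mu = read_volume(p("mu")),
                        sigma = read_volume(p("sigma")),
                        n = man$n, modality = man$modality,
                        age_model = NULL),
                   class = "normative_template")
  if (isTRUE(man$has_age_model)) {
    tpl$age_model <- list(offset = read_volume(p("age_offset"))$data,
                          slope = read_volume(p("age_slope"))$data,
                          resid_sd = read_volume(p("age_resid_sd"))$data,
                          ages = man$ages)
  }
  tpl
}
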