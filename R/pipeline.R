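#' Detection run configuration
#'
#' Bundles every tunable of the detection pipelines with its recorded
#' default. The effective configuration travels with each run report, so
#' any output can be reproduced from its manifest.
#'
#' @param modality `"junction"`, `"extension"`, or `"thickness"`.
#' @param z_threshold Cluster cutoff (default 1.96; overlap evaluation
#'   conventionally uses 2).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 6).
#' @param connectivity Cluster connectivity (default 26).
#' @param sigma_floor Template SD floor; `NULL` = 1% of the median positive
#'   sigma.
#' @param min_cluster_mm3 Minimum cluster volume retained (default 0).
#' @param diff_threshold Cavity difference cutoff (default 0.05).
#' @param prob_threshold Tissue probability cutoff for statistics.
#' @param n_thresholds ROC sweep resolution (default 200).
#' @param exclusion Optional path to an exclusion mask NIfTI.
#' @param seed Seed for any stochastic stage.
#' @param output_dir Optional directory for per-subject outputs.
#' @return An `fcd_config` (a named list).
#' @export
fcd_config <- function(modality = "junction", z_threshold = 1.96,
                       fwhm_mm = 6, connectivity = 26, sigma_floor = NULL,
                       min_cluster_mm3 = 0, diff_threshold = 0.05,
                       prob_threshold = 0.5, n_thresholds = 200,
                       exclusion = NULL, seed = 1, output_dir = NULL) {
  structure(list(modality = modality, z_threshold = z_threshold,
                 fwhm_mm = fwhm_mm, connectivity = connectivity,
                 sigma_floor = sigma_floor,
                 min_cluster_mm3 = min_cluster_mm3,
                 diff_threshold = diff_threshold,
                 prob_threshold = prob_threshold,
                 n_thresholds = n_thresholds, exclusion = exclusion,
                 seed = seed, output_dir = output_dir),
            class = "fcd_config")
}

#' Read / write a run configuration as YAML
#'
#' Keys missing from the file keep their [fcd_config()] defaults; unknown
#' keys are an error.
#'
#' @param path YAML key/value file.
#' @return An `fcd_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  base <- fcd_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(unclass(base), vals)
  class(out) <- "fcd_config"
  out
}

#' @rdname read_config
#' @param config An `fcd_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fcd_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

#' Run one subject through a detection pipeline
#'
#' Orchestrates segmentation, feature-map computation, normative z-scoring,
#' and cluster extraction for one modality. The T1 is mean-normalized
#' within the brain mask first, so the junction band thresholds and the
#' voxel values share one intensity scale. Identical inputs and
#' configuration give identical outputs.
#'
#' @param t1 Subject T1 `volume3d`.
#' @param brain_mask `binary_mask`.
#' @param template A [build_template()] result whose modality matches
#'   `config$modality`.
#' @param config An [fcd_config()].
#' @param cortical_mask Cortical `binary_mask` (required for the extension
#'   modality; also used as the junction band domain when given).
#' @param exclusion Optional exclusion `binary_mask` applied at cluster
#'   extraction.
#' @param age Optional patient age in years; with an age-model template
#'   this selects age-adjusted scoring.
#' @param seg Optional precomputed `tissue_seg` (e.g. external probability
#'   maps); segmented internally when `NULL`.
#' @param subject Subject identifier used in reports and file names.
#' @return An `fcd_detection`: `feature`, `zmap`, `clusters`, `seg`, and a
#'   one-row `report` tibble.
#' @export
run_detection <- function(t1, brain_mask, template, config = fcd_config(),
                          cortical_mask = NULL, exclusion = NULL, age = NULL,
                          seg = NULL, subject = "subject") {
  stopifnot(inherits(config, "fcd_config"))
  modality <- match.arg(config$modality,
                        c("junction", "extension", "thickness"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("[%s] stage '%s' failed: %s", subject, name, conditionMessage(e))
    })
  }
  t1n <- stage("normalize", normalize_by_mean(t1, brain_mask))
  if (is.null(seg)) {
    seg <- stage("segment", segment_tissues(t1n, brain_mask))
  }
  spec <- smoothing_spec(config$fwhm_mm)
  feature <- stage(modality, switch(
    modality,
    junction = junction_map(t1n, seg$stats, brain_mask, spec),
    extension = {
      if (is.null(cortical_mask)) stopf("extension modality needs a cortical_mask")
      extension_map(seg, cortical_mask, spec)
    },
    thickness = thickness_map(seg)))
  zm <- stage("zmap", {
    if (!is.null(age) && !is.null(template$age_model)) {
      age_adjusted_zmap(feature, age, template,
                        sigma_floor = config$sigma_floor)
    } else {
      zmap(feature, template, sigma_floor = config$sigma_floor)
    }
  })
  clusters <- stage("clusters", threshold_clusters(
    zm, z_threshold = config$z_threshold,
    connectivity = config$connectivity,
    min_cluster_mm3 = config$min_cluster_mm3, exclusion = exclusion))

  report <- tibble::tibble(subject = subject, modality = modality,
                           z_threshold = config$z_threshold,
                           fwhm_mm = config$fwhm_mm,
                           n_clusters = nrow(clusters$clusters),
                           max_peak_z = if (nrow(clusters$clusters) > 0)
                             max(clusters$clusters$peak_z) else NA_real_)
  res <- structure(list(subject = subject, modality = modality, seg = seg,
                        feature = feature, zmap = zm, clusters = clusters,
                        config = config, report = report),
                   class = "fcd_detection")
  if (!is.null(config$output_dir)) {
    write_detection(res, config$output_dir)
  }
  res
}

#' @export
print.fcd_detection <- function(x, ...) {
  cat(sprintf("<fcd_detection> %s / %s: %d cluster(s) at z > %.3g\n",
              x$subject, x$modality, nrow(x$clusters$clusters),
              x$clusters$threshold))
  invisible(x)
}

write_cluster_tsv <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters$clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_detection <- function(res, dir) {
  sub_dir <- file.path(dir, res$subject)
  dir.create(sub_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(part, ext) {
    file.path(sub_dir, sprintf("%s_%s.%s", res$subject, part, ext))
  }
  write_volume(res$feature$volume, p(res$modality, "nii.gz"),
               datatype = "float")
  write_volume(res$zmap$z, p(paste0(res$modality, "_z"), "nii.gz"),
               datatype = "float")
  write_cluster_tsv(res$clusters, p(paste0(res$modality, "_clusters"), "tsv"))
  jsonlite::write_json(
    list(report = res$report,
         params = res$feature$params,
         config = Filter(Negate(is.null), unclass(res$config))),
    p(res$modality, "json"), auto_unbox = TRUE, digits = NA)
  invisible(sub_dir)
}

#' Evaluate detections against reference masks
#'
#' For every subject and every available reference mask (post-resection
#' cavity and/or radiological ROI), computes the overlap report of the
#' binarized cluster map, the per-cluster overlap counts, and the voxel
#' ROC/AUC of the z-map. Subjects with a missing reference are reported
#' with a warning and skipped for that reference; the run continues.
#'
#' @param detections List of [run_detection()] results.
#' @param references Named list per subject; each element is a list with
#'   any of `prc`, `prr` (`binary_mask`s on the subject grid).
#' @param brain_masks List of `binary_mask`s, one per subject (same order
#'   as `detections`).
#' @param n_thresholds ROC sweep resolution.
#' @return A tibble, one row per subject x reference, with overlap, DICE,
#'   cluster counts, and AUC. Summarize with [summarize_study()].
#' @export
run_evaluation <- function(detections, references, brain_masks,
                           n_thresholds = 200) {
  stopifnot(is.list(detections), is.list(references),
            length(detections) == length(brain_masks))
  rows <- list()
  for (i in seq_along(detections)) {
    det <- detections[[i]]
    stopifnot(inherits(det, "fcd_detection"))
    refs <- references[[det$subject]] %||% references[[i]]
    if (is.null(refs) || length(refs) == 0) {
      warnf("no reference mask for subject '%s'; skipped", det$subject)
      next
    }
    detected <- binary_mask(det$clusters$label_map > 0,
                            det$zmap$z$spacing, det$zmap$z$affine)
    for (ref_name in names(refs)) {
      ref <- refs[[ref_name]]
      if (is.null(ref)) {
        warnf("subject '%s' has no '%s' reference; skipped",
              det$subject, ref_name)
        next
      }
      ov <- overlap_report(detected, ref)
      ct <- cluster_overlap_table(det$clusters, ref)
      roc <- roc_curve(det$zmap, ref, brain_masks[[i]],
                       n_thresholds = n_thresholds)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = det$subject, modality = det$modality,
        reference = ref_name, ov, ct, auc = roc$auc)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(subject = character(), modality = character(),
                          reference = character()))
  }
  do.call(rbind, rows)
}

#' Cohort summary of an evaluation table
#'
#' Median and interquartile range of DICE plus mean AUC, grouped by
#' modality and reference - the shape of a study summary table.
#'
#' @param eval_table A [run_evaluation()] result.
#' @return A tibble with one row per modality x reference.
#' @export
summarize_study <- function(eval_table) {
  stopifnot(is.data.frame(eval_table), nrow(eval_table) > 0)
  key <- interaction(eval_table$modality, eval_table$reference, drop = TRUE)
  out <- lapply(levels(key), function(lv) {
    sub <- eval_table[key == lv, ]
    tibble::tibble(modality = sub$modality[1], reference = sub$reference[1],
                   n = nrow(sub),
                   median_dice = stats::median(sub$dice, na.rm = TRUE),
                   iqr_dice = stats::IQR(sub$dice, na.rm = TRUE),
                   mean_auc = mean(sub$auc, na.rm = TRUE))
  })
  do.call(rbind, out)
}
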