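#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster set
#'
#' @param x A [threshold_clusters()] result.
#' @param ... Unused.
#' @return The per-cluster tibble (`id`, `n_voxels`, `volume_mm3`,
#'   `peak_z`, `x`, `y`, `z`).
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @rdname tidy.cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 total_volume_mm3 = sum(x$clusters$volume_mm3),
                 max_peak_z = if (nrow(x$clusters) > 0)
                   max(x$clusters$peak_z) else NA_real_,
                 threshold = x$threshold,
                 connectivity = x$connectivity)
}

#' Tidy an ROC result
#'
#' @param x A [roc_curve()] result.
#' @param ... Unused.
#' @return `tidy()`: the threshold/TPR/FPR points; `glance()`: one row with
#'   the AUC.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = x$n_thresholds)
}

#' Tidy a tissue segmentation
#'
#' @param x A [segment_tissues()] result.
#' @param ... Unused.
#' @return `tidy()`: the fitted mixture components (empty tibble for
#'   externally supplied probability maps); `glance()`: convergence
#'   information and tissue counts.
#' @export
tidy.tissue_seg <- function(x, ...) {
  x$mixture %||% tibble::tibble(tissue = character(), mean = numeric(),
                                sd = numeric(), weight = numeric())
}

#' @rdname tidy.tissue_seg
#' @export
glance.tissue_seg <- function(x, ...) {
  tibble::tibble(
    n_csf = sum(x$labels == 1L), n_gm = sum(x$labels == 2L),
    n_wm = sum(x$labels == 3L),
    converged = x$converged,
    n_iterations = length(x$loglik %||% numeric(0)),
    loglik = if (length(x$loglik %||% numeric(0)) > 0)
      x$loglik[length(x$loglik)] else NA_real_)
}

#' Tidy a normative template
#'
#' @param x A [build_template()] result.
#' @param ... Unused.
#' @return One row with modality, cohort size, and sigma summaries.
#' @export
glance.normative_template <- function(x, ...) {
  tibble::tibble(modality = x$modality, n = x$n,
                 median_sigma = stats::median(x$sigma$data),
                 has_age_model = !is.null(x$age_model))
}
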