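#' Overlap metrics between a detection and a reference mask
#'
#' Computes, on one grid, the detected volume, reference volume, their
#' intersection, the percent overlay (share of the reference covered by the
#' detection, the convention used when the reference is a resection cavity),
#' and the DICE coefficient `2|A&B| / (|A| + |B|)`. An empty reference makes
#' percent overlay (and an all-empty pair makes DICE) undefined: these are
#' reported as `NA` with a warning, never as zero.
#'
#' @param detected,reference `binary_mask`s on one grid.
#' @return A one-row tibble with columns `vol_a_mm3` (detected),
#'   `vol_b_mm3` (reference), `overlap_mm3`, `percent_overlay`, `dice`.
#' @examples
#' m <- make_overlap_masks(1593, 3096, 1056)
#' overlap_report(m$detected, m$reference) # percent_overlay 34.1%
#' @export
overlap_report <- function(detected, reference) {
  stopifnot(is_binary_mask(detected), is_binary_mask(reference))
  assert_same_grid(detected, reference, what = "detection and reference")
  vv <- voxel_volume(detected)
  na <- sum(detected$data)
  nb <- sum(reference$data)
  nab <- sum(detected$data * reference$data)
  pct <- if (nb > 0) 100 * nab / nb else {
    warnf("empty reference mask: percent overlay undefined")
    NA_real_
  }
  dice <- if (na + nb > 0) 2 * nab / (na + nb) else {
    warnf("both masks empty: DICE undefined")
    NA_real_
  }
  tibble::tibble(vol_a_mm3 = na * vv, vol_b_mm3 = nb * vv,
                 overlap_mm3 = nab * vv, percent_overlay = pct, dice = dice)
}

#' Synthetic mask pair with prescribed volumes
#'
#' Builds, on a unit-spaced grid, a detection/reference mask pair with the
#' requested voxel counts and intersection - useful for reproducing overlap
#' metrics from published volume tables and for testing.
#'
#' @param n_detected,n_reference,n_overlap Voxel counts
#'   (`n_overlap <= min(n_detected, n_reference)`).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @return A list with `detected` and `reference` `binary_mask`s.
#' @export
make_overlap_masks <- function(n_detected, n_reference, n_overlap,
                               spacing = c(1, 1, 1)) {
  if (n_overlap > min(n_detected, n_reference)) {
    stopf("overlap (%d) exceeds one of the mask sizes", n_overlap)
  }
  total <- n_detected + n_reference - n_overlap
  nx <- 64
  ny <- 64
  nz <- max(1L, as.integer(ceiling(total / (nx * ny))) + 1L)
  d <- c(nx, ny, nz)
  ref <- array(0, d)
  det <- array(0, d)
  ref[seq_len(n_reference)] <- 1
  det[seq(n_reference - n_overlap + 1, length.out = n_detected)] <- 1
  list(detected = binary_mask(det, spacing),
       reference = binary_mask(ref, spacing))
}

#' Per-cluster overlap bookkeeping
#'
#' Counts how many detected clusters touch the reference mask (one shared
#' voxel suffices) and what share of the reference all clusters jointly
#' cover.
#'
#' @param clusters A [threshold_clusters()] result.
#' @param reference A non-empty `binary_mask` on the cluster grid.
#' @return A one-row tibble: `n_overlapping`, `n_total`,
#'   `percent_reference_covered`.
#' @export
cluster_overlap_table <- function(clusters, reference) {
  stopifnot(inherits(clusters, "cluster_set"), is_binary_mask(reference))
  if (!identical(dim(clusters$label_map), dim(reference$data))) {
    stopf("clusters and reference are not on the same grid")
  }
  nb <- sum(reference$data)
  if (nb == 0) stopf("empty reference mask")
  k <- nrow(clusters$clusters)
  if (k == 0) {
    return(tibble::tibble(n_overlapping = 0L, n_total = 0L,
                          percent_reference_covered = 0))
  }
  in_ref <- clusters$label_map[reference$data > 0]
  overlapping <- length(unique(in_ref[in_ref > 0]))
  covered <- sum(in_ref > 0)
  tibble::tibble(n_overlapping = as.integer(overlapping),
                 n_total = as.integer(k),
                 percent_reference_covered = 100 * covered / nb)
}

#' Voxel-level ROC curve of a score map against a reference mask
#'
#' Sweeps `n_thresholds` evenly spaced cutoffs between the minimum and
#' maximum in-brain score. At each cutoff `t` the detection is
#' `score > t` (strictly greater, matching the cluster threshold
#' convention); the true positive rate is the detected share of the
#' reference mask, and the false positive rate is the detected share of the
#' brain excluding the reference. The curve is closed with (0,0) and (1,1)
#' and summarized by the trapezoidal area under the curve.
#'
#' @param score A `volume3d` (or `zscore_map`/`feature_map`) score image.
#' @param reference Non-empty `binary_mask` contained in the brain mask.
#' @param brain_mask `binary_mask` defining the evaluation domain.
#' @param n_thresholds Number of cutoffs in the sweep (default 200).
#' @return A `roc_result`: tibble `points` (`threshold`, `tpr`, `fpr`) and
#'   scalar `auc`.
#' @export
roc_curve <- function(score, reference, brain_mask, n_thresholds = 200) {
  if (inherits(score, "zscore_map")) score <- score$z
  if (inherits(score, "feature_map")) score <- score$volume
  stopifnot(is_volume3d(score), is_binary_mask(reference),
            is_binary_mask(brain_mask))
  assert_same_grid(score, reference, brain_mask,
                   what = "score, reference, and brain mask")
  inside <- brain_mask$data > 0
  ref <- reference$data[inside] > 0
  if (any(reference$data > 0 & !inside)) {
    stopf("reference mask extends outside the brain mask")
  }
  n_pos <- sum(ref)
  n_neg <- sum(!ref)
  if (n_pos == 0) stopf("empty reference mask")
  if (n_neg == 0) stopf("brain mask minus reference is empty")

  s <- score$data[inside]
  lo <- min(s)
  hi <- max(s)
  if (hi <= lo) {
    warnf("constant score map: degenerate ROC with AUC 0.5")
    pts <- tibble::tibble(threshold = c(Inf, lo),
                          tpr = c(0, 1), fpr = c(0, 1))
    return(structure(list(points = pts, auc = 0.5,
                          n_thresholds = n_thresholds),
                     class = "roc_result"))
  }
  thr <- seq(lo, hi, length.out = n_thresholds)
  # counts of scores > t via sorted vectors
  pos_sorted <- sort(s[ref])
  neg_sorted <- sort(s[!ref])
  tpr <- (n_pos - findInterval(thr, pos_sorted)) / n_pos
  fpr <- (n_neg - findInterval(thr, neg_sorted)) / n_neg

  pts <- tibble::tibble(threshold = c(Inf, rev(thr), -Inf),
                        tpr = c(0, rev(tpr), 1),
                        fpr = c(0, rev(fpr), 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_thresholds = n_thresholds),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d thresholds\n", x$auc,
              x$n_thresholds))
  invisible(x)
}

#' Cohort volume summary
#'
#' Arithmetic mean, minimum, and maximum of a set of volumes; the mean is
#' conventionally reported to the nearest mm^3.
#'
#' @param volumes Non-empty numeric vector of volumes (mm^3).
#' @return A one-row tibble: `n`, `mean_mm3`, `min_mm3`, `max_mm3`.
#' @export
summarize_volumes <- function(volumes) {
  volumes <- as.numeric(volumes)
  if (length(volumes) == 0 || any(!is.finite(volumes))) {
    stopf("volumes must be a non-empty finite numeric vector")
  }
  tibble::tibble(n = length(volumes), mean_mm3 = mean(volumes),
                 min_mm3 = min(volumes), max_mm3 = max(volumes))
}

#' Paired t comparison of two metric vectors
#'
#' Classical paired two-sided t-test via [stats::t.test()]. Zero-variance
#' differences (e.g. identical metric lists) are reported with the
#' convention t = 0, p = 1 and a warning rather than an error.
#'
#' @param metric_a,metric_b Equal-length numeric vectors (n >= 2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `mean_difference`.
#' @export
paired_compare <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) {
    stopf("paired comparison needs equal lengths (%d vs %d)",
          length(metric_a), length(metric_b))
  }
  if (length(metric_a) < 2) stopf("need at least 2 pairs")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    warnf("zero-variance differences: reporting t = 0, p = 1")
    return(tibble::tibble(statistic = 0, df = length(d) - 1, p_value = 1,
                          mean_difference = mean(d)))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak adjustment: order the m p-values ascending, set
#' `adj_i = 1 - (1 - p_(i))^(m - i + 1)`, enforce monotonicity by a running
#' maximum, cap at 1, and return in the original order. More powerful than
#' Bonferroni-Holm for moderately correlated tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.04)) # 0.0199, 0.04
#' @export
holm_sidak <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
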