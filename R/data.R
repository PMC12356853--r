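#' Reference cohort volumes
#'
#' Volumes (mm^3, at 1 mm^3 voxels) for a surgical pediatric FCD type II
#' cohort of 23 subjects: the manually outlined radiological lesion (PRR,
#' available for 17 subjects), the automatically detected post-resection
#' cavity (PRC, all subjects), their overlap, and the percent overlay
#' (`100 * overlap / PRC`, one decimal). These are the worked-example
#' inputs for the overlap metrics: reconstructing mask pairs with these
#' voxel counts via [make_overlap_masks()] reproduces the tabulated percent
#' overlays exactly.
#'
#' One subject's cavity entry is internally inconsistent as individually
#' reported; its PRC volume is reconstructed from the cohort mean and its
#' overlap fields are left `NA` (see the `note` column).
#'
#' @return A tibble with columns `subject`, `prr_mm3`, `prc_mm3`,
#'   `overlap_mm3`, `percent_overlay`, `note`.
#' @examples
#' cv <- fcd_cohort_volumes()
#' round(mean(cv$prr_mm3, na.rm = TRUE)) # 1781
#' @export
fcd_cohort_volumes <- function() {
  path <- system.file("extdata", "fcd_cohort_volumes.csv",
                      package = "fcdmaps", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
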