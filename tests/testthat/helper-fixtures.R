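# Shared fixtures; everything is generated in code, seeded.

# compact phantom for fast unit tests (full 64^3 geometry is exercised in
# the acceptance suite)
small_spec <- function(seed = 1, ...) {
  args <- list(shape = c(40, 40, 40), semi_axes = c(15, 13, 12),
               csf_mm = 2.5, ribbon_mm = 4, noise_sd = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# one-hot tissue_seg from a bare label array (0 bg, 1 CSF, 2 GM, 3 WM)
seg_from_labels <- function(labels, spacing = c(1, 1, 1)) {
  structure(list(labels = labels,
                 prob_csf = (labels == 1L) * 1,
                 prob_gm = (labels == 2L) * 1,
                 prob_wm = (labels == 3L) * 1,
                 mixture = NULL, loglik = NULL, converged = NA,
                 spacing = spacing, affine = diag(c(spacing, 1)),
                 space = "test"),
            class = "tissue_seg")
}

# junction feature map of a phantom through the standard pipeline steps
phantom_junction_map <- function(ph, fwhm = 6) {
  t1n <- normalize_by_mean(ph$t1, ph$brain_mask)
  seg <- segment_tissues(t1n, ph$brain_mask)
  junction_map(t1n, seg$stats, ph$brain_mask, smoothing_spec(fwhm))
}

phantom_thickness_map <- function(ph) {
  thickness_map(segment_tissues(ph$t1, ph$brain_mask))
}

# independent rank-based (Mann-Whitney) AUC
rank_auc <- function(scores, positives) {
  r <- rank(scores)
  n1 <- sum(positives)
  n0 <- sum(!positives)
  (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

tmp_nii <- function(ext = ".nii.gz") tempfile(fileext = ext)

# complement of a phantom's brain mask, for in-brain cluster extraction
outside_brain <- function(ph) {
  binary_mask(1 - ph$brain_mask$data, ph$t1$spacing, ph$t1$affine)
}
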