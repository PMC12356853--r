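#' @importFrom Rcpp sourceCpp
#' @useDynLib fcdmaps, .registration = TRUE
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Gaussian z cutoff for a two-sided significance level
#'
#' The voxel-wise detection threshold used throughout the package follows the
#' usual normal-theory convention: a two-sided level `alpha` corresponds to
#' the `1 - alpha/2` standard-normal quantile, e.g. 1.96 for `alpha = 0.05`.
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @return The positive z cutoff.
#' @examples
#' z_cutoff(0.05) # 1.959964
#' @export
z_cutoff <- function(alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stopf("alpha must be a single value in (0, 1)")
  }
  stats::qnorm(1 - alpha / 2)
}
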