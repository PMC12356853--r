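#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(color = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

slice_df <- function(vol, slice, axis) {
  d <- dim(vol$data)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  m <- switch(axis,
              vol$data[slice, , ],
              vol$data[, slice, ],
              vol$data[, , slice])
  expand <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  expand$value <- c(m)
  expand
}

#' Plot one slice of a volume
#'
#' @param vol A `volume3d` (or `feature_map`/`zscore_map`).
#' @param slice Slice index (default: middle slice).
#' @param axis Axis perpendicular to the slice (1, 2, or 3; default 3).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(vol, slice = NULL, axis = 3) {
  if (inherits(vol, "feature_map")) vol <- vol$volume
  if (inherits(vol, "zscore_map")) vol <- vol$z
  stopifnot(is_volume3d(vol), axis %in% 1:3)
  df <- slice_df(vol, slice, axis)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_slice
#' @param object A `zscore_map`.
#' @param ... Passed to [plot_slice()].
#' @export
autoplot.zscore_map <- function(object, ...) plot_slice(object, ...)

#' @rdname plot_slice
#' @export
autoplot.feature_map <- function(object, ...) plot_slice(object, ...)

#' @importFrom ggplot2 .data
NULL
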