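#' Plot a split-data RSM as a heat map
#'
#' @param object A `split_rsm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.split_rsm <- function(object, ...) {
  df <- tidy.split_rsm(object)
  df$condition_a <- factor(df$condition_a, levels = object$conditions)
  df$condition_b <- factor(df$condition_b, levels = object$conditions)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition_b, .data$condition_a,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_discrete(limits = rev(object$conditions)) +
    ggplot2::labs(x = "half B condition", y = "half A condition",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a searchlight stat map
#'
#' @param object A `stat_map`.
#' @param slice Axial (third-axis) voxel slice, 1-based; default the middle
#'   mapped slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stat_map <- function(object, slice = NULL, ...) {
  vol <- as_volume(object)
  ij <- voxel_ijk(object$voxels, object$grid_shape)
  if (is.null(slice)) slice <- round(median(ij[, 3])) + 1L
  df <- expand.grid(i = seq_len(dim(vol)[1]), j = seq_len(dim(vol)[2]))
  df$value <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = sprintf("%s map, slice k = %d", object$stat_name,
                                  slice),
                  x = "voxel i", y = "voxel j", fill = object$stat_name) +
    ggplot2::theme_minimal()
}

#' Plot peak-coordinate distributions in three axis-pair projections
#'
#' @param peaks A `peak_set` tibble.
#' @return A ggplot (faceted by projection plane).
#' @export
plot_peaks <- function(peaks) {
  proj <- dplyr::bind_rows(
    tibble::tibble(plane = "R-A", x = peaks$R, y = peaks$A,
                   label = peaks$label),
    tibble::tibble(plane = "R-S", x = peaks$R, y = peaks$S,
                   label = peaks$label),
    tibble::tibble(plane = "A-S", x = peaks$A, y = peaks$S,
                   label = peaks$label)
  )
  ggplot2::ggplot(proj, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::labs(x = "mm", y = "mm", colour = "representation") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `loocv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loocv_result <- function(object, ...) {
  df <- tidy.loocv_result(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$expected,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}
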