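# ggplot2 visualizations for result objects.

raster_df <- function(px) {
  h <- dim(px)[1]; w <- dim(px)[2]
  data.frame(
    x = rep(0:(w - 1L), each = h),
    y = rep(0:(h - 1L), times = w),
    fill = grDevices::rgb(px[, , 1], px[, , 2], px[, , 3], maxColorValue = 255)
  )
}

gg_image <- function(px) {
  df <- raster_df(px)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = I(.data$fill))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}

#' @rdname generate_scene
#' @param object a `synthetic_scene`.
#' @param ... unused.
#' @export
autoplot.synthetic_scene <- function(object, ...) {
  p <- gg_image(as_rgb_array(object$rgb))
  tr <- object$truth$fruit_centroids
  if (nrow(tr) > 0) {
    p <- p + ggplot2::geom_point(
      data = as.data.frame(tr),
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
      shape = 3, color = "yellow", size = 3, stroke = 1.2
    )
  }
  p + ggplot2::ggtitle(sprintf("synthetic scene (seed %d)", object$spec$seed))
}

#' @rdname segment_fruits
#' @param object a `fruit_segmentation`.
#' @export
autoplot.fruit_segmentation <- function(object, ...) {
  mask <- object$stages$mask_filtered
  if (is.null(mask)) {
    stop_goji("autoplot needs a result with keep_intermediates = TRUE",
              "gojivision_invalid_argument")
  }
  px <- array(0, c(dim(mask), 3))
  for (k in 1:3) px[, , k] <- mask * 255
  p <- gg_image(px)
  det <- object$detections
  if (nrow(det) > 0) {
    p <- p + ggplot2::geom_point(
      data = as.data.frame(det),
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
      shape = 3, color = "red", size = 3, stroke = 1.2
    )
  }
  p + ggplot2::ggtitle(sprintf("%d fruit(s), threshold %d (%s)",
                               nrow(det), object$threshold$threshold,
                               object$threshold$method))
}

#' @rdname segment_branch
#' @param object a `branch_segmentation`.
#' @export
autoplot.branch_segmentation <- function(object, ...) {
  mask <- object$region$mask
  px <- array(0, c(dim(mask), 3))
  for (k in 1:3) px[, , k] <- mask * 255
  gp <- object$grip_point
  gg_image(px) +
    ggplot2::geom_point(
      data = data.frame(x = gp$x, y = gp$y),
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 3, color = "cyan", size = 4, stroke = 1.5
    ) +
    ggplot2::ggtitle(sprintf("branch region, grip point (%d, %d)", gp$x, gp$y))
}

#' Plot a grayscale histogram with its threshold
#'
#' @param hist a [compute_histogram()] result.
#' @param threshold optional `threshold_result` to mark.
#' @return A ggplot object.
#' @export
plot_histogram <- function(hist, threshold = NULL) {
  stopifnot(inherits(hist, "gray_histogram"))
  df <- data.frame(bin = 0:255, count = hist$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "gray level", y = "pixel count")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold$threshold,
                                 color = "red", linetype = 2) +
      ggplot2::ggtitle(sprintf("threshold %d (%s)", threshold$threshold,
                               threshold$method))
  }
  p
}
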