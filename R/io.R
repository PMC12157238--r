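# Readers, writers, debug artifact dumping.

#' Read an 8-bit RGB PNG
#'
#' Returns an [rgb_image()] with values on the 0-255 scale. An alpha
#' channel, if present, is dropped with a warning; grayscale PNGs are
#' expanded to three identical channels.
#'
#' @param path PNG file path.
#' @return An `rgb_image`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) {
    stop_goji(sprintf("file not found: %s", path), "gojivision_io_error")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] == 4L) {
    warning("alpha channel present; dropping it", call. = FALSE)
    px <- px[, , 1:3, drop = FALSE]
  }
  if (dim(px)[3] == 2L) {  # gray + alpha
    warning("alpha channel present; dropping it", call. = FALSE)
    px <- array(rep(px[, , 1], 3), c(dim(px)[1:2], 3L))
  }
  rgb_image(px * 255)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img an [rgb_image()] or `H x W x 3` array (0-255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  px <- as_rgb_array(img)
  png::writePNG(clamp(px, 0, 255) / 255, path)
  invisible(path)
}

#' Write a single-channel image as 8-bit grayscale PNG
#'
#' Feature channels are rescaled onto \[0, 255\] via their recorded
#' `display_range`; plain matrices are min-max rescaled.
#'
#' @param channel a `feature_channel`, logical mask, or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(channel, path) {
  v <- if (is.logical(channel)) channel * 255 else
    rescale_to_u8(as_channel_matrix(channel))
  png::writePNG(v / 255, path)
  invisible(path)
}

#' Read a depth map
#'
#' `.png` files are read as 16-bit grayscale PNG (values returned on the
#' raw 0-65535 scale); any other extension is parsed as a
#' whitespace-delimited numeric matrix. Depth units are millimeters by
#' convention (`depth_scale = 0.001`).
#'
#' @param path depth file path.
#' @param rgb optional [rgb_image()] to validate dimensions against.
#' @return `H x W` numeric matrix.
#' @export
read_depth <- function(path, rgb = NULL) {
  if (!file.exists(path)) {
    stop_goji(sprintf("file not found: %s", path), "gojivision_io_error")
  }
  d <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      stop_goji("depth PNG must be single-channel grayscale",
                "gojivision_io_error")
    }
    round(px * 65535)
  } else {
    as.matrix(utils::read.table(path))
  }
  d <- unname(as.matrix(d))
  if (!is.null(rgb)) {
    px <- as_rgb_array(rgb)
    if (!identical(dim(d), dim(px)[1:2])) {
      stop_goji(sprintf(
        "depth map is %d x %d but RGB image is %d x %d",
        nrow(d), ncol(d), dim(px)[1], dim(px)[2]),
        "gojivision_dimension_error")
    }
  }
  d
}

#' Write a depth map as a plain-text matrix
#'
#' @param depth `H x W` numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path) {
  assert_matrix(depth, "depth")
  utils::write.table(depth, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write segmentation results as JSON
#'
#' Serializes a `fruit_segmentation` or `branch_segmentation` (detections /
#' grip point plus the run report) with a schema version; the document
#' round-trips through [jsonlite::read_json].
#'
#' @param result a `fruit_segmentation` or `branch_segmentation`.
#' @param path output JSON path.
#' @param debug_dir optional directory; when given, every intermediate
#'   stage image is written there as PNG together with an annotated
#'   overlay.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, debug_dir = NULL) {
  doc <- if (inherits(result, "fruit_segmentation")) {
    list(schema = "gojivision/fruit-detections/v1",
         detections = result$detections,
         threshold = result$threshold$threshold,
         threshold_method = result$threshold$method,
         report = result$report)
  } else if (inherits(result, "branch_segmentation")) {
    gp <- result$grip_point
    list(schema = "gojivision/branch-grip/v1",
         grip = list(x = gp$x, y = gp$y, on_centroid = gp$on_centroid,
                     depth = gp$depth,
                     point3d = if (!is.null(gp$point3d))
                       as.list(gp$point3d[1, c("X", "Y", "Z")]) else NULL),
         region = list(area = result$region$area,
                       bbox_height = result$region$bbox_height),
         report = result$report)
  } else {
    stop_goji("unsupported result type", "gojivision_invalid_argument")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(debug_dir)) write_debug_stages(result, debug_dir)
  invisible(path)
}

write_debug_stages <- function(result, debug_dir) {
  dir.create(debug_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$stages)) {
    s <- result$stages[[nm]]
    write_gray(s, file.path(debug_dir, paste0(nm, ".png")))
  }
  invisible(debug_dir)
}

#' Annotate an RGB image with detections or a grip point
#'
#' Draws crosshair markers (fruit centroids in yellow, the grip point in
#' cyan) onto a copy of the input image; the overlay has the same
#' dimensions as the input.
#'
#' @param rgb an [rgb_image()] or array.
#' @param result a `fruit_segmentation` or `branch_segmentation`.
#' @param marker_size half-length of the crosshair arms, pixels.
#' @return An `rgb_image`.
#' @export
overlay_result <- function(rgb, result, marker_size = 6L) {
  px <- as_rgb_array(rgb)
  draw_cross <- function(px, x, y, col) {
    h <- dim(px)[1]; w <- dim(px)[2]
    xi <- as.integer(round(x)); yi <- as.integer(round(y))
    xs <- clamp((xi - marker_size):(xi + marker_size), 0L, w - 1L)
    ys <- clamp((yi - marker_size):(yi + marker_size), 0L, h - 1L)
    for (k in 1:3) {
      px[yi + 1L, xs + 1L, k] <- col[k]
      px[ys + 1L, xi + 1L, k] <- col[k]
    }
    px
  }
  if (inherits(result, "fruit_segmentation")) {
    det <- result$detections
    for (i in seq_len(nrow(det))) {
      px <- draw_cross(px, det$centroid_x[i], det$centroid_y[i],
                       c(255, 230, 0))
    }
  } else if (inherits(result, "branch_segmentation")) {
    px <- draw_cross(px, result$grip_point$x, result$grip_point$y,
                     c(0, 230, 255))
  }
  rgb_image(px)
}
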