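# Fruit segmentation: fused feature image -> valley threshold -> opening ->
# area filter -> centroids -> optional 3D back-projection.

#' First-moment centroids of mask components
#'
#' One detection per 8-connected component; the centroid is the mean of the
#' member pixel coordinates (the binary image's first moment), in the
#' 0-based x = column / y = row convention.
#'
#' @param mask logical matrix.
#' @return A tibble with columns `centroid_x`, `centroid_y`, `area`,
#'   `xmin`, `xmax`, `ymin`, `ymax` (one row per component; empty mask gives
#'   zero rows).
#' @export
fruit_centroids <- function(mask) {
  st <- component_stats(mask)
  st[, c("centroid_x", "centroid_y", "area",
         "xmin", "xmax", "ymin", "ymax")]
}

#' Back-project pixels to 3D camera coordinates
#'
#' Pinhole model: `Z = depth * depth_scale`, `X = (x - cx) Z / fx`,
#' `Y = (y - cy) Z / fy`. Zero, negative or non-finite depth yields an
#' invalid point (`valid = FALSE`, NA coordinates), not an error.
#'
#' @param x,y pixel coordinates (0-based, vectorized).
#' @param depth_value depth reading(s) in depth units.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return A tibble with columns `X`, `Y`, `Z` (meters) and `valid`.
#' @export
pixel_to_3d <- function(x, y, depth_value, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  valid <- is.finite(depth_value) & depth_value > 0
  Z <- ifelse(valid, depth_value * intrinsics$depth_scale, NA_real_)
  tibble::tibble(
    X = (x - intrinsics$cx) * Z / intrinsics$fx,
    Y = (y - intrinsics$cy) * Z / intrinsics$fy,
    Z = Z,
    valid = valid
  )
}

# depth at each centroid's nearest integer pixel (no RGB-depth registration)
depth_at <- function(depth, x, y) {
  xi <- pmin(pmax(as.integer(round(x)), 0L), ncol(depth) - 1L)
  yi <- pmin(pmax(as.integer(round(y)), 0L), nrow(depth) - 1L)
  depth[cbind(yi + 1L, xi + 1L)]
}

#' Segment wolfberry fruits in an RGB image
#'
#' Full fruit pipeline: extract the a* (Lab) and I (YIQ) feature channels,
#' rescale both to \[0, 255\], fuse them through a 3-level wavelet transform
#' (max-absolute detail rule, weighted-average approximation), threshold at
#' the histogram valley, clean with morphological opening and a 100-pixel
#' area filter, and report per-fruit first-moment centroids. With a depth
#' map and intrinsics, centroids are back-projected to 3D.
#'
#' `channel` selects which feature image is thresholded: the fused image
#' (default) or a single channel, for comparison experiments.
#'
#' @param rgb an [rgb_image()] or `H x W x 3` array (values 0-255).
#' @param depth optional depth matrix of the same `H x W` (depth units).
#' @param intrinsics optional [camera_intrinsics()].
#' @param config a [pipeline_config()].
#' @param channel `"fused"` (default), `"a_channel"` or `"i_channel"`.
#' @param keep_intermediates keep every stage image in the result (default
#'   `TRUE`; disable for large batch runs).
#' @return A `fruit_segmentation` object: list with `detections` (tibble,
#'   one row per fruit, including 3D columns when depth was supplied),
#'   `threshold` (a `threshold_result`), `stages` (named list of
#'   intermediate images), `config`, and `report`.
#' @export
segment_fruits <- function(rgb, depth = NULL, intrinsics = NULL,
                           config = pipeline_config(),
                           channel = c("fused", "a_channel", "i_channel"),
                           keep_intermediates = TRUE) {
  channel <- match.arg(channel)
  stopifnot(inherits(config, "pipeline_config"))
  px <- as_rgb_array(rgb)
  if (!is.null(depth)) {
    assert_matrix(depth, "depth")
    if (!identical(dim(depth), dim(px)[1:2])) {
      stop_goji("depth map dimensions do not match the RGB image",
                "gojivision_dimension_error")
    }
  }
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  a8 <- rescale_channel(extract_feature_channel(px, "a_channel"))
  i8 <- rescale_channel(extract_feature_channel(px, "i_channel"))
  tick("feature_extraction")

  gray <- switch(channel,
    fused = {
      f <- fuse_feature_images(a8, i8,
                               fusion_weights(config$alpha, config$beta),
                               levels = config$levels,
                               wavelet = config$wavelet)
      # reconstruction can overshoot [0, 255] slightly at sharp edges
      feature_channel(clamp(f$values, 0, 255), source = "fused")
    },
    a_channel = a8,
    i_channel = i8
  )
  tick("fusion")

  hist <- compute_histogram(gray)
  thr <- valley_threshold(hist, smooth_width = config$hist_smooth)
  raw_mask <- binarize(gray, thr, polarity = config$fruit_polarity)
  tick("threshold")

  opened <- morphological_open(raw_mask, config$fruit_kernel)
  filtered <- area_filter(opened, config$min_area)
  tick("morphology")

  detections <- fruit_centroids(filtered)
  if (!is.null(depth) && nrow(detections) > 0) {
    d <- depth_at(depth, detections$centroid_x, detections$centroid_y)
    detections$depth <- d
    if (!is.null(intrinsics)) {
      p3 <- pixel_to_3d(detections$centroid_x, detections$centroid_y, d,
                        intrinsics)
      detections$X <- p3$X; detections$Y <- p3$Y; detections$Z <- p3$Z
      detections$valid_3d <- p3$valid
    }
  }
  tick("centroids")

  if (keep_intermediates) {
    stages <- list(a_channel = a8, i_channel = i8, gray = gray,
                   mask_raw = raw_mask, mask_opened = opened,
                   mask_filtered = filtered)
  }
  structure(
    list(
      detections = detections,
      threshold = thr,
      stages = stages,
      config = config,
      report = run_report(
        stage_timings = timings,
        flags = list(threshold_method = thr$method, channel = channel),
        input_digest = content_fingerprint(px),
        seed = config$seed
      )
    ),
    class = "fruit_segmentation"
  )
}

run_report <- function(stage_timings, flags, input_digest, seed) {
  list(stage_timings = as.list(stage_timings), flags = flags,
       input_digest = input_digest, seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.fruit_segmentation <- function(x, ...) {
  cat(sprintf(
    "<fruit_segmentation> %d fruit(s), threshold %d (%s), channel %s\n",
    nrow(x$detections), x$threshold$threshold, x$threshold$method,
    x$report$flags$channel))
  if (nrow(x$detections) > 0) print(x$detections)
  invisible(x)
}

#' @rdname segment_fruits
#' @param x a `fruit_segmentation` object.
#' @param ... unused.
#' @export
tidy.fruit_segmentation <- function(x, ...) x$detections

#' @rdname segment_fruits
#' @export
glance.fruit_segmentation <- function(x, ...) {
  tibble::tibble(
    n_detections = nrow(x$detections),
    total_area = sum(x$detections$area),
    threshold = x$threshold$threshold,
    threshold_method = x$threshold$method,
    channel = x$report$flags$channel
  )
}
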