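# Color-space conversions used for feature extraction.
#
# The fruit pipeline relies on two chroma features that are largely
# insensitive to illumination: the a* axis of Lab (green <-> red) computed
# through chromaticity-normalized XYZ, and the I axis of YIQ (orange <->
# cyan) computed directly from the raw 8-bit RGB values.

# RGB -> XYZ matrix applied to chromaticity-normalized (r, g, b).
.XYZ_MATRIX <- matrix(c(
  0.433953, 0.376219, 0.289828,
  0.212671, 0.715160, 0.072169,
  0.017758, 0.109477, 0.872765
), nrow = 3, byrow = TRUE)

# YIQ coefficients applied to raw 0-255 R, G, B.
.YIQ_MATRIX <- matrix(c(
  0.2990,  0.5870,  0.1140,
  0.5957, -0.2745, -0.3213,
  0.2115, -0.5226,  0.3111
), nrow = 3, byrow = TRUE)

#' Construct an RGB image object
#'
#' Wraps an `H x W x 3` numeric array (channel order R, G, B, values in
#' \[0, 255\]) and validates its invariants. All pipeline entry points accept
#' either an `rgb_image` or a plain array of the same shape.
#'
#' @param pixels numeric array of dimension `H x W x 3` with values in
#'   \[0, 255\].
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_goji("`pixels` must be an H x W x 3 array", "gojivision_invalid_argument")
  }
  if (min(pixels) < 0 || max(pixels) > 255 || anyNA(pixels)) {
    stop_goji("RGB values must lie in [0, 255]", "gojivision_invalid_argument")
  }
  structure(pixels, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, value range [%g, %g]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

# extract one channel as a matrix even for 1 x 1 images
rgb_plane <- function(px, k) matrix(px[, , k], dim(px)[1], dim(px)[2])

as_rgb_array <- function(img) {
  if (inherits(img, "rgb_image")) return(unclass(img))
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) return(img)
  stop_goji("expected an rgb_image or H x W x 3 array", "gojivision_invalid_argument")
}

#' Chromaticity normalization of an RGB image
#'
#' Divides each channel by the per-pixel channel sum, removing overall
#' intensity: `r = R/(R+G+B)` and likewise for g, b. Black pixels
#' (`R+G+B = 0`) map to `(0, 0, 0)` by convention (the continuous limit),
#' so no NaN is produced.
#'
#' @param img an [rgb_image()] or `H x W x 3` array.
#' @return `H x W x 3` array of chromaticities in \[0, 1\].
#' @examples
#' normalize_rgb(array(c(128, 128, 128), dim = c(1, 1, 3)))
#' @export
normalize_rgb <- function(img) {
  px <- as_rgb_array(img)
  s <- rgb_plane(px, 1) + rgb_plane(px, 2) + rgb_plane(px, 3)
  s0 <- s
  s0[s0 == 0] <- 1  # black-pixel convention: 0/1 = 0
  out <- px
  for (k in 1:3) out[, , k] <- rgb_plane(px, k) / s0
  out
}

#' Convert RGB to the XYZ color space
#'
#' Applies the fixed 3x3 linear map to the chromaticity-normalized
#' `(r, g, b)` triple of every pixel (see [normalize_rgb()]).
#'
#' @inheritParams normalize_rgb
#' @return A list with `H x W` numeric matrices `X`, `Y`, `Z`.
#' @export
rgb_to_xyz <- function(img) {
  chr <- normalize_rgb(img)
  M <- .XYZ_MATRIX
  r <- rgb_plane(chr, 1); g <- rgb_plane(chr, 2); b <- rgb_plane(chr, 3)
  list(
    X = M[1, 1] * r + M[1, 2] * g + M[1, 3] * b,
    Y = M[2, 1] * r + M[2, 2] * g + M[2, 3] * b,
    Z = M[3, 1] * r + M[3, 2] * g + M[3, 3] * b
  )
}

# Piecewise cube-root used by the Lab transform.
lab_f <- function(t) {
  out <- 7.787 * t + 16 / 116
  big <- t > 0.008856
  out[big] <- t[big]^(1 / 3)
  out
}

#' Convert XYZ to the Lab color space
#'
#' `L* = 116 f(Y) - 16`, `a* = 500 (f(X) - f(Y))`, `b* = 200 (f(Y) - f(Z))`
#' with `f(t) = t^(1/3)` for `t > 0.008856` and `7.787 t + 16/116`
#' otherwise. `f` is applied to X, Y, Z directly — there is deliberately no
#' reference-white division (see the methods vignette); the chromaticity
#' normalization upstream already bounds X, Y, Z near \[0, 1.1\]. For the
#' standard CIE variant see [xyz_to_lab_cie()].
#'
#' @param xyz list with matrices `X`, `Y`, `Z` as from [rgb_to_xyz()].
#' @return A list with `H x W` matrices `L`, `a`, `b_star`.
#' @export
xyz_to_lab <- function(xyz) {
  fX <- lab_f(xyz$X); fY <- lab_f(xyz$Y); fZ <- lab_f(xyz$Z)
  list(L = 116 * fY - 16, a = 500 * (fX - fY), b_star = 200 * (fY - fZ))
}

#' Standard CIE Lab (D65 white point) from XYZ
#'
#' Alternate conversion that divides X, Y, Z by the D65 reference white
#' before applying `f`, provided for comparison experiments only; the
#' pipelines use [xyz_to_lab()].
#'
#' @inheritParams xyz_to_lab
#' @param white reference white `(Xn, Yn, Zn)`; default D65 normalized to
#'   `Yn = 1`.
#' @return A list with matrices `L`, `a`, `b_star`.
#' @export
xyz_to_lab_cie <- function(xyz, white = c(0.95047, 1, 1.08883)) {
  fX <- lab_f(xyz$X / white[1])
  fY <- lab_f(xyz$Y / white[2])
  fZ <- lab_f(xyz$Z / white[3])
  list(L = 116 * fY - 16, a = 500 * (fX - fY), b_star = 200 * (fY - fZ))
}

#' Convert RGB to the YIQ color space
#'
#' Linear transform of the raw 8-bit R, G, B values (no normalization):
#' `Y = 0.2990 R + 0.5870 G + 0.1140 B`, `I = 0.5957 R - 0.2745 G -
#' 0.3213 B`, `Q = 0.2115 R - 0.5226 G + 0.3111 B`.
#'
#' @inheritParams normalize_rgb
#' @return A list with `H x W` matrices `Y_luma`, `I_chroma`, `Q_chroma`.
#' @export
rgb_to_yiq <- function(img) {
  px <- as_rgb_array(img)
  M <- .YIQ_MATRIX
  R <- rgb_plane(px, 1); G <- rgb_plane(px, 2); B <- rgb_plane(px, 3)
  list(
    Y_luma   = M[1, 1] * R + M[1, 2] * G + M[1, 3] * B,
    I_chroma = M[2, 1] * R + M[2, 2] * G + M[2, 3] * B,
    Q_chroma = M[3, 1] * R + M[3, 2] * G + M[3, 3] * B
  )
}

#' Convert RGB to Lab (full pipeline composition)
#'
#' Convenience composition [rgb_to_xyz()] then [xyz_to_lab()], used by the
#' branch pipeline's clustering feature space.
#'
#' @inheritParams normalize_rgb
#' @return A list with matrices `L`, `a`, `b_star`.
#' @export
rgb_to_lab <- function(img) xyz_to_lab(rgb_to_xyz(img))

#' Extract a chroma feature channel
#'
#' Returns the a*-plane (red-green axis of Lab, computed via
#' chromaticity-normalized XYZ) or the I-plane (of YIQ, computed from raw
#' 8-bit RGB) as a `feature_channel`: the raw float plane plus the recorded
#' `display_range` used later for 8-bit rescaling.
#'
#' @inheritParams normalize_rgb
#' @param which `"a_channel"` or `"i_channel"`.
#' @return A `feature_channel` object: list with `values` (`H x W` matrix),
#'   `source`, and `display_range` (`c(min, max)`).
#' @export
extract_feature_channel <- function(img, which = c("a_channel", "i_channel")) {
  if (length(which) != 1L || !which %in% c("a_channel", "i_channel")) {
    stop_goji("`which` must be \"a_channel\" or \"i_channel\"",
              "gojivision_invalid_argument")
  }
  values <- if (which == "a_channel") {
    rgb_to_lab(img)$a
  } else {
    rgb_to_yiq(img)$I_chroma
  }
  feature_channel(values, source = which)
}

#' Construct a feature channel
#'
#' @param values `H x W` numeric matrix.
#' @param source label describing where the plane came from.
#' @return A `feature_channel` object.
#' @export
feature_channel <- function(values, source = "custom") {
  assert_matrix(values, "values")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_goji("feature channel must be finite", "gojivision_invalid_argument")
  }
  structure(
    list(values = values, source = source, display_range = range(values)),
    class = "feature_channel"
  )
}

#' @export
print.feature_channel <- function(x, ...) {
  cat(sprintf("<feature_channel: %s> %d x %d px, display range [%.3f, %.3f]\n",
              x$source, nrow(x$values), ncol(x$values),
              x$display_range[1], x$display_range[2]))
  invisible(x)
}

as_channel_matrix <- function(x) {
  if (inherits(x, "feature_channel")) return(x$values)
  assert_matrix(x, "channel")
  x
}

#' Rescale a feature channel onto an 8-bit display range
#'
#' Linear min-max rescale of the float plane to \[0, 255\] so that channels
#' on different native scales (a* roughly \[-90, 130\], I roughly
#' \[-80, 152\]) become commensurate before fusion and histogramming. The
#' original range stays recorded in `display_range`.
#'
#' @param channel a `feature_channel` or numeric matrix.
#' @return A `feature_channel` with values in \[0, 255\].
#' @export
rescale_channel <- function(channel) {
  values <- as_channel_matrix(channel)
  out <- feature_channel(rescale_to_u8(values),
                         source = if (inherits(channel, "feature_channel"))
                           channel$source else "custom")
  out$display_range <- range(values)
  out
}
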