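# 2D discrete wavelet transform and pixel-level fusion.
#
# The transform is a periodized orthogonal DWT (Mallat pyramid) with
# Daubechies filters; periodization keeps the analysis operator exactly
# orthogonal, so inverse(forward(x)) == x to machine precision. Images whose
# sides are not multiples of 2^levels are padded by symmetric (mirror)
# extension on the bottom/right and cropped back after reconstruction.

.WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

wavelet_filters <- function(name) {
  h <- .WAVELET_FILTERS[[name]]
  if (is.null(h)) {
    stop_goji(sprintf("unknown wavelet \"%s\"; available: %s", name,
                      paste(names(.WAVELET_FILTERS), collapse = ", ")),
              "gojivision_invalid_argument")
  }
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)  # quadrature mirror filter
  list(lo = h, hi = g, length = L)
}

# Single-level analysis along rows (the transform runs over columns of each
# row); returns H x W/2 approximation and detail halves.
dwt_along_x <- function(m, flt) {
  w <- ncol(m)
  w2 <- w %/% 2L
  A <- matrix(0, nrow(m), w2)
  D <- matrix(0, nrow(m), w2)
  base <- 2L * (seq_len(w2) - 1L)
  for (n in seq_len(flt$length)) {
    idx <- ((base + (n - 1L)) %% w) + 1L
    A <- A + flt$lo[n] * m[, idx, drop = FALSE]
    D <- D + flt$hi[n] * m[, idx, drop = FALSE]
  }
  list(A = A, D = D)
}

dwt_along_y <- function(m, flt) {
  h <- nrow(m)
  h2 <- h %/% 2L
  A <- matrix(0, h2, ncol(m))
  D <- matrix(0, h2, ncol(m))
  base <- 2L * (seq_len(h2) - 1L)
  for (n in seq_len(flt$length)) {
    idx <- ((base + (n - 1L)) %% h) + 1L
    A <- A + flt$lo[n] * m[idx, , drop = FALSE]
    D <- D + flt$hi[n] * m[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

idwt_along_x <- function(A, D, flt) {
  w2 <- ncol(A)
  w <- 2L * w2
  out <- matrix(0, nrow(A), w)
  base <- 2L * (seq_len(w2) - 1L)
  for (n in seq_len(flt$length)) {
    idx <- ((base + (n - 1L)) %% w) + 1L
    out[, idx] <- out[, idx] + flt$lo[n] * A + flt$hi[n] * D
  }
  out
}

idwt_along_y <- function(A, D, flt) {
  h2 <- nrow(A)
  h <- 2L * h2
  out <- matrix(0, h, ncol(A))
  base <- 2L * (seq_len(h2) - 1L)
  for (n in seq_len(flt$length)) {
    idx <- ((base + (n - 1L)) %% h) + 1L
    out[idx, ] <- out[idx, ] + flt$lo[n] * A + flt$hi[n] * D
  }
  out
}

# Pad bottom/right by symmetric extension so both sides are multiples of
# 2^levels and the coarsest level is at least the filter length.
padded_size <- function(n, levels, flt_len) {
  block <- 2L^levels
  n_min <- max(n, flt_len * 2L^(levels - 1L))
  as.integer(ceiling(n_min / block) * block)
}

pad_bottom_right <- function(m, h_out, w_out) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(seq_len(h), mirror_tail(h, h_out - h))
  ci <- c(seq_len(w), mirror_tail(w, w_out - w))
  m[ri, ci, drop = FALSE]
}

mirror_tail <- function(n, p) {
  if (p == 0L) return(integer(0))
  base <- c(rev(seq_len(n)), seq_len(n))
  base[((seq_len(p) - 1L) %% (2L * n)) + 1L]
}

#' Multi-level 2D wavelet decomposition
#'
#' Decomposes a feature channel into a coarsest approximation plane plus
#' per-level detail planes in three orientations (`horizontal`, `vertical`,
#' `diagonal`), finest level first. Default three levels.
#'
#' @param channel a `feature_channel` or numeric matrix.
#' @param levels number of decomposition levels (>= 1); image sides must be
#'   at least `2^levels`.
#' @param wavelet filter family: `"haar"`, `"db2"` (default) or `"db4"`.
#' @return A `wavelet_pyramid` object.
#' @examples
#' img <- matrix(rnorm(64 * 64), 64)
#' pyr <- wavelet_decompose(img, levels = 3)
#' max(abs(wavelet_reconstruct(pyr) - img))  # ~1e-15: perfect reconstruction
#' @export
wavelet_decompose <- function(channel, levels = 3L, wavelet = "db2") {
  m <- as_channel_matrix(channel)
  levels <- as.integer(levels)
  if (levels < 1L) {
    stop_goji("`levels` must be >= 1", "gojivision_invalid_argument")
  }
  flt <- wavelet_filters(wavelet)
  if (nrow(m) < 2L^levels || ncol(m) < 2L^levels) {
    stop_goji(sprintf(
      "image %d x %d too small for %d levels; each side must be >= %d",
      nrow(m), ncol(m), levels, 2L^levels), "gojivision_dimension_error")
  }
  original_shape <- dim(m)
  ph <- padded_size(nrow(m), levels, flt$length)
  pw <- padded_size(ncol(m), levels, flt$length)
  if (ph != nrow(m) || pw != ncol(m)) m <- pad_bottom_right(m, ph, pw)

  details <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    rx <- dwt_along_x(cur, flt)
    lo <- dwt_along_y(rx$A, flt)   # LL, LH from the lowpass-x half
    hi <- dwt_along_y(rx$D, flt)   # HL, HH from the highpass-x half
    details[[l]] <- list(
      horizontal = lo$D,  # lowpass x, highpass y: horizontal edges
      vertical   = hi$A,  # highpass x, lowpass y: vertical edges
      diagonal   = hi$D
    )
    cur <- lo$A
  }
  structure(
    list(approx = cur, details = details, levels = levels,
         wavelet_name = wavelet, original_shape = original_shape,
         padded_shape = c(ph, pw)),
    class = "wavelet_pyramid"
  )
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("<wavelet_pyramid> %s, %d levels, source %d x %d\n",
              x$wavelet_name, x$levels, x$original_shape[1], x$original_shape[2]))
  invisible(x)
}

check_pyramid <- function(pyr) {
  ok <- inherits(pyr, "wavelet_pyramid") &&
    is.matrix(pyr$approx) && is.list(pyr$details) &&
    length(pyr$details) == pyr$levels &&
    all(vapply(pyr$details, function(d)
      all(c("horizontal", "vertical", "diagonal") %in% names(d)), logical(1)))
  if (!ok) stop_goji("corrupted wavelet pyramid", "gojivision_structure_error")
  invisible(pyr)
}

#' Inverse 2D wavelet transform
#'
#' Reconstructs the image plane from a [wavelet_decompose()] pyramid and
#' crops it back to the original shape.
#'
#' @param pyr a `wavelet_pyramid`.
#' @return `H x W` numeric matrix of the pyramid's `original_shape`.
#' @export
wavelet_reconstruct <- function(pyr) {
  check_pyramid(pyr)
  flt <- wavelet_filters(pyr$wavelet_name)
  cur <- pyr$approx
  for (l in rev(seq_len(pyr$levels))) {
    d <- pyr$details[[l]]
    loA <- idwt_along_y(cur, d$horizontal, flt)
    hiA <- idwt_along_y(d$vertical, d$diagonal, flt)
    cur <- idwt_along_x(loA, hiA, flt)
  }
  cur[seq_len(pyr$original_shape[1]), seq_len(pyr$original_shape[2]), drop = FALSE]
}

#' Fusion weights for the approximation planes
#'
#' Weighted-average coefficients for the low-frequency (approximation)
#' fusion: `alpha` weights the a-channel pyramid, `beta` the I-channel
#' pyramid; they must sum to 1. Default `0.5 / 0.5`.
#'
#' @param alpha weight of the first (a-channel) pyramid, in \[0, 1\].
#' @param beta weight of the second (I-channel) pyramid, in \[0, 1\].
#' @return A `fusion_weights` object.
#' @export
fusion_weights <- function(alpha = 0.5, beta = 0.5) {
  if (!is_scalar_number(alpha) || !is_scalar_number(beta) ||
      alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12) {
    stop_goji("weights must be non-negative and sum to 1",
              "gojivision_invalid_argument")
  }
  structure(list(alpha = alpha, beta = beta), class = "fusion_weights")
}

fuse_detail <- function(ca, ci) {
  # maximum-absolute-value rule, sign preserved; ties keep the a-channel
  # coefficient (|ca| >= |ci| selects ca)
  take_a <- abs(ca) >= abs(ci)
  out <- ci
  out[take_a] <- ca[take_a]
  out
}

#' Fuse two wavelet pyramids
#'
#' Detail (high-frequency) coefficients are fused by the
#' maximum-absolute-value rule, preserving sign; the approximation
#' (low-frequency) planes are fused by the weighted average
#' `alpha * A_a + beta * A_i`.
#'
#' @param pyr_a,pyr_i pyramids of identical levels, shapes and wavelet.
#' @param w a [fusion_weights()] object.
#' @return A fused `wavelet_pyramid`.
#' @export
wavelet_fuse <- function(pyr_a, pyr_i, w = fusion_weights()) {
  check_pyramid(pyr_a); check_pyramid(pyr_i)
  if (pyr_a$levels != pyr_i$levels ||
      pyr_a$wavelet_name != pyr_i$wavelet_name ||
      !identical(pyr_a$original_shape, pyr_i$original_shape)) {
    stop_goji("pyramids are incompatible (levels, wavelet or shape differ)",
              "gojivision_incompatible")
  }
  out <- pyr_a
  out$approx <- w$alpha * pyr_a$approx + w$beta * pyr_i$approx
  for (l in seq_len(out$levels)) {
    out$details[[l]] <- list(
      horizontal = fuse_detail(pyr_a$details[[l]]$horizontal,
                               pyr_i$details[[l]]$horizontal),
      vertical   = fuse_detail(pyr_a$details[[l]]$vertical,
                               pyr_i$details[[l]]$vertical),
      diagonal   = fuse_detail(pyr_a$details[[l]]$diagonal,
                               pyr_i$details[[l]]$diagonal)
    )
  }
  out
}

#' Pixel-level fusion of two feature channels
#'
#' Composition decompose -> fuse -> reconstruct. The two channels must have
#' equal shape and are expected to already live on a common scale (the fruit
#' pipeline rescales both to \[0, 255\] first, see [rescale_channel()]).
#'
#' @param chan_a,chan_i feature channels or matrices of equal shape.
#' @param w a [fusion_weights()] object.
#' @param levels decomposition levels (default 3).
#' @param wavelet wavelet family (default `"db2"`).
#' @return A `feature_channel` holding the fused plane.
#' @export
fuse_feature_images <- function(chan_a, chan_i, w = fusion_weights(),
                                levels = 3L, wavelet = "db2") {
  ma <- as_channel_matrix(chan_a)
  mi <- as_channel_matrix(chan_i)
  if (!identical(dim(ma), dim(mi))) {
    stop_goji("feature channels have different shapes", "gojivision_incompatible")
  }
  pa <- wavelet_decompose(ma, levels = levels, wavelet = wavelet)
  pi_ <- wavelet_decompose(mi, levels = levels, wavelet = wavelet)
  fused <- wavelet_reconstruct(wavelet_fuse(pa, pi_, w))
  feature_channel(fused, source = "fused")
}
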