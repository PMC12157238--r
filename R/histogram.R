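# Grayscale histogramming and bimodal valley thresholding.
#
# The fused feature image has a bimodal grayscale distribution: a tall
# background peak and a smaller fruit peak at higher gray values. The
# binarization threshold is the valley between the two highest smoothed
# peaks; when the fruit peak is submerged (fewer than two peaks found) the
# threshold falls back to a variance-maximizing (Otsu) split, and the method
# actually used is recorded in the result.

#' Grayscale histogram of an 8-bit plane
#'
#' Bins values into 256 integer bins (bin = `floor(value)`, clamped to
#' \[0, 255\]). Counts always sum to the pixel count.
#'
#' @param img a `feature_channel` or numeric matrix with values in
#'   \[0, 255\].
#' @return A `gray_histogram`: list with integer `counts` (length 256) and
#'   `total`.
#' @export
compute_histogram <- function(img) {
  v <- as_channel_matrix(img)
  if (min(v) < 0 || max(v) > 255) {
    stop_goji("histogram input must lie in [0, 255]; rescale first",
              "gojivision_invalid_argument")
  }
  bins <- pmin(as.integer(floor(v)), 255L)
  structure(
    list(counts = tabulate(bins + 1L, nbins = 256L), total = length(v)),
    class = "gray_histogram"
  )
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat(sprintf("<gray_histogram> %d px, populated bins %d..%d\n",
              x$total, min(nz), max(nz)))
  invisible(x)
}

# moving average with partial windows at the ends (effective-count divisor)
smooth_counts <- function(counts, width) {
  if (width <= 1L) return(as.numeric(counts))
  half <- (width - 1L) %/% 2L
  kern <- rep(1, 2L * half + 1L)
  num <- stats::filter(c(rep(0, half), counts, rep(0, half)), kern, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(counts)), rep(0, half)),
                       kern, sides = 2)
  (num / den)[(half + 1L):(half + length(counts))]
}

# local maxima of a vector with plateau handling: a maximal run of equal
# values higher than both neighbors is one peak at the run's center
find_peaks <- function(v) {
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  heights <- numeric(0)
  for (i in seq_along(r$values)) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == length(r$values)) -Inf else r$values[i + 1L]
    if (r$values[i] > left && r$values[i] > right && r$values[i] > 0) {
      peaks <- c(peaks, as.integer(round((starts[i] + ends[i]) / 2)))
      heights <- c(heights, r$values[i])
    }
  }
  list(pos = peaks, height = heights)
}

# Otsu's variance-maximizing split on raw counts; returns a bin in [0, 255]
otsu_threshold <- function(counts) {
  counts <- as.numeric(counts)  # cumulative moments overflow integers
  total <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  mu <- cumsum(counts * levels)
  mu_t <- mu[256]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, 256)
  between[valid] <- (mu_t * w0[valid] - total * mu[valid])^2 /
    (w0[valid] * w1[valid])
  which.max(between) - 1L
}

#' Valley threshold of a bimodal histogram
#'
#' Smooths the histogram with a small moving average (default width 5),
#' locates the two highest sufficiently separated peaks, and places the
#' threshold at the valley between them: the midpoint of the longest
#' contiguous run of bins whose smoothed count is within
#' `valley_tolerance` (a fraction of the pixel total) of the minimum. A
#' flat zero plateau thus resolves to its midpoint, and a valley floor
#' carrying a thin smear of edge-gradient pixels is treated as flat rather
#' than letting a few stray counts pin the threshold against one mode.
#' When fewer than two distinct peaks exist (the minority mode can be
#' submerged), falls back to a variance-maximizing (Otsu) split; the
#' method used is recorded.
#'
#' @param hist a [compute_histogram()] result.
#' @param smooth_width moving-average width in bins (odd, default 5).
#' @param min_separation smallest distance in bins between the two peaks
#'   for them to count as distinct modes (default 32); closer maxima are
#'   ripples of a single mode, not a bimodal structure. The method's
#'   premise is a widely spaced foreground/background pair of modes, so
#'   textured backgrounds whose own ripples sit closer than this are not
#'   mistaken for bimodality.
#' @param valley_tolerance counts within `valley_tolerance * total` of the
#'   valley minimum belong to the valley floor (default `1e-4`).
#' @return A `threshold_result`: list with integer `threshold` (0-255),
#'   `method` (`"valley"` or `"otsu"`), and `peaks` (the two peak bins, or
#'   `NULL` under the fallback).
#' @export
valley_threshold <- function(hist, smooth_width = 5L, min_separation = 32L,
                             valley_tolerance = 1e-4) {
  if (!inherits(hist, "gray_histogram")) hist <- compute_histogram(hist)
  if (hist$total == 0L) {
    stop_goji("empty histogram", "gojivision_invalid_argument")
  }
  sm <- smooth_counts(hist$counts, as.integer(smooth_width))
  pk <- find_peaks(sm)
  if (length(pk$pos) >= 2L) {
    ord <- order(pk$height, decreasing = TRUE)
    first <- ord[1]
    second <- NA_integer_
    for (j in ord[-1]) {
      if (abs(pk$pos[j] - pk$pos[first]) >= min_separation) {
        second <- j
        break
      }
    }
    p <- if (is.na(second)) integer(0) else sort(pk$pos[c(first, second)])
    if (length(p) == 2L && p[2] - p[1] >= 2L) {
      inner <- sm[(p[1] + 1L):(p[2] - 1L)]
      floor_tol <- min(inner) + valley_tolerance * hist$total
      runs <- rle(inner <= floor_tol)
      run_end <- cumsum(runs$lengths)
      run_start <- run_end - runs$lengths + 1L
      best <- which(runs$values)[which.max(runs$lengths[runs$values])]
      cand <- run_start[best]:run_end[best]
      t_bin <- p[1] + as.integer(round(mean(cand))) - 1L  # 0-based bin
      return(structure(list(threshold = t_bin, method = "valley",
                            peaks = p - 1L),
                       class = "threshold_result"))
    }
  }
  structure(list(threshold = otsu_threshold(hist$counts), method = "otsu",
                 peaks = NULL),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t = %d (%s)\n", x$threshold, x$method))
  invisible(x)
}

#' Binarize a gray plane at a threshold
#'
#' Default polarity is bright-is-foreground (`value > t`), matching fruits
#' whose fused gray values exceed the background's; `polarity = "dark"`
#' selects `value <= t` (used for dark branches against bright
#' surroundings).
#'
#' @param img a `feature_channel` or numeric matrix.
#' @param t integer threshold in \[0, 255\], or a `threshold_result`.
#' @param polarity `"bright"` (default) or `"dark"`.
#' @return Logical `H x W` matrix (`TRUE` = foreground).
#' @export
binarize <- function(img, t, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  v <- as_channel_matrix(img)
  if (inherits(t, "threshold_result")) t <- t$threshold
  if (!is_scalar_number(t) || t < 0 || t > 255) {
    stop_goji("`t` must be a number in [0, 255]", "gojivision_invalid_argument")
  }
  if (polarity == "bright") v > t else v <= t
}
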