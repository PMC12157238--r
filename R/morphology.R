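# Binary-mask operations: morphology, median filtering, connected
# components, area filtering.
#
# Masks are plain logical H x W matrices (TRUE = foreground). Components
# are 8-connected throughout; labeling rides on EBImage::bwlabel (which is
# 4-connected) plus a union-find merge across diagonal adjacencies.

as_mask <- function(mask) {
  assert_matrix(mask, "mask")
  if (!is.logical(mask)) mask <- mask > 0
  mask
}

square_offsets <- function(side) {
  side <- as.integer(side)
  if (side < 1L) stop_goji("kernel side must be >= 1", "gojivision_invalid_argument")
  # odd kernels centered; even kernels anchored with origin at top-left cell
  lo <- -((side - 1L) %/% 2L)
  off <- lo:(lo + side - 1L)
  expand.grid(dy = off, dx = off)
}

#' Morphological erosion of a binary mask
#'
#' @param mask logical matrix (or numeric; nonzero = foreground).
#' @param kernel side length of the square structuring element. Odd kernels
#'   are centered; even kernels (e.g. the branch stage's 2x2) anchor their
#'   origin at the top-left cell.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, kernel = 3L) {
  m <- as_mask(mask)
  off <- square_offsets(kernel)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mat(m, off$dy[i], off$dx[i], FALSE)
  }
  out
}

#' Morphological dilation of a binary mask
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, kernel = 3L) {
  m <- as_mask(mask)
  off <- square_offsets(kernel)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(m, -off$dy[i], -off$dx[i], FALSE)
  }
  out
}

#' Morphological opening (erosion then dilation)
#'
#' Removes foreground structures smaller than the structuring element (the
#' union of all kernel translates contained in the mask); idempotent.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
morphological_open <- function(mask, kernel = 3L) {
  dilate_mask(erode_mask(mask, kernel), kernel)
}

#' Median filter
#'
#' Replaces each pixel by the median of its `window x window` neighborhood
#' with symmetric (mirror) border extension. Binary input uses an exact
#' majority-vote fast path; the general path sorts each neighborhood.
#'
#' @param img numeric or logical matrix.
#' @param window odd window size >= 3 (default 3).
#' @return Matrix of the same type (logical in, logical out).
#' @export
median_filter <- function(img, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop_goji("`window` must be an odd integer >= 3", "gojivision_invalid_argument")
  }
  was_logical <- is.logical(img)
  assert_matrix(img, "img")
  half <- (window - 1L) %/% 2L
  padded <- pad_symmetric(if (was_logical) img * 1 else img, half)
  h <- nrow(img); w <- ncol(img)
  vals <- unique(as.numeric(padded))
  if (length(vals) <= 2L && all(vals %in% c(0, 1))) {
    # binary: median of window^2 zeros/ones = majority vote
    acc <- matrix(0, h, w)
    for (dy in -half:half) for (dx in -half:half) {
      acc <- acc + padded[(1 + half + dy):(h + half + dy),
                          (1 + half + dx):(w + half + dx), drop = FALSE]
    }
    out <- acc >= (window^2 + 1) / 2
    return(if (was_logical) out else out * 1)
  }
  stack <- matrix(0, h * w, window^2)
  k <- 0L
  for (dy in -half:half) for (dx in -half:half) {
    k <- k + 1L
    stack[, k] <- as.numeric(padded[(1 + half + dy):(h + half + dy),
                                    (1 + half + dx):(w + half + dx), drop = FALSE])
  }
  matrix(apply(stack, 1L, stats::median), h, w)
}

# small iterative union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label 8-connected components
#'
#' @param mask logical matrix.
#' @return Integer matrix of labels (0 = background, components numbered
#'   `1..n` in scan order) with attribute `n` giving the component count.
#' @export
label_components <- function(mask) {
  m <- as_mask(mask)
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n4 <- max(lab)
  if (n4 > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    # diagonal adjacencies missed by 4-connected labeling
    p1 <- lab[-h, -w]; q1 <- lab[-1, -1]   # down-right
    p2 <- lab[-1, -w]; q2 <- lab[-h, -1]   # up-right
    sel1 <- p1 > 0L & q1 > 0L & p1 != q1
    sel2 <- p2 > 0L & q2 > 0L & p2 != q2
    pairs <- unique(rbind(cbind(p1[sel1], q1[sel1]), cbind(p2[sel2], q2[sel2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(n4)
      for (i in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[i, 1]); rb <- uf_find(parent, pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n4), function(i) uf_find(parent, i), integer(1))
      remap <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  structure(lab, n = max(lab))
}

#' Per-component statistics of a binary mask
#'
#' Areas, bounding boxes and first-moment centroids of every 8-connected
#' component, in the package's 0-based x = column / y = row convention.
#'
#' @param mask logical matrix.
#' @return A tibble with columns `component`, `area`, `centroid_x`,
#'   `centroid_y`, `xmin`, `xmax`, `ymin`, `ymax`, `bbox_height`.
#' @export
component_stats <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n")
  if (n == 0L) {
    return(tibble::tibble(
      component = integer(0), area = integer(0),
      centroid_x = numeric(0), centroid_y = numeric(0),
      xmin = integer(0), xmax = integer(0), ymin = integer(0),
      ymax = integer(0), bbox_height = integer(0)
    ))
  }
  sel <- which(lab > 0L)
  l <- lab[sel]
  rows <- ((sel - 1L) %% nrow(lab))        # 0-based y
  cols <- ((sel - 1L) %/% nrow(lab))       # 0-based x
  area <- tabulate(l, nbins = n)
  cx <- as.numeric(tapply(cols, l, mean))
  cy <- as.numeric(tapply(rows, l, mean))
  xmin <- as.integer(tapply(cols, l, min)); xmax <- as.integer(tapply(cols, l, max))
  ymin <- as.integer(tapply(rows, l, min)); ymax <- as.integer(tapply(rows, l, max))
  tibble::tibble(
    component = seq_len(n), area = as.integer(area),
    centroid_x = cx, centroid_y = cy,
    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    bbox_height = ymax - ymin + 1L
  )
}

#' Remove small connected components
#'
#' Drops every 8-connected component with area strictly below `min_area`
#' ("fewer than `min_area` pixels"); a component of exactly `min_area`
#' pixels survives.
#'
#' @param mask logical matrix.
#' @param min_area minimum surviving area in pixels (default 100).
#' @return Logical matrix.
#' @export
area_filter <- function(mask, min_area = 100L) {
  if (!is_scalar_number(min_area) || min_area < 0) {
    stop_goji("`min_area` must be a non-negative number", "gojivision_invalid_argument")
  }
  m <- as_mask(mask)
  lab <- label_components(m)
  n <- attr(lab, "n")
  if (n == 0L) return(m)
  area <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(area >= min_area)
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[lab %in% keep & lab > 0L] <- TRUE
  out
}
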