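# Internal helpers shared across modules.
#
# Coordinate convention (package-wide): x = column index, y = row index,
# both 0-based, pixel centers at integer coordinates. R matrices are indexed
# 1-based, so x = col - 1, y = row - 1 at the public surface.

stop_goji <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gojivision_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
assert_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x) && !is.logical(x)) {
    stop_goji(sprintf("`%s` must be a numeric or logical matrix", what),
              "gojivision_invalid_argument")
  }
  invisible(x)
}

# Shift a matrix by (dy, dx): out[i, j] = m[i + dy, j + dx] where defined,
# `fill` elsewhere. Used by the morphology kernels.
shift_mat <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ri <- seq_len(h) + dy
  ci <- seq_len(w) + dx
  keep_r <- ri >= 1L & ri <= h
  keep_c <- ci >= 1L & ci <= w
  if (any(keep_r) && any(keep_c)) {
    out[which(keep_r), which(keep_c)] <- m[ri[keep_r], ci[keep_c], drop = FALSE]
  }
  out
}

# Symmetric (edge-repeating mirror) padding by `p` pixels on every side.
pad_symmetric <- function(m, p) {
  h <- nrow(m); w <- ncol(m)
  if (p >= h || p >= w) {
    # mirror repeatedly for very small inputs
    ri <- mirror_index(h, p)
    ci <- mirror_index(w, p)
  } else {
    ri <- c(p:1, seq_len(h), h:(h - p + 1L))
    ci <- c(p:1, seq_len(w), w:(w - p + 1L))
  }
  m[ri, ci, drop = FALSE]
}

mirror_index <- function(n, p) {
  # index sequence for symmetric extension of 1:n by p on both sides
  base <- c(seq_len(n), rev(seq_len(n)))
  idx <- ((seq.int(-p, n + p - 1L)) %% (2L * n)) + 1L
  base[idx]
}

# Linear min-max rescale of a numeric plane onto [0, 255]. A constant plane
# maps to 0 (no contrast to preserve).
rescale_to_u8 <- function(values) {
  rng <- range(values)
  if (!all(is.finite(rng))) {
    stop_goji("plane contains non-finite values", "gojivision_invalid_argument")
  }
  if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1]) * 255 else values * 0
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Cheap provenance fingerprint for run reports (dimensions + value sum).
content_fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("%s:%.8g", paste(dim(x) %||% length(x), collapse = "x"), sum(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
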