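# Independent brute-force oracles. These deliberately use explicit loops
# and scalar arithmetic, sharing no code path with the package internals
# they check.

# per-pixel 3x3 matrix-vector product
oracle_linear_map <- function(M, v) {
  out <- numeric(3)
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + M[i, j] * v[j]
    out[i] <- acc
  }
  out
}

XYZ_M <- matrix(c(
  0.433953, 0.376219, 0.289828,
  0.212671, 0.715160, 0.072169,
  0.017758, 0.109477, 0.872765
), nrow = 3, byrow = TRUE)

YIQ_M <- matrix(c(
  0.2990,  0.5870,  0.1140,
  0.5957, -0.2745, -0.3213,
  0.2115, -0.5226,  0.3111
), nrow = 3, byrow = TRUE)

# single-level periodized DWT along a vector, explicit loops
oracle_dwt_1d <- function(x, h, g) {
  n <- length(x)
  n2 <- n %/% 2
  A <- numeric(n2); D <- numeric(n2)
  for (k in 0:(n2 - 1)) {
    a <- 0; d <- 0
    for (m in seq_along(h)) {
      xi <- ((2 * k + (m - 1)) %% n) + 1
      a <- a + h[m] * x[xi]
      d <- d + g[m] * x[xi]
    }
    A[k + 1] <- a; D[k + 1] <- d
  }
  list(A = A, D = D)
}

db2_lo <- c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604)
db2_hi <- (-1)^(0:3) * rev(db2_lo)

# single-level 2D DWT by looping the 1D oracle over rows then columns
oracle_dwt_2d <- function(m, h = db2_lo, g = db2_hi) {
  H <- nrow(m); W <- ncol(m)
  Arows <- matrix(0, H, W %/% 2); Drows <- matrix(0, H, W %/% 2)
  for (i in seq_len(H)) {
    r <- oracle_dwt_1d(m[i, ], h, g)
    Arows[i, ] <- r$A; Drows[i, ] <- r$D
  }
  res <- list()
  for (half in c("A", "D")) {
    src <- if (half == "A") Arows else Drows
    Acol <- matrix(0, H %/% 2, ncol(src)); Dcol <- Acol
    for (j in seq_len(ncol(src))) {
      r <- oracle_dwt_1d(src[, j], h, g)
      Acol[, j] <- r$A; Dcol[, j] <- r$D
    }
    res[[half]] <- list(lo = Acol, hi = Dcol)
  }
  # orientation naming as in the package: horizontal = lo-x/hi-y,
  # vertical = hi-x/lo-y, diagonal = hi-x/hi-y
  list(LL = res$A$lo, horizontal = res$A$hi,
       vertical = res$D$lo, diagonal = res$D$hi)
}

# brute-force centroid of a logical mask in 0-based x/y
oracle_centroid <- function(mask) {
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        sx <- sx + (j - 1); sy <- sy + (i - 1); n <- n + 1
      }
    }
  }
  c(x = sx / n, y = sy / n)
}

# brute-force median filter with symmetric (mirror, edge-repeating) border
oracle_median_filter <- function(m, w) {
  reflect <- function(i, n) {
    # edge-repeating mirror: 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
    i
  }
  half <- (w - 1) %/% 2
  out <- m * 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      vals <- c()
      for (di in -half:half) {
        for (dj in -half:half) {
          vals <- c(vals, m[reflect(i + di, nrow(m)), reflect(j + dj, ncol(m))])
        }
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# brute-force nearest foreground pixel to a point (0-based), ties by
# smaller y then smaller x
oracle_nearest_fg <- function(mask, cx, cy) {
  best <- NULL; bd <- Inf
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      x <- j - 1; y <- i - 1
      d <- (x - cx)^2 + (y - cy)^2
      if (d < bd - 1e-12 ||
          (abs(d - bd) <= 1e-12 && (y < best[2] ||
                                    (y == best[2] && x < best[1])))) {
        bd <- d; best <- c(x, y)
      }
    }
  }
  best
}

# deterministic small RGB test images
flat_rgb <- function(h, w, col) {
  arr <- array(0, c(h, w, 3))
  for (k in 1:3) arr[, , k] <- col[k]
  arr
}

disk_on_background <- function(h, w, cx, cy, r, fg, bg) {
  arr <- flat_rgb(h, w, bg)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if ((j - 1 - cx)^2 + (i - 1 - cy)^2 <= r^2) {
        for (k in 1:3) arr[i, j, k] <- fg[k]
      }
    }
  }
  arr
}
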