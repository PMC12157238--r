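test_that("decompose/reconstruct is a perfect-reconstruction pair", {
  set.seed(21)
  for (wv in c("haar", "db2", "db4")) {
    img <- matrix(runif(64 * 64, 0, 255), 64)
    pyr <- wavelet_decompose(img, levels = 3, wavelet = wv)
    expect_equal(pyr$levels, 3L)
    expect_length(pyr$details, 3L)
    expect_lt(max(abs(wavelet_reconstruct(pyr) - img)), 1e-8)
  }
  # non-dyadic sizes are padded symmetrically and cropped back
  odd <- matrix(runif(57 * 43, 0, 255), 57)
  rec <- wavelet_reconstruct(wavelet_decompose(odd, levels = 3))
  expect_equal(dim(rec), dim(odd))
  expect_lt(max(abs(rec - odd)), 1e-8)
})

test_that("constant images carry no detail energy", {
  pyr <- wavelet_decompose(matrix(42, 32, 32), levels = 3)
  for (l in 1:3) {
    for (b in c("horizontal", "vertical", "diagonal")) {
      expect_lt(max(abs(pyr$details[[l]][[b]])), 1e-10)
    }
  }
})

test_that("level-1 planes agree with an independent loop implementation", {
  set.seed(5)
  img <- matrix(runif(16 * 16, 0, 10), 16)
  pyr <- wavelet_decompose(img, levels = 1, wavelet = "db2")
  ora <- oracle_dwt_2d(img)
  expect_equal(pyr$approx, ora$LL, tolerance = 1e-12)
  expect_equal(pyr$details[[1]]$horizontal, ora$horizontal, tolerance = 1e-12)
  expect_equal(pyr$details[[1]]$vertical, ora$vertical, tolerance = 1e-12)
  expect_equal(pyr$details[[1]]$diagonal, ora$diagonal, tolerance = 1e-12)
})

test_that("a vertical step edge concentrates energy in the vertical band", {
  img <- matrix(0, 64, 64)
  img[, 33:64] <- 200  # step across columns: a vertical edge
  pyr <- wavelet_decompose(img, levels = 3)
  e_v <- sum(pyr$details[[1]]$vertical^2)
  e_d <- sum(pyr$details[[1]]$diagonal^2)
  e_h <- sum(pyr$details[[1]]$horizontal^2)
  expect_gt(e_v, e_d)
  expect_gt(e_v, e_h)
})

test_that("too-small images and malformed pyramids raise typed errors", {
  expect_error(wavelet_decompose(matrix(0, 4, 4), levels = 3),
               class = "gojivision_dimension_error")
  expect_error(wavelet_decompose(matrix(0, 4, 4), levels = 3),
               regexp = ">= 8")
  pyr <- wavelet_decompose(matrix(runif(64), 8), levels = 1)
  pyr$details <- list()
  expect_error(wavelet_reconstruct(pyr), class = "gojivision_structure_error")
})

test_that("fusion rules: max-abs details, weighted-average approximation", {
  set.seed(31)
  a <- matrix(runif(32 * 32, 0, 255), 32)
  b <- matrix(runif(32 * 32, 0, 255), 32)
  pa <- wavelet_decompose(a, 3)
  pb <- wavelet_decompose(b, 3)
  fused <- wavelet_fuse(pa, pb, fusion_weights(0.5, 0.5))
  expect_equal(fused$approx, 0.5 * pa$approx + 0.5 * pb$approx)
  for (l in 1:3) {
    for (band in c("horizontal", "vertical", "diagonal")) {
      ca <- pa$details[[l]][[band]]
      cb <- pb$details[[l]][[band]]
      cf <- fused$details[[l]][[band]]
      # every fused coefficient has the larger absolute value, sign kept
      expect_equal(abs(cf), pmax(abs(ca), abs(cb)))
      expect_true(all(cf == ca | cf == cb))
    }
  }
  # signed max-abs: (-3, 2) -> -3, and ties keep the first pyramid
  expect_equal(gojivision:::fuse_detail(matrix(-3), matrix(2)), matrix(-3))
  expect_equal(gojivision:::fuse_detail(matrix(-2), matrix(2)), matrix(-2))
})

test_that("fusion is idempotent and symmetric at equal weights", {
  set.seed(41)
  a <- matrix(runif(48 * 40, 0, 255), 48)
  b <- matrix(runif(48 * 40, 0, 255), 48)
  expect_lt(max(abs(fuse_feature_images(a, a)$values - a)), 1e-6)
  f_ab <- fuse_feature_images(a, b)
  f_ba <- fuse_feature_images(b, a)
  expect_lt(max(abs(f_ab$values - f_ba$values)), 1e-9)
})

test_that("fused approximation stays inside the pointwise convex hull", {
  set.seed(51)
  a <- matrix(runif(32 * 32, 0, 255), 32)
  b <- matrix(runif(32 * 32, 0, 255), 32)
  for (al in c(0.2, 0.5, 0.8)) {
    f <- wavelet_fuse(wavelet_decompose(a, 2), wavelet_decompose(b, 2),
                      fusion_weights(al, 1 - al))
    lo <- pmin(wavelet_decompose(a, 2)$approx, wavelet_decompose(b, 2)$approx)
    hi <- pmax(wavelet_decompose(a, 2)$approx, wavelet_decompose(b, 2)$approx)
    expect_true(all(f$approx >= lo - 1e-9 & f$approx <= hi + 1e-9))
  }
})

test_that("incompatible pyramids and invalid weights are rejected", {
  a <- wavelet_decompose(matrix(runif(64 * 64), 64), 3)
  b <- wavelet_decompose(matrix(runif(32 * 32), 32), 3)
  expect_error(wavelet_fuse(a, b), class = "gojivision_incompatible")
  c2 <- wavelet_decompose(matrix(runif(64 * 64), 64), 2)
  expect_error(wavelet_fuse(a, c2), class = "gojivision_incompatible")
  expect_error(fusion_weights(0.7, 0.7), class = "gojivision_invalid_argument")
  expect_error(fuse_feature_images(matrix(0, 16, 16), matrix(0, 16, 8)),
               class = "gojivision_incompatible")
})

test_that("fusion keeps the contrast of a structure present in one channel", {
  a <- matrix(20, 64, 64)
  a[25:40, 25:40] <- 220  # bright block only in the a-channel
  b <- matrix(120, 64, 64)
  inside <- function(m) mean(m[28:37, 28:37])
  outside <- function(m) mean(m[1:10, 1:10])
  f <- fuse_feature_images(a, b)$values
  contrast_f <- inside(f) - outside(f)
  contrast_min <- min(inside(a) - outside(a), inside(b) - outside(b))
  expect_gte(contrast_f, contrast_min)
})
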