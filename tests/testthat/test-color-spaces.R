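test_that("chromaticity normalization sums to one and handles black pixels", {
  px <- array(c(255, 0, 0, 128, 128, 128, 0, 0, 0, 12, 200, 99),
              c(2, 2, 3))
  # fill deliberately: construct explicit pixels instead
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(255, 0, 0)
  px[1, 2, ] <- c(128, 128, 128)
  px[2, 1, ] <- c(0, 0, 0)
  px[2, 2, ] <- c(12, 200, 99)
  chr <- normalize_rgb(px)
  expect_equal(chr[1, 1, ], c(1, 0, 0))
  expect_equal(chr[1, 2, ], c(1, 1, 1) / 3)
  expect_equal(chr[2, 1, ], c(0, 0, 0))  # black-pixel convention
  s <- chr[, , 1] + chr[, , 2] + chr[, , 3]
  expect_equal(s[2, 2], 1, tolerance = 1e-12)
})

test_that("rgb_to_xyz and rgb_to_yiq match an independent matrix product", {
  set.seed(11)
  n <- 500
  px <- array(sample(0:255, n * 3, replace = TRUE), c(n, 1, 3))
  xyz <- rgb_to_xyz(px)
  yiq <- rgb_to_yiq(px)
  for (i in seq_len(n)) {
    v <- px[i, 1, ]
    chr <- if (sum(v) > 0) v / sum(v) else c(0, 0, 0)
    ex <- oracle_linear_map(XYZ_M, chr)
    expect_equal(c(xyz$X[i, 1], xyz$Y[i, 1], xyz$Z[i, 1]), ex,
                 tolerance = 1e-9)
    ey <- oracle_linear_map(YIQ_M, v)
    expect_equal(c(yiq$Y_luma[i, 1], yiq$I_chroma[i, 1], yiq$Q_chroma[i, 1]),
                 ey, tolerance = 1e-9)
  }
})

test_that("printed-coefficient spot values reproduce", {
  red <- array(c(255, 0, 0), c(1, 1, 3))
  xyz <- rgb_to_xyz(red)
  expect_equal(xyz$X[1, 1], 0.433953)
  expect_equal(xyz$Y[1, 1], 0.212671)
  expect_equal(xyz$Z[1, 1], 0.017758)
  yiq <- rgb_to_yiq(red)
  expect_equal(yiq$Y_luma[1, 1], 76.245)
  expect_equal(yiq$I_chroma[1, 1], 151.9035)
  expect_equal(yiq$Q_chroma[1, 1], 53.9325)
  gray <- array(100, c(1, 1, 3))
  yg <- rgb_to_yiq(gray)
  expect_equal(yg$Y_luma[1, 1], 100)
  expect_equal(yg$I_chroma[1, 1], -0.01)
  expect_equal(yg$Q_chroma[1, 1], 0)
})

test_that("Lab transform follows the piecewise f and zeroes chroma on equal XYZ", {
  lab1 <- xyz_to_lab(list(X = matrix(1), Y = matrix(1), Z = matrix(1)))
  expect_equal(lab1$L[1, 1], 100)
  expect_equal(lab1$a[1, 1], 0)
  expect_equal(lab1$b_star[1, 1], 0)
  # below the knee the linear branch applies
  lab2 <- xyz_to_lab(list(X = matrix(0.004), Y = matrix(0.004),
                          Z = matrix(0.004)))
  expect_equal(lab2$L[1, 1], 116 * (7.787 * 0.004 + 16 / 116) - 16)
  expect_equal(lab2$a[1, 1], 0)
  # pure red evaluated by scalar arithmetic
  lab3 <- xyz_to_lab(list(X = matrix(0.433953), Y = matrix(0.212671),
                          Z = matrix(0.017758)))
  expect_equal(lab3$a[1, 1],
               500 * (0.433953^(1 / 3) - 0.212671^(1 / 3)),
               tolerance = 1e-12)
})

test_that("achromatic images have a constant a-plane and near-zero I-plane", {
  # the XYZ matrix's first row sums to 1.1 (the others to 1.0), so equal
  # R = G = B gives X != Y and a constant, non-zero a*; what must hold is
  # that a* carries no spatial structure on achromatic regions, and that
  # the I residual stays within 255 x |row-sum| = 0.026
  a_ref <- 500 * (gojivision:::lab_f(1.1 / 3) - gojivision:::lab_f(1 / 3))
  for (level in c(100, 200, 255)) {
    img <- flat_rgb(4, 5, c(level, level, level))
    a <- extract_feature_channel(img, "a_channel")
    i <- extract_feature_channel(img, "i_channel")
    expect_lt(diff(range(a$values)), 1e-9)       # constant plane
    expect_equal(a$values[1, 1], a_ref, tolerance = 1e-9)
    expect_true(all(abs(i$values) <= 0.026))
  }
})

test_that("a* and I respond monotonically to red with G, B fixed", {
  rs <- seq(10, 255, by = 35)
  a_vals <- vapply(rs, function(R) {
    extract_feature_channel(flat_rgb(1, 1, c(R, 80, 60)), "a_channel")$values[1, 1]
  }, numeric(1))
  i_vals <- vapply(rs, function(R) {
    extract_feature_channel(flat_rgb(1, 1, c(R, 80, 60)), "i_channel")$values[1, 1]
  }, numeric(1))
  expect_true(all(diff(a_vals) >= 0))
  expect_true(all(diff(i_vals) >= 0))
})

test_that("feature channel extraction separates a red disk from green ground", {
  img <- disk_on_background(32, 32, 15, 15, 8,
                            fg = c(196, 30, 40), bg = c(64, 115, 48))
  a <- extract_feature_channel(img, "a_channel")$values
  inside <- a[16, 16]
  outside <- a[2, 2]
  expect_gt(inside, outside)
  expect_error(extract_feature_channel(img, "q_channel"),
               class = "gojivision_invalid_argument")
})

test_that("rescale_channel maps onto [0, 255] and records the native range", {
  ch <- feature_channel(matrix(c(-30, 0, 45, 120), 2), source = "custom")
  r <- rescale_channel(ch)
  expect_equal(range(r$values), c(0, 255))
  expect_equal(r$display_range, c(-30, 120))
  # constant planes have no contrast to preserve
  expect_true(all(rescale_channel(matrix(7, 3, 3))$values == 0))
})

test_that("standard CIE Lab variant differs from the pipeline variant", {
  xyz <- rgb_to_xyz(flat_rgb(2, 2, c(210, 90, 60)))
  lit <- xyz_to_lab(xyz)
  cie <- xyz_to_lab_cie(xyz)
  expect_false(isTRUE(all.equal(lit$a, cie$a)))
})
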