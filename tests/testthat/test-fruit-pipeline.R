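test_that("centroids are first moments and match the brute-force oracle", {
  m <- matrix(FALSE, 10, 10)
  m[2, 3] <- TRUE   # x = 2, y = 1 in 0-based coordinates
  det <- fruit_centroids(m)
  expect_equal(det$centroid_x, 2)
  expect_equal(det$centroid_y, 1)

  sq <- matrix(FALSE, 12, 12)
  sq[1:10, 1:10] <- TRUE
  det2 <- fruit_centroids(sq)
  expect_equal(det2$centroid_x, 4.5)
  expect_equal(det2$centroid_y, 4.5)

  disk <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    if ((j - 1 - 20)^2 + (i - 1 - 30)^2 <= 49) disk[i, j] <- TRUE
  }
  det3 <- fruit_centroids(disk)
  expect_lt(abs(det3$centroid_x - 20), 0.1)
  expect_lt(abs(det3$centroid_y - 30), 0.1)
  ora <- oracle_centroid(disk)
  expect_equal(det3$centroid_x, ora[["x"]], tolerance = 1e-9)
  expect_equal(det3$centroid_y, ora[["y"]], tolerance = 1e-9)

  expect_equal(nrow(fruit_centroids(matrix(FALSE, 5, 5))), 0L)
})

test_that("every centroid lies inside its component bounding box", {
  set.seed(17)
  for (rep in 1:5) {
    m <- morphological_open(matrix(runif(40 * 40) < 0.45, 40, 40), 2)
    det <- fruit_centroids(m)
    if (nrow(det) == 0) next
    expect_true(all(det$centroid_x >= det$xmin & det$centroid_x <= det$xmax))
    expect_true(all(det$centroid_y >= det$ymin & det$centroid_y <= det$ymax))
  }
})

test_that("pinhole back-projection follows the camera geometry", {
  intr <- camera_intrinsics(fx = 600, fy = 600, cx = 320, cy = 240,
                            depth_scale = 0.001)
  p <- pixel_to_3d(320, 240, 500, intr)   # principal ray
  expect_equal(c(p$X, p$Y, p$Z), c(0, 0, 0.5))
  p2 <- pixel_to_3d(320 + 600, 240, 1000, intr)  # unit tangent
  expect_equal(c(p2$X, p2$Y, p2$Z), c(1, 0, 1))
  p0 <- pixel_to_3d(100, 100, 0, intr)
  expect_false(p0$valid)
  expect_true(is.na(p0$Z))
  expect_error(camera_intrinsics(-1, 600, 0, 0),
               class = "gojivision_invalid_argument")
})

test_that("the full fruit pipeline recovers unoccluded synthetic fruits", {
  sc <- generate_scene(scene_spec(width = 256L, height = 192L,
                                  branch = FALSE, seed = 42L))
  seg <- segment_fruits(sc$rgb)
  truth <- sc$truth$fruit_centroids
  expect_equal(nrow(seg$detections), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((seg$detections$centroid_x - truth$centroid_x[i])^2 +
                (seg$detections$centroid_y - truth$centroid_y[i])^2)
    expect_lt(min(d), 2)
  }
  # intermediates are retrievable
  expect_named(seg$stages,
               c("a_channel", "i_channel", "gray", "mask_raw",
                 "mask_opened", "mask_filtered"))
  # foreground never grows across opening and area filtering
  expect_lte(sum(seg$stages$mask_opened), sum(seg$stages$mask_raw))
  expect_lte(sum(seg$stages$mask_filtered), sum(seg$stages$mask_opened))
})

test_that("fruitless scenes and sub-threshold fruits give empty detections", {
  sc0 <- generate_scene(scene_spec(width = 128L, height = 96L, n_fruits = 0L,
                                   branch = FALSE, seed = 3L))
  seg0 <- segment_fruits(sc0$rgb)
  expect_equal(nrow(seg0$detections), 0L)

  # a single small fruit falls below the 100-px area filter
  sc1 <- generate_scene(scene_spec(width = 128L, height = 96L, n_fruits = 1L,
                                   fruit_radius_range = c(4, 4.5),
                                   branch = FALSE, impulse_noise_rate = 0,
                                   seed = 8L))
  expect_lt(sc1$truth$fruit_centroids$area[1], 100)
  seg1 <- segment_fruits(sc1$rgb)
  expect_equal(nrow(seg1$detections), 0L)
})

test_that("depth and intrinsics attach 3D coordinates to detections", {
  sc <- generate_scene(scene_spec(width = 192L, height = 160L,
                                  branch = FALSE, seed = 21L))
  intr <- camera_intrinsics(fx = 400, fy = 400, cx = 95.5, cy = 79.5)
  seg <- segment_fruits(sc$rgb, depth = sc$depth, intrinsics = intr)
  expect_true(all(c("depth", "X", "Y", "Z", "valid_3d") %in%
                    names(seg$detections)))
  expect_true(all(seg$detections$valid_3d))
  # fruits sit at the 200-300 mm working distance
  expect_true(all(seg$detections$Z >= 0.19 & seg$detections$Z <= 0.31))
  expect_error(
    segment_fruits(sc$rgb, depth = matrix(0, 2, 2)),
    class = "gojivision_dimension_error"
  )
})

test_that("tidy and glance summarize a fruit segmentation", {
  sc <- generate_scene(scene_spec(width = 192L, height = 160L,
                                  branch = FALSE, seed = 33L))
  seg <- segment_fruits(sc$rgb)
  td <- tidy(seg)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(seg$detections))
  gl <- glance(seg)
  expect_equal(gl$n_detections, nrow(td))
  expect_equal(gl$channel, "fused")
})
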