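test_that("Lloyd K-means recovers a flat-color partition exactly", {
  img <- array(0, c(12, 12, 3))
  img[1:4, , 1] <- 10
  img[5:8, , 2] <- 120
  img[9:12, , 3] <- 240
  truth <- rep(1:3, each = 4)[row(matrix(0, 12, 12))]
  km <- kmeans_cluster(img, k = 3, seed = 2)
  # labels match the ground-truth partition up to permutation
  tab <- table(km$labels, truth)
  expect_equal(sum(tab > 0), 3L)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(km$converged)
  # cross-check the achieved inertia against stats::kmeans
  ref <- stats::kmeans(matrix(img, 144, 3), centers = 3, nstart = 5)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("k = 1 yields the global mean and inertia is non-increasing", {
  set.seed(13)
  img <- array(runif(10 * 10 * 2), c(10, 10, 2))
  km1 <- kmeans_cluster(img, k = 1, seed = 1)
  expect_equal(as.numeric(km1$centers),
               c(mean(img[, , 1]), mean(img[, , 2])))
  km <- kmeans_cluster(img, k = 4, seed = 7)
  expect_true(all(diff(km$inertia_trace) <= 1e-9))
  expect_error(kmeans_cluster(img, k = 500),
               class = "gojivision_invalid_argument")
})

test_that("K-means is deterministic given the seed", {
  set.seed(1234)  # global RNG state must not leak in
  img <- array(runif(16 * 16 * 3, 0, 100), c(16, 16, 3))
  a <- kmeans_cluster(img, k = 4, seed = 99)
  set.seed(5678)
  b <- kmeans_cluster(img, k = 4, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("cluster_to_gray renders one level per cluster", {
  img <- array(0, c(9, 9, 3))
  img[1:3, , 1] <- 5; img[4:6, , 1] <- 100; img[7:9, , 1] <- 250
  km <- kmeans_cluster(img, k = 3, seed = 1)
  g <- cluster_to_gray(km)
  lv <- unique(as.numeric(g$values))
  expect_equal(length(lv), 3L)
  expect_true(all(g$values >= 0 & g$values <= 255))
  # pixels sharing a cluster share a level
  expect_equal(length(unique(as.numeric(g$values[1:3, ]))), 1L)
})

test_that("threshold_clusters keeps whole clusters on the dark side", {
  g <- feature_channel(matrix(c(rep(0, 30), rep(200, 70)), 10), "cluster_levels")
  m <- threshold_clusters(g)
  expect_equal(sum(m), 30L)
  expect_true(all(m == (g$values == 0)))
  mb <- threshold_clusters(g, polarity = "bright")
  expect_equal(mb, !m)
  # single-level image: nothing to split
  expect_true(all(threshold_clusters(feature_channel(matrix(5, 4, 4)))))
})

test_that("longest_region ranks by bounding-box height with documented ties", {
  m <- matrix(FALSE, 50, 40)
  m[2:11, 2:6] <- TRUE      # height 10
  m[1:40, 20:23] <- TRUE    # height 40
  r <- longest_region(m)
  expect_equal(r$bbox_height, 40L)
  expect_true(all(r$mask[1:40, 20:23]))
  expect_false(any(r$mask[2:11, 2:6]))

  single <- matrix(FALSE, 10, 10); single[3:7, 4] <- TRUE
  expect_equal(longest_region(single)$area, 5L)

  # height tie: larger area wins
  tie <- matrix(FALSE, 30, 30)
  tie[2:11, 2:5] <- TRUE    # height 10, area 40
  tie[15:24, 10:20] <- TRUE # height 10, area 110
  expect_equal(longest_region(tie)$area, 110L)

  expect_error(longest_region(matrix(FALSE, 4, 4)),
               class = "gojivision_no_region")
})

test_that("grip point is the centroid when on the branch, else the nearest pixel", {
  bar <- matrix(FALSE, 21, 21); bar[3:19, 10:12] <- TRUE
  gp <- locate_grip_point(longest_region(bar))
  expect_true(gp$on_centroid)
  expect_equal(gp$x, 10L)
  expect_equal(gp$y, 10L)

  # C-shape whose centroid falls in the cavity
  cs <- matrix(FALSE, 20, 20)
  cs[5:15, 5:7] <- TRUE
  cs[5:7, 8:15] <- TRUE
  cs[13:15, 8:15] <- TRUE
  reg <- longest_region(cs)
  gp2 <- locate_grip_point(reg)
  cen <- oracle_centroid(cs)
  if (!cs[round(cen[["y"]]) + 1, round(cen[["x"]]) + 1]) {
    expect_false(gp2$on_centroid)
  }
  near <- oracle_nearest_fg(cs, cen[["x"]], cen[["y"]])
  expect_equal(c(gp2$x, gp2$y), as.integer(near))
  expect_true(cs[gp2$y + 1, gp2$x + 1])

  # single-pixel region
  px1 <- matrix(FALSE, 5, 5); px1[3, 2] <- TRUE
  gp3 <- locate_grip_point(longest_region(px1))
  expect_equal(c(gp3$x, gp3$y), c(1L, 2L))
})

test_that("the branch pipeline grips the synthetic branch", {
  sc <- generate_scene(scene_spec(width = 256L, height = 192L, seed = 5L))
  sb <- segment_branch(sc$rgb, depth = sc$depth,
                       intrinsics = camera_intrinsics(400, 400, 127.5, 95.5))
  gp <- sb$grip_point
  # hard invariant: the grip point is a foreground pixel of the final mask
  expect_true(sb$region$mask[gp$y + 1L, gp$x + 1L])
  expect_true(sc$truth$branch_mask[gp$y + 1L, gp$x + 1L])
  expect_true(gp$depth >= 200 && gp$depth <= 310)
  expect_true(gp$point3d$valid)
  # the grip point sits within 3 px of the analytic midline laterally
  mid <- sc$truth$branch_midline
  expect_lt(abs(gp$x - mid[gp$y + 1L, "x"]), 5)
  gl <- glance(sb)
  expect_true(gl$kmeans_converged)
})

test_that("scenes without branch-like pixels raise a no-region error", {
  sc <- generate_scene(scene_spec(width = 96L, height = 96L, n_fruits = 0L,
                                  branch = FALSE, texture_sd = 0,
                                  impulse_noise_rate = 0, seed = 2L))
  expect_error(segment_branch(sc$rgb), class = "gojivision_no_region")
})
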