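# Branch segmentation: K-means clustering in Lab space, histogram
# thresholding of the clustered image, longest-region selection, median
# filtering + opening, and gripping-point localization.

#' K-means clustering of a pixel feature image (Lloyd's algorithm)
#'
#' Implements the four Lloyd steps directly: (1) seeded random selection of
#' k distinct pixels as initial centers, (2) nearest-center assignment by
#' Euclidean distance, (3) mean update of each center, (4) repeat until the
#' assignment is unchanged, the centers move less than `tol`, or `max_iter`
#' is reached. Empty clusters are re-seeded from the point farthest from
#' its assigned center. The inertia (within-cluster sum of squares) is
#' recorded after every iteration and is non-increasing.
#'
#' @param features `H x W x d` numeric array (or `H x W` matrix for d = 1).
#' @param k number of clusters (1 <= k <= number of pixels).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 300).
#' @param tol center-movement stopping tolerance (default 1e-4).
#' @param init `"random"` (sample k pixels, default) or `"plusplus"`
#'   (distance-weighted seeding).
#' @return A `pixel_kmeans` object: list with `k`, `centers` (`k x d`),
#'   `labels` (`H x W` integer matrix, values `1..k`), `inertia`,
#'   `inertia_trace`, `iterations`, `converged`.
#' @export
kmeans_cluster <- function(features, k, seed = 1L, max_iter = 300L,
                           tol = 1e-4, init = c("random", "plusplus")) {
  init <- match.arg(init)
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  stopifnot(is.array(features), length(dim(features)) == 3L)
  h <- dim(features)[1]; w <- dim(features)[2]; d <- dim(features)[3]
  n <- h * w
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop_goji(sprintf("`k` must be in [1, %d]", n), "gojivision_invalid_argument")
  }
  X <- matrix(features, n, d)

  res <- withr::with_seed(as.integer(seed), {
    centers <- if (init == "random") {
      X[sample.int(n, k), , drop = FALSE]
    } else {
      kmeanspp_init(X, k)
    }
    xsq <- rowSums(X^2)
    labels <- integer(n)
    inertia_trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # squared distances to every center via the expansion trick
      d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
      new_labels <- max.col(-d2, ties.method = "first")
      assigned_d2 <- d2[cbind(seq_len(n), new_labels)]
      # re-seed empty clusters from the farthest point *before* the mean
      # update, so every step of the iteration lowers the objective
      for (j in which(tabulate(new_labels, nbins = k) == 0L)) {
        far <- which.max(assigned_d2)
        new_labels[far] <- j
        assigned_d2[far] <- -Inf  # never reseed two clusters from one point
      }
      new_centers <- centers
      for (j in seq_len(k)) {
        new_centers[j, ] <- colMeans(X[new_labels == j, , drop = FALSE])
      }
      moved <- sqrt(max(rowSums((new_centers - centers)^2)))
      assignments_stable <- iter > 1L && identical(new_labels, labels)
      centers <- new_centers
      labels <- new_labels
      inertia_trace <- c(inertia_trace,
                         sum((X - centers[labels, , drop = FALSE])^2))
      if (assignments_stable || moved < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
    }
    list(centers = centers, labels = labels, inertia_trace = inertia_trace,
         iterations = iter, converged = converged)
  })

  structure(
    list(k = k, centers = res$centers,
         labels = matrix(res$labels, h, w),
         inertia = res$inertia_trace[length(res$inertia_trace)],
         inertia_trace = res$inertia_trace,
         iterations = res$iterations, converged = res$converged,
         feature_dim = d),
    class = "pixel_kmeans"
  )
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- rep(Inf, n)
    for (c in seq_len(nrow(centers))) {
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c, ])^2))
    }
    s <- sum(d2)
    pick <- if (s > 0) sample.int(n, 1L, prob = d2 / s) else sample.int(n, 1L)
    centers <- rbind(centers, X[pick, , drop = FALSE])
  }
  centers
}

#' @export
print.pixel_kmeans <- function(x, ...) {
  cat(sprintf("<pixel_kmeans> k = %d, inertia %.4g after %d iteration(s)%s\n",
              x$k, x$inertia, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x a `pixel_kmeans` object.
#' @param ... unused.
#' @export
tidy.pixel_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = as.integer(tabulate(x$labels, nbins = x$k)),
    center = lapply(seq_len(x$k), function(i) x$centers[i, ])
  )
}

#' @rdname kmeans_cluster
#' @export
glance.pixel_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, iterations = x$iterations,
                 converged = x$converged)
}

#' Render a clustered image as a k-level gray plane
#'
#' Replaces every pixel by a scalar rendering of its cluster center — the
#' center's first component (L* when clustering on Lab) or, for feature
#' spaces without a lightness axis, the mean of the center's components —
#' then min-max rescales the k levels onto \[0, 255\]. The result has at
#' most k distinct gray levels, so its histogram is a set of spikes that
#' valley thresholding can split.
#'
#' @param model a [kmeans_cluster()] result.
#' @param use_first_component render by the center's first feature (default
#'   `TRUE`); otherwise by the mean of all features.
#' @return A `feature_channel` with at most k distinct values in
#'   \[0, 255\].
#' @export
cluster_to_gray <- function(model, use_first_component = TRUE) {
  stopifnot(inherits(model, "pixel_kmeans"))
  level <- if (use_first_component && model$feature_dim >= 1L) {
    model$centers[, 1]
  } else {
    rowMeans(model$centers)
  }
  # guard against amplifying float noise between effectively equal centers
  level <- if (diff(range(level)) > 1e-8) rescale_to_u8(level) else level * 0
  feature_channel(matrix(level[model$labels], nrow(model$labels)),
                  source = "cluster_levels")
}

#' Select branch-like clusters by histogram thresholding
#'
#' Splits the k-level clustered gray image at its histogram valley and
#' keeps the level group on the configured side: `polarity = "dark"`
#' (default) selects the levels at or below the valley — dark branches
#' against brighter foliage — so whole clusters are kept or dropped, never
#' split. The histogram of a k-level image is a set of spikes, so smooth
#' peak/valley detection degenerates; instead, levels carrying fewer than
#' `min_level_fraction` of the pixels are set aside (isolated-noise
#' clusters cannot form a mode), and the remaining levels are divided into
#' a dark and a bright group at the split minimizing the within-group
#' variance of the level values. The threshold is the midpoint between the
#' two groups; whole clusters are kept or dropped, never split. A
#' single-level image returns an all-foreground mask.
#'
#' @param gray a [cluster_to_gray()] result.
#' @param polarity `"dark"` (default) or `"bright"`.
#' @param min_level_fraction smallest pixel share for a level to count as
#'   a substantive mode (default 0.005).
#' @return Logical mask.
#' @export
threshold_clusters <- function(gray, polarity = c("dark", "bright"),
                               min_level_fraction = 0.005) {
  polarity <- match.arg(polarity)
  v <- as_channel_matrix(gray)
  vals <- as.numeric(v)
  tab <- table(vals)
  levels <- as.numeric(names(tab))
  counts <- as.numeric(tab)
  keep <- counts >= min_level_fraction * length(vals)
  lv <- if (any(keep)) levels[keep] else levels
  if (length(lv) < 2L) {
    return(matrix(TRUE, nrow(v), ncol(v)))
  }
  # best split of the sorted levels into two contiguous groups by
  # within-group sum of squares
  ss <- function(x) if (length(x) < 2L) 0 else sum((x - mean(x))^2)
  tot <- vapply(seq_len(length(lv) - 1L), function(s) {
    ss(lv[1:s]) + ss(lv[(s + 1L):length(lv)])
  }, numeric(1))
  s <- which.min(tot)
  t <- (lv[s] + lv[s + 1L]) / 2
  if (polarity == "dark") v <= t else v > t
}

#' Longest region of a mask
#'
#' Returns the 8-connected component whose bounding-rectangle height (row
#' extent) is maximal — the method's notion of "longest", suited to
#' predominantly vertical branches. Ties break by larger area, then by
#' smaller top-row index.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return A `branch_region`: list with `mask` (single-component logical
#'   matrix), `bbox_height`, `area`, and `centroid` (`c(x, y)`, 0-based).
#' @export
longest_region <- function(mask) {
  m <- as_mask(mask)
  st <- component_stats(m)
  if (nrow(st) == 0L) {
    stop_goji("mask has no foreground component", "gojivision_no_region")
  }
  ord <- order(-st$bbox_height, -st$area, st$ymin)
  pick <- st[ord[1], ]
  lab <- label_components(m)
  structure(
    list(mask = lab == pick$component & lab > 0L,
         bbox_height = pick$bbox_height,
         area = pick$area,
         centroid = c(x = pick$centroid_x, y = pick$centroid_y)),
    class = "branch_region"
  )
}

#' @export
print.branch_region <- function(x, ...) {
  cat(sprintf(
    "<branch_region> area %d px, bbox height %d, centroid (%.1f, %.1f)\n",
    x$area, x$bbox_height, x$centroid[["x"]], x$centroid[["y"]]))
  invisible(x)
}

#' Locate the gripping point on a branch region
#'
#' The region's first-moment centroid, rounded to the nearest pixel, is the
#' gripping point when it lands on the branch (`on_centroid = TRUE`);
#' otherwise the foreground pixel closest (Euclidean) to the unrounded
#' centroid is chosen, ties broken by smaller y then smaller x. With a
#' depth map (and optionally intrinsics) the depth value and 3D camera
#' coordinates are attached.
#'
#' @param region a [longest_region()] result (or logical mask).
#' @param depth optional depth matrix.
#' @param intrinsics optional [camera_intrinsics()].
#' @return A `grip_point`: list with integer pixel coordinates `x`, `y`
#'   (0-based), `on_centroid`, and optionally `depth` and `point3d`.
#' @export
locate_grip_point <- function(region, depth = NULL, intrinsics = NULL) {
  if (!inherits(region, "branch_region")) region <- longest_region(region)
  m <- region$mask
  cx <- region$centroid[["x"]]; cy <- region$centroid[["y"]]
  xi <- as.integer(round(cx)); yi <- as.integer(round(cy))
  on_centroid <- xi >= 0L && yi >= 0L && xi < ncol(m) && yi < nrow(m) &&
    m[yi + 1L, xi + 1L]
  if (!on_centroid) {
    sel <- which(m)
    ys <- (sel - 1L) %% nrow(m)
    xs <- (sel - 1L) %/% nrow(m)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    best <- order(d2, ys, xs)[1]
    xi <- as.integer(xs[best]); yi <- as.integer(ys[best])
  }
  gp <- list(x = xi, y = yi, on_centroid = on_centroid,
             depth = NULL, point3d = NULL)
  if (!is.null(depth)) {
    gp$depth <- depth_at(depth, xi, yi)
    if (!is.null(intrinsics)) {
      gp$point3d <- pixel_to_3d(xi, yi, gp$depth, intrinsics)
    }
  }
  structure(gp, class = "grip_point")
}

#' @export
print.grip_point <- function(x, ...) {
  cat(sprintf("<grip_point> (%d, %d)%s%s\n", x$x, x$y,
              if (x$on_centroid) " at centroid" else " nearest to centroid",
              if (!is.null(x$depth)) sprintf(", depth %g", x$depth) else ""))
  invisible(x)
}

#' Segment the branch and locate its gripping point
#'
#' Full branch pipeline: Lab conversion, K-means clustering (K = 8 by
#' default), k-level gray rendering, histogram thresholding (dark polarity
#' by default), longest-region selection, median filtering (window 3),
#' morphological opening (2x2 kernel), longest-region selection again, and
#' gripping-point localization.
#'
#' @inheritParams segment_fruits
#' @return A `branch_segmentation` object: list with `grip_point`,
#'   `region` (the final `branch_region`), `kmeans` (the fitted
#'   `pixel_kmeans`), `stages`, `config`, and `report`. Raises a
#'   `gojivision_no_region` error when no branch-like region survives.
#' @export
segment_branch <- function(rgb, depth = NULL, intrinsics = NULL,
                           config = pipeline_config(),
                           keep_intermediates = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  px <- as_rgb_array(rgb)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  lab <- rgb_to_lab(px)
  features <- if (config$kmeans_features == "lab") {
    array(c(lab$L, lab$a, lab$b_star), c(dim(lab$L), 3L))
  } else {
    array(c(lab$a, lab$b_star), c(dim(lab$L), 2L))
  }
  tick("lab_conversion")

  km <- kmeans_cluster(features, k = config$k, seed = config$seed,
                       max_iter = config$kmeans_max_iter,
                       tol = config$kmeans_tol, init = config$kmeans_init)
  gray <- cluster_to_gray(km,
                          use_first_component = config$kmeans_features == "lab")
  tick("kmeans")

  cluster_mask <- threshold_clusters(gray, polarity = config$branch_polarity)
  if (mean(cluster_mask) > 0.9) {
    # a branch is a minority structure; a "dark group" covering nearly the
    # whole frame means there is no branch-background contrast to segment
    stop_goji("no branch-like minority cluster group in the image",
              "gojivision_no_region")
  }
  region1 <- longest_region(cluster_mask)
  tick("cluster_threshold")

  cleaned <- median_filter(region1$mask, config$median_window)
  opened <- morphological_open(cleaned, config$branch_kernel)
  if (!any(opened)) {
    stop_goji("no branch region survives median filtering and opening",
              "gojivision_no_region")
  }
  region <- longest_region(opened)
  grip <- locate_grip_point(region, depth, intrinsics)
  tick("refine_and_grip")

  stages <- if (keep_intermediates) {
    list(cluster_gray = gray, cluster_mask = cluster_mask,
         longest_raw = region1$mask, median_filtered = cleaned,
         opened = opened, final_mask = region$mask)
  } else {
    list()
  }
  structure(
    list(grip_point = grip, region = region, kmeans = km, stages = stages,
         config = config,
         report = run_report(
           stage_timings = timings,
           flags = list(kmeans_converged = km$converged,
                        kmeans_iterations = km$iterations),
           input_digest = content_fingerprint(px),
           seed = config$seed
         )),
    class = "branch_segmentation"
  )
}

#' @export
print.branch_segmentation <- function(x, ...) {
  cat(sprintf("<branch_segmentation> region %d px (height %d), grip (%d, %d)\n",
              x$region$area, x$region$bbox_height,
              x$grip_point$x, x$grip_point$y))
  invisible(x)
}

#' @rdname segment_branch
#' @param x a `branch_segmentation` object.
#' @param ... unused.
#' @export
tidy.branch_segmentation <- function(x, ...) {
  gp <- x$grip_point
  out <- tibble::tibble(
    grip_x = gp$x, grip_y = gp$y, on_centroid = gp$on_centroid,
    region_area = x$region$area, region_height = x$region$bbox_height,
    centroid_x = x$region$centroid[["x"]],
    centroid_y = x$region$centroid[["y"]]
  )
  if (!is.null(gp$depth)) out$depth <- gp$depth
  if (!is.null(gp$point3d)) {
    out$X <- gp$point3d$X; out$Y <- gp$point3d$Y; out$Z <- gp$point3d$Z
  }
  out
}

#' @rdname segment_branch
#' @export
glance.branch_segmentation <- function(x, ...) {
  tibble::tibble(
    region_area = x$region$area,
    region_height = x$region$bbox_height,
    on_centroid = x$grip_point$on_centroid,
    kmeans_inertia = x$kmeans$inertia,
    kmeans_iterations = x$kmeans$iterations,
    kmeans_converged = x$kmeans$converged
  )
}
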