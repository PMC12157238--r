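# Seeded synthetic orchard scenes with ground truth.
#
# The generator emulates the acquisition conditions the pipelines are
# designed for: close-range (20-30 cm) 640 x 480 views of red elliptical
# wolfberry fruits against green foliage, an elongated dark branch crossing
# the frame, a bright sky band behind the upper canopy, a multiplicative
# illumination gradient standing in for front/back/side/cloudy lighting,
# foliage-colored occlusion patches over fruit borders, and salt-and-pepper
# impulse noise. Ground truth (per-fruit masks and centroids, branch mask
# and midline, depth) is recorded before occlusion, illumination and noise
# are applied.

#' Synthetic scene specification
#'
#' All knobs of the scene generator with field-realistic defaults: ripe
#' wolfberries are deep red, foliage mid-green, branches grey-brown, and the
#' camera resolution matches the acquisition setup (640 x 480). Every scene
#' is fully determined by its `seed`.
#'
#' @param width,height image size in pixels (default 640 x 480).
#' @param n_fruits number of fruits to place (default 5).
#' @param fruit_radius_range min/max semi-major axis of the fruit ellipses,
#'   pixels.
#' @param fruit_color,foliage_color,branch_color,sky_color RGB triples
#'   (0-255).
#' @param color_jitter half-width of the uniform per-object color jitter.
#' @param texture_sd per-pixel Gaussian mottle of the foliage, gray levels.
#' @param sky_fraction fraction of the image height occupied by sky at the
#'   top (fruits are placed below it). Default 0: at the 20-30 cm working
#'   distance the frame is filled by the canopy.
#' @param branch logical: draw a branch.
#' @param branch_width stroke width of the branch, pixels.
#' @param branch_angle tilt of the branch from vertical, radians.
#' @param branch_curvature lateral bow of the branch as a fraction of the
#'   image width.
#' @param illumination_strength gradient amplitude in \[0, 1\] (0 = flat
#'   "cloudy" light).
#' @param illumination_direction gradient direction, radians (0 = brightens
#'   to the right).
#' @param occlusion_fraction target fraction of each fruit's pixels covered
#'   by a foliage-colored patch, in \[0, 1\].
#' @param impulse_noise_rate fraction of pixels replaced by salt/pepper
#'   impulses, in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width = 640L, height = 480L, n_fruits = 5L,
                       fruit_radius_range = c(10, 18),
                       fruit_color = c(196, 30, 40),
                       foliage_color = c(64, 115, 48),
                       branch_color = c(101, 72, 47),
                       sky_color = c(190, 205, 225),
                       color_jitter = 12, texture_sd = 6,
                       sky_fraction = 0,
                       branch = TRUE, branch_width = 9,
                       branch_angle = 0.08, branch_curvature = 0.06,
                       illumination_strength = 0.25,
                       illumination_direction = 0,
                       occlusion_fraction = 0,
                       impulse_noise_rate = 0.005,
                       seed = 1L) {
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    n_fruits = as.integer(n_fruits),
    fruit_radius_range = as.numeric(fruit_radius_range),
    fruit_color = as.numeric(fruit_color),
    foliage_color = as.numeric(foliage_color),
    branch_color = as.numeric(branch_color),
    sky_color = as.numeric(sky_color),
    color_jitter = color_jitter, texture_sd = texture_sd,
    sky_fraction = sky_fraction,
    branch = isTRUE(branch), branch_width = branch_width,
    branch_angle = branch_angle, branch_curvature = branch_curvature,
    illumination_strength = illumination_strength,
    illumination_direction = illumination_direction,
    occlusion_fraction = occlusion_fraction,
    impulse_noise_rate = impulse_noise_rate,
    seed = as.integer(seed)
  )
  with(spec, {
    if (width < 16L || height < 16L)
      stop_goji("scene must be at least 16 x 16 px", "gojivision_invalid_argument")
    if (n_fruits < 0L)
      stop_goji("`n_fruits` must be >= 0", "gojivision_invalid_argument")
    if (any(fruit_radius_range <= 0) || diff(fruit_radius_range) < 0)
      stop_goji("`fruit_radius_range` must be positive and ordered",
                "gojivision_invalid_argument")
    for (f in c(occlusion_fraction, impulse_noise_rate,
                illumination_strength, sky_fraction)) {
      if (f < 0 || f > 1)
        stop_goji("fractions must lie in [0, 1]", "gojivision_invalid_argument")
    }
  })
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d, %d fruit(s)%s, illum %.2f @ %.2f rad, occl %.2f, noise %.3f, seed %d\n",
    x$width, x$height, x$n_fruits, if (x$branch) " + branch" else "",
    x$illumination_strength, x$illumination_direction,
    x$occlusion_fraction, x$impulse_noise_rate, x$seed))
  invisible(x)
}

jitter_color <- function(base, jitter) {
  clamp(base + runif(3, -jitter, jitter), 0, 255)
}

# ellipse coverage field: <= 1 inside; alpha blends a ~1 px soft rim
ellipse_field <- function(xg, yg, cx, cy, a, b, theta) {
  dx <- xg - cx; dy <- yg - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sqrt(u^2 + v^2)
}

#' Generate a synthetic orchard scene
#'
#' Deterministically renders the scene described by a [scene_spec()]:
#' sky band, mottled foliage, optional branch, anti-aliased elliptical
#' fruits, then (in order) occlusion patches, the illumination gradient and
#' impulse noise. Ground truth is recorded before the three corruptions.
#'
#' @param spec a [scene_spec()].
#' @return A `synthetic_scene`: list with `rgb` (an [rgb_image()]), `depth`
#'   (`H x W` matrix, depth units = mm), `truth` (list: `fruit_centroids`
#'   tibble, `fruit_masks` list of logical matrices, `branch_mask`,
#'   `branch_midline` two-column x/y matrix, `depth`), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  # the chroma contrast the fruit pipeline relies on must hold by design
  a_fruit <- extract_feature_channel(
    array(spec$fruit_color, c(1, 1, 3)), "a_channel")$values[1, 1]
  a_foliage <- extract_feature_channel(
    array(spec$foliage_color, c(1, 1, 3)), "a_channel")$values[1, 1]
  if (a_fruit <= a_foliage) {
    stop_goji("scene colors violate the a*(fruit) > a*(foliage) contract",
              "gojivision_invalid_argument")
  }
  withr::with_seed(spec$seed, render_scene(spec))
}

render_scene <- function(spec) {
  h <- spec$height; w <- spec$width
  xg <- matrix(rep(0:(w - 1L), each = h), h, w)   # x = column, 0-based
  yg <- matrix(rep(0:(h - 1L), times = w), h, w)  # y = row, 0-based

  img <- array(0, c(h, w, 3))
  sky_rows <- max(0L, as.integer(round(spec$sky_fraction * h)))
  mottle <- matrix(rnorm(h * w, 0, spec$texture_sd), h, w)
  for (k in 1:3) {
    plane <- matrix(spec$foliage_color[k], h, w)
    if (sky_rows > 0L) plane[seq_len(sky_rows), ] <- spec$sky_color[k]
    img[, , k] <- plane + mottle
  }

  depth <- matrix(500 + (1500 - 500) * (yg / max(h - 1L, 1L)), h, w)

  # ---- branch ------------------------------------------------------------
  branch_mask <- matrix(FALSE, h, w)
  branch_midline <- NULL
  if (spec$branch) {
    x0 <- runif(1, 0.3, 0.7) * (w - 1L)
    ys <- 0:(h - 1L)
    t <- ys / max(h - 1L, 1L) - 0.5
    xline <- x0 + tan(spec$branch_angle) * (ys - (h - 1) / 2) +
      spec$branch_curvature * w * (t^2 - 0.25) * 4
    branch_midline <- cbind(x = xline, y = ys)
    halfw <- spec$branch_width / 2
    branch_mask <- abs(xg - matrix(xline, h, w)) <= halfw
    bcol <- jitter_color(spec$branch_color, spec$color_jitter)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[branch_mask] <- bcol[k] + mottle[branch_mask] * 0.5
      img[, , k] <- plane
    }
    bdepth <- runif(1, 200, 300)
    depth[branch_mask] <- bdepth + 0.05 * (yg[branch_mask] - h / 2)
  }

  # ---- fruits ------------------------------------------------------------
  fruit_masks <- list()
  centroids_x <- numeric(0); centroids_y <- numeric(0)
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, bounding radius
  if (spec$n_fruits > 0L) {
    rr <- spec$fruit_radius_range
    y_lo <- sky_rows + rr[2] + 2
    y_hi <- h - 1 - rr[2] - 2
    x_lo <- rr[2] + 2
    x_hi <- w - 1 - rr[2] - 2
    if (y_hi <= y_lo || x_hi <= x_lo) {
      stop_goji("scene too small to place fruits of the requested size",
                "gojivision_placement_error")
    }
    for (i in seq_len(spec$n_fruits)) {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        a <- runif(1, rr[1], rr[2])
        b <- a * runif(1, 0.72, 1)
        theta <- runif(1, 0, pi)
        cx <- runif(1, x_lo, x_hi)
        cy <- runif(1, y_lo, y_hi)
        if (nrow(placed) > 0) {
          gap <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) -
            (placed[, 3] + a)
          if (min(gap) < 8) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_goji(sprintf("could not place fruit %d after 200 attempts", i),
                  "gojivision_placement_error")
      }
      placed <- rbind(placed, c(cx, cy, a))
      e <- ellipse_field(xg, yg, cx, cy, a, b, theta)
      mask <- e <= 1
      alpha <- clamp(0.5 + (1 - e) * min(a, b), 0, 1)
      fcol <- jitter_color(spec$fruit_color, spec$color_jitter)
      for (k in 1:3) {
        img[, , k] <- img[, , k] * (1 - alpha) + fcol[k] * alpha
      }
      fdepth <- runif(1, 200, 300)
      depth[mask] <- fdepth + (e[mask] - 0.5) * 4  # gentle bulge
      fruit_masks[[i]] <- mask
      centroids_x <- c(centroids_x, mean(xg[mask]))
      centroids_y <- c(centroids_y, mean(yg[mask]))
    }
  }

  truth <- list(
    fruit_centroids = tibble::tibble(
      fruit = seq_along(fruit_masks),
      centroid_x = centroids_x, centroid_y = centroids_y,
      area = vapply(fruit_masks, sum, integer(1))
    ),
    fruit_masks = fruit_masks,
    branch_mask = branch_mask,
    branch_midline = branch_midline,
    depth = depth
  )

  # ---- occlusion patches (image only; truth stays intact) ----------------
  if (spec$occlusion_fraction > 0 && length(fruit_masks) > 0) {
    for (i in seq_along(fruit_masks)) {
      mask <- fruit_masks[[i]]
      target <- spec$occlusion_fraction * sum(mask)
      # pick a boundary point of the fruit as the patch center
      sel <- which(mask)
      bx <- placed[i, 1] + placed[i, 3] * cos(runif(1, 0, 2 * pi)) * 0.9
      by <- placed[i, 2] + placed[i, 3] * sin(runif(1, 0, 2 * pi)) * 0.9
      pr <- placed[i, 3] * 0.4
      pcol <- jitter_color(spec$foliage_color, spec$color_jitter)
      for (grow in seq_len(12L)) {
        pf <- ellipse_field(xg, yg, bx, by, pr, pr * 0.8, runif(1, 0, pi))
        patch <- (abs(pf))^1.6 <= 1  # superellipse-like rounded patch
        if (sum(patch & mask) >= target || grow == 12L) {
          for (k in 1:3) {
            plane <- img[, , k]
            plane[patch] <- pcol[k] + mottle[patch]
            img[, , k] <- plane
          }
          break
        }
        pr <- pr * 1.25
      }
    }
  }

  # ---- illumination gradient ---------------------------------------------
  if (spec$illumination_strength > 0) {
    u <- ((xg - (w - 1) / 2) * cos(spec$illumination_direction) +
            (yg - (h - 1) / 2) * sin(spec$illumination_direction))
    u <- u / max(abs(u))
    gain <- 1 + spec$illumination_strength * u
    for (k in 1:3) img[, , k] <- img[, , k] * gain
  }

  # ---- impulse noise ------------------------------------------------------
  img <- clamp(img, 0, 255)
  if (spec$impulse_noise_rate > 0) {
    n_imp <- round(spec$impulse_noise_rate * h * w)
    if (n_imp > 0) {
      sel <- sample.int(h * w, n_imp)
      val <- sample(c(0, 255), n_imp, replace = TRUE)
      for (k in 1:3) {
        plane <- img[, , k]
        plane[sel] <- val
        img[, , k] <- plane
      }
    }
  }

  structure(
    list(rgb = rgb_image(img), depth = depth, truth = truth, spec = spec),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, %d fruit(s)%s, seed %d\n",
              x$spec$height, x$spec$width,
              length(x$truth$fruit_masks),
              if (x$spec$branch) " + branch" else "", x$spec$seed))
  invisible(x)
}

#' Battery of scene specifications over lighting and occlusion conditions
#'
#' Produces `n_scenes` deterministic [scene_spec()]s cycling through four
#' lighting analogues (front-lit, backlit, side-lit, cloudy) and the given
#' occlusion fractions, with per-scene seeds derived from `seed`. Scenes
#' are described, not rendered; pass each spec to [generate_scene()].
#'
#' @param n_scenes number of scenes (>= 1).
#' @param base_spec a [scene_spec()] providing all other parameters.
#' @param seed battery seed; scene i uses `seed + i`.
#' @param occlusion_grid occlusion fractions to cycle through (default
#'   `c(0, 0.1, 0.25)`).
#' @return A list of `scene_spec` objects with attribute `conditions`
#'   (tibble of per-scene lighting/occlusion settings).
#' @export
scene_battery <- function(n_scenes, base_spec = scene_spec(), seed = 1L,
                          occlusion_grid = c(0, 0.1, 0.25)) {
  n_scenes <- as.integer(n_scenes)
  if (n_scenes < 1L) {
    stop_goji("`n_scenes` must be >= 1", "gojivision_invalid_argument")
  }
  lighting <- list(
    front  = list(strength = 0.35, direction = 0),
    back   = list(strength = 0.50, direction = pi),
    side   = list(strength = 0.35, direction = pi / 2),
    cloudy = list(strength = 0.08, direction = 0)
  )
  specs <- vector("list", n_scenes)
  cond <- tibble::tibble(scene = integer(0), lighting = character(0),
                         occlusion = numeric(0), seed = integer(0))
  for (i in seq_len(n_scenes)) {
    li <- ((i - 1L) %% length(lighting)) + 1L
    oi <- (((i - 1L) %/% length(lighting)) %% length(occlusion_grid)) + 1L
    s <- unclass(base_spec)
    s$illumination_strength <- lighting[[li]]$strength
    s$illumination_direction <- lighting[[li]]$direction
    s$occlusion_fraction <- occlusion_grid[oi]
    s$seed <- as.integer(seed + i)
    specs[[i]] <- do.call(scene_spec, s)
    cond <- rbind(cond, tibble::tibble(
      scene = i, lighting = names(lighting)[li],
      occlusion = occlusion_grid[oi], seed = s$seed))
  }
  attr(specs, "conditions") <- cond
  specs
}
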