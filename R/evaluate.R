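# Battery evaluation: run a pipeline over synthetic scenes and score it
# against the recorded ground truth.

match_centroids <- function(detected, truth, tol) {
  # greedy nearest matching, each truth fruit matched at most once
  if (nrow(truth) == 0L) return(0L)
  if (nrow(detected) == 0L) return(0L)
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  errors <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected$centroid_x - truth$centroid_x[i])^2 +
                (detected$centroid_y - truth$centroid_y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
      errors <- c(errors, d[j])
    }
  }
  attr(matched, "errors") <- errors
  matched
}

#' Evaluate the fruit pipeline on a scene battery
#'
#' Generates each scene, runs [segment_fruits()] with the requested feature
#' channel, and scores detections against the ground truth by greedy
#' nearest-centroid matching within `match_tol` pixels.
#'
#' @param specs list of [scene_spec()]s (e.g. from [scene_battery()]).
#' @param channel `"fused"`, `"a_channel"` or `"i_channel"`.
#' @param config a [pipeline_config()].
#' @param match_tol centroid matching tolerance, pixels (default 5).
#' @return A tibble with one row per scene: `scene`, `seed`, `n_true`,
#'   `n_detected`, `n_matched`, `recall`, `count_exact`,
#'   `mean_centroid_error`, `threshold_method`.
#' @export
evaluate_fruit_battery <- function(specs, channel = "fused",
                                   config = pipeline_config(),
                                   match_tol = 5) {
  rows <- lapply(seq_along(specs), function(i) {
    sc <- generate_scene(specs[[i]])
    seg <- segment_fruits(sc$rgb, config = config, channel = channel,
                          keep_intermediates = FALSE)
    truth <- sc$truth$fruit_centroids
    m <- match_centroids(seg$detections, truth, match_tol)
    errs <- attr(m, "errors")
    tibble::tibble(
      scene = i, seed = specs[[i]]$seed,
      n_true = nrow(truth), n_detected = nrow(seg$detections),
      n_matched = as.integer(m),
      recall = if (nrow(truth) > 0) as.integer(m) / nrow(truth) else NA_real_,
      count_exact = nrow(seg$detections) == nrow(truth),
      mean_centroid_error = if (length(errs) > 0) mean(errs) else NA_real_,
      threshold_method = seg$threshold$method
    )
  })
  do.call(rbind, rows)
}

#' Evaluate the branch pipeline on a scene battery
#'
#' Generates each scene, runs [segment_branch()], and checks the hard
#' invariant (grip point on the final mask) and the accuracy property (grip
#' point on the ground-truth branch mask). Scenes where no branch-like
#' region survives are recorded as failures rather than raising.
#'
#' @param specs list of [scene_spec()]s.
#' @param config a [pipeline_config()].
#' @return A tibble with one row per scene: `scene`, `seed`, `found`,
#'   `on_mask`, `on_truth`, `on_centroid`, `inertia_monotone`,
#'   `kmeans_iterations`.
#' @export
evaluate_branch_battery <- function(specs, config = pipeline_config()) {
  rows <- lapply(seq_along(specs), function(i) {
    sc <- generate_scene(specs[[i]])
    seg <- tryCatch(
      segment_branch(sc$rgb, config = config, keep_intermediates = TRUE),
      gojivision_no_region = function(e) NULL
    )
    if (is.null(seg)) {
      return(tibble::tibble(
        scene = i, seed = specs[[i]]$seed, found = FALSE,
        on_mask = NA, on_truth = NA, on_centroid = NA,
        inertia_monotone = NA, kmeans_iterations = NA_integer_
      ))
    }
    gp <- seg$grip_point
    tibble::tibble(
      scene = i, seed = specs[[i]]$seed, found = TRUE,
      on_mask = seg$region$mask[gp$y + 1L, gp$x + 1L],
      on_truth = sc$truth$branch_mask[gp$y + 1L, gp$x + 1L],
      on_centroid = gp$on_centroid,
      inertia_monotone = !is.unsorted(rev(seg$kmeans$inertia_trace)),
      kmeans_iterations = seg$kmeans$iterations
    )
  })
  do.call(rbind, rows)
}
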