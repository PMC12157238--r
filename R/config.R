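# Pipeline configuration: every tunable with its default, YAML load/save
# with strict key validation.

.CONFIG_DEFAULTS <- list(
  wavelet = "db2",          # wavelet family for the fusion transform
  levels = 3L,              # decomposition levels
  alpha = 0.5,              # weight of the a-channel approximation
  beta = 0.5,               # weight of the I-channel approximation
  min_area = 100L,          # smallest surviving fruit component, px
  fruit_kernel = 3L,        # opening kernel side for the fruit stage
  branch_kernel = 2L,       # opening kernel side for the branch stage
  median_window = 3L,       # median filter window for the branch mask
  k = 8L,                   # K-means cluster count
  kmeans_max_iter = 300L,
  kmeans_tol = 1e-4,        # center-movement stopping tolerance
  kmeans_features = "lab",  # "lab" (L, a*, b*) or "ab" (chroma only)
  kmeans_init = "random",   # "random" (sample k pixels) or "plusplus"
  fruit_polarity = "bright",   # fruit gray values sit above the threshold
  branch_polarity = "dark",    # branch cluster levels sit below it
  hist_smooth = 5L,         # histogram moving-average width, bins
  seed = 1L                 # RNG seed (K-means initialization)
)

#' Pipeline configuration
#'
#' Builds a validated configuration holding every tunable of the fruit and
#' branch pipelines, with defaults matching the method's printed constants
#' (3 decomposition levels, alpha = beta = 0.5, 100-pixel area filter,
#' K = 8, 2x2 branch opening kernel, median window 3).
#'
#' @param ... named overrides of the defaults; unknown names are rejected.
#' @return A `pipeline_config` object (named list).
#' @examples
#' cfg <- pipeline_config(min_area = 50)
#' cfg$min_area
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop_goji("all configuration overrides must be named",
              "gojivision_config_error")
  }
  unknown <- setdiff(names(overrides), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    stop_goji(sprintf("unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")),
              "gojivision_config_error")
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, overrides)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!ok) stop_goji(sprintf("invalid configuration value for `%s`", what),
                       "gojivision_config_error")
  }
  chk(cfg$wavelet %in% names(.WAVELET_FILTERS), "wavelet")
  chk(is_scalar_number(cfg$levels) && cfg$levels >= 1, "levels")
  chk(is_scalar_number(cfg$alpha) && cfg$alpha >= 0 && cfg$alpha <= 1, "alpha")
  chk(is_scalar_number(cfg$beta) && cfg$beta >= 0 && cfg$beta <= 1, "beta")
  chk(abs(cfg$alpha + cfg$beta - 1) < 1e-9, "alpha/beta (must sum to 1)")
  chk(is_scalar_number(cfg$min_area) && cfg$min_area >= 0, "min_area")
  chk(is_scalar_number(cfg$fruit_kernel) && cfg$fruit_kernel >= 1, "fruit_kernel")
  chk(is_scalar_number(cfg$branch_kernel) && cfg$branch_kernel >= 1, "branch_kernel")
  chk(is_scalar_number(cfg$median_window) && cfg$median_window >= 3 &&
        cfg$median_window %% 2 == 1, "median_window")
  chk(is_scalar_number(cfg$k) && cfg$k >= 1, "k")
  chk(is_scalar_number(cfg$kmeans_max_iter) && cfg$kmeans_max_iter >= 1,
      "kmeans_max_iter")
  chk(is_scalar_number(cfg$kmeans_tol) && cfg$kmeans_tol >= 0, "kmeans_tol")
  chk(cfg$kmeans_features %in% c("lab", "ab"), "kmeans_features")
  chk(cfg$kmeans_init %in% c("random", "plusplus"), "kmeans_init")
  chk(cfg$fruit_polarity %in% c("bright", "dark"), "fruit_polarity")
  chk(cfg$branch_polarity %in% c("bright", "dark"), "branch_polarity")
  chk(is_scalar_number(cfg$hist_smooth) && cfg$hist_smooth >= 1, "hist_smooth")
  chk(is_scalar_number(cfg$seed), "seed")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Save / load a pipeline configuration as YAML
#'
#' `save_config()` writes the configuration; `load_config()` reads one back
#' with the same strict validation as [pipeline_config()] — unknown keys are
#' rejected with a named error, so `load_config(save_config(cfg))`
#' round-trips exactly.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path of the YAML document.
#' @return `load_config()` returns a `pipeline_config`; `save_config()`
#'   returns `path` invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_goji(sprintf("configuration file not found: %s", path),
              "gojivision_io_error")
  }
  raw <- yaml::read_yaml(path)
  int_keys <- c("levels", "min_area", "fruit_kernel", "branch_kernel",
                "median_window", "k", "kmeans_max_iter", "hist_smooth", "seed")
  for (k in intersect(int_keys, names(raw))) raw[[k]] <- as.integer(raw[[k]])
  do.call(pipeline_config, raw)
}

#' Camera intrinsics for pinhole back-projection
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param depth_scale meters per depth unit (default `0.001`: depth maps in
#'   millimeters).
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, depth_scale = 0.001) {
  if (!is_scalar_number(fx) || !is_scalar_number(fy) || fx <= 0 || fy <= 0) {
    stop_goji("focal lengths must be positive", "gojivision_invalid_argument")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 depth_scale = depth_scale),
            class = "camera_intrinsics")
}

#' Read camera intrinsics from a YAML file
#'
#' Expects keys `fx`, `fy`, `cx`, `cy` and optionally `depth_scale`.
#'
#' @param path YAML file path.
#' @return A [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("fx", "fy", "cx", "cy")
  if (!all(need %in% names(raw))) {
    stop_goji("intrinsics YAML must define fx, fy, cx, cy",
              "gojivision_config_error")
  }
  camera_intrinsics(raw$fx, raw$fy, raw$cx, raw$cy,
                    raw$depth_scale %||% 0.001)
}
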