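#' Run configuration for the mitochondrial dynamics pipeline
#'
#' Collects every tunable constant of the pipeline in one flat list so that a
#' complete run is reproducible from a single artifact. The defaults are the
#' fixed constants of the published protocol: a 3x3 top-hat structuring
#' element applied 5 times, a threshold 3 background standard deviations above
#' the intensity mode, 2 "clean" and 3 "separate" binary-processing rounds, a
#' 2-frame (10 s at 5 s intervals) event persistence requirement, a 10 um
#' neighbourhood radius, a 5-pixel Gaussian kernel for neck detection, a
#' 2000-tree random forest with 3 candidate features per split, and 8
#' pre-event frames for the normalized perimeter/solidity traces.
#'
#' @param tophat_size_px Side (pixels) of the square structuring element used
#'   by the white top-hat background flattening. Default 3.
#' @param tophat_counts Number of times the erosion and dilation passes of the
#'   top-hat opening are iterated. Default 5.
#' @param threshold_sigma_mult Number of background standard deviations (in
#'   square-root intensity space) above the intensity mode at which the lower
#'   threshold limit is placed. Default 3.
#' @param clean_iterations Rounds of binary opening + despeckling applied to
#'   the thresholded mask. Default 2.
#' @param separate_iterations Rounds of watershed separation of touching
#'   objects. Default 3.
#' @param persistence_frames Number of frames an event configuration must
#'   persist to be confirmed (the skip-frame consistency check). Default 2.
#' @param neighbor_radius_um Radius (um) of the neighbourhood used for the
#'   neighbour-surface positional feature. Default 10.
#' @param neck_kernel_px Width (pixels of boundary arc) of the Gaussian kernel
#'   used to smooth the boundary pairwise-distance matrix. Default 5.
#' @param n_trees Number of trees in the random forest. Default 2000.
#' @param rf_split_candidates Number of candidate features tried at each tree
#'   split (the mtry parameter). Default 3.
#' @param pre_event_frames Number of frames tracked backwards from each event
#'   for the normalized perimeter/solidity traces. Default 8.
#' @param threshold_per_frame If `TRUE` the intensity threshold is re-estimated
#'   on every frame; the default (`FALSE`) estimates it once on the first
#'   frame of the series, within the ROI.
#' @param overlap_weighted_scores If `TRUE`, a descendant region's unit weight
#'   is split among its ancestors proportionally to pixel overlap instead of
#'   equally. Default `FALSE` (equal split).
#' @param perimeter_edge_count If `TRUE`, perimeter is computed as the number
#'   of boundary pixels times the pixel length instead of the traced
#'   boundary-walk length. Default `FALSE`.
#' @param importance_refit If `TRUE`, feature importance is computed by
#'   refitting one forest per dropped feature instead of by out-of-bag
#'   permutation. Default `FALSE`.
#' @param separate_tolerance Minimum distance-transform depth (pixels) between
#'   a watershed seed and its saddle for two objects to be kept separate.
#'   Default 1.
#' @param separate_smooth_sigma Standard deviation (pixels) of the Gaussian
#'   blur applied to the distance transform before watershed. Default 1.
#' @param prefilter Optional function `function(frame) frame` applied to each
#'   frame before the top-hat step (a user-supplied deconvolution or
#'   denoising stand-in). Default `NULL`.
#' @param random_seed Integer seed from which all randomness flows.
#'
#' @return A list of class `mito_config`.
#' @examples
#' cfg <- run_config(n_trees = 500)
#' cfg$threshold_sigma_mult
#' @export
run_config <- function(tophat_size_px = 3L,
                       tophat_counts = 5L,
                       threshold_sigma_mult = 3,
                       clean_iterations = 2L,
                       separate_iterations = 3L,
                       persistence_frames = 2L,
                       neighbor_radius_um = 10,
                       neck_kernel_px = 5L,
                       n_trees = 2000L,
                       rf_split_candidates = 3L,
                       pre_event_frames = 8L,
                       threshold_per_frame = FALSE,
                       overlap_weighted_scores = FALSE,
                       perimeter_edge_count = FALSE,
                       importance_refit = FALSE,
                       separate_tolerance = 1,
                       separate_smooth_sigma = 1,
                       prefilter = NULL,
                       random_seed = 1L) {
  cfg <- list(
    tophat_size_px = as.integer(tophat_size_px),
    tophat_counts = as.integer(tophat_counts),
    threshold_sigma_mult = as.numeric(threshold_sigma_mult),
    clean_iterations = as.integer(clean_iterations),
    separate_iterations = as.integer(separate_iterations),
    persistence_frames = as.integer(persistence_frames),
    neighbor_radius_um = as.numeric(neighbor_radius_um),
    neck_kernel_px = as.integer(neck_kernel_px),
    n_trees = as.integer(n_trees),
    rf_split_candidates = as.integer(rf_split_candidates),
    pre_event_frames = as.integer(pre_event_frames),
    threshold_per_frame = isTRUE(threshold_per_frame),
    overlap_weighted_scores = isTRUE(overlap_weighted_scores),
    perimeter_edge_count = isTRUE(perimeter_edge_count),
    importance_refit = isTRUE(importance_refit),
    separate_tolerance = as.numeric(separate_tolerance),
    separate_smooth_sigma = as.numeric(separate_smooth_sigma),
    prefilter = prefilter,
    random_seed = as.integer(random_seed)
  )
  counts <- c("tophat_size_px", "tophat_counts", "clean_iterations",
              "separate_iterations", "persistence_frames", "neck_kernel_px",
              "n_trees", "rf_split_candidates", "pre_event_frames")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (!is.finite(cfg$threshold_sigma_mult) || cfg$threshold_sigma_mult <= 0) {
    stop("`threshold_sigma_mult` must be > 0", call. = FALSE)
  }
  if (cfg$neighbor_radius_um <= 0) {
    stop("`neighbor_radius_um` must be > 0", call. = FALSE)
  }
  if (!is.null(prefilter) && !is.function(prefilter)) {
    stop("`prefilter` must be NULL or a function", call. = FALSE)
  }
  structure(cfg, class = "mito_config")
}

#' @export
print.mito_config <- function(x, ...) {
  cat("<mito_config>\n")
  flat <- x[!vapply(x, is.function, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

#' Write / read a run configuration as flat JSON
#'
#' The `prefilter` function, if any, is not serialized (a note is stored in
#' its place); every other field round-trips exactly.
#'
#' @param config A [run_config()] object.
#' @param path File path for the JSON artifact.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `mito_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mito_config"))
  flat <- config[!vapply(config, is.function, logical(1))]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, flat)
}
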