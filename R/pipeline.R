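# End-to-end orchestration: movie -> segmentation -> events -> features ->
# forest -> traces, with all tabular artifacts written to an output
# directory together with a JSON run manifest.

#' Run the full analysis pipeline on a movie
#'
#' Segments every frame, classifies fission/fusion events with the
#' weight-distribution score and persistence check, measures the 11
#' features of each confirmed event, and (when the event table is large
#' enough to support it) trains the random forest and computes the
#' importance ranking, error curve, per-feature stumps, and pre-event
#' traces.
#'
#' @param movie A [mito_movie()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, `events.csv`,
#'   `features.csv`, `importance.csv`, `traces.csv`, `error_curve.csv`,
#'   `stumps.csv`, `threshold.json`, `forest_summary.json`, a labeled-mask
#'   TIFF stack and a JSON run manifest are written there.
#' @param min_events_for_forest Minimum confirmed events (with both classes)
#'   needed to fit the forest. Default 50.
#' @return A list of class `mito_run`: `segmentation`, `events`, `features`,
#'   and (possibly `NULL`) `forest`, `importance`, `error_curve`, `stumps`,
#'   `traces`.
#' @export
run_pipeline <- function(movie, config = run_config(), out_dir = NULL,
                         min_events_for_forest = 50L) {
  seg <- segment_movie(movie, config)
  events <- classify_events(seg$labels, config)
  features <- feature_table(events, seg$labels, movie, config)
  forest <- importance <- curve <- stumps <- traces <- NULL
  n_classes <- length(unique(features$event_call[!is.na(features$event_call)]))
  if (nrow(features) >= min_events_for_forest && n_classes == 2L) {
    forest <- train_forest(features, config)
    importance <- importance_ranking(forest)
    curve <- class_error_curve(forest)
    stumps <- dplyr::bind_rows(purrr::map(
      mito_feature_names()[vapply(mito_feature_names(), function(nm) {
        length(unique(stats::na.omit(features[[nm]]))) > 1
      }, logical(1))],
      function(nm) stump_boundary(features, nm)))
  }
  has_simple <- nrow(dplyr::filter(
    events, .data$call %in% c("fission", "fusion"))) > 0L
  if (has_simple) {
    traces <- tryCatch(
      pre_event_traces(events, seg$labels, movie$pixel_size_um, config),
      error = function(e) NULL)
  }
  run <- structure(list(segmentation = seg, events = events,
                        features = features, forest = forest,
                        importance = importance, error_curve = curve,
                        stumps = stumps, traces = traces, config = config),
                   class = "mito_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.mito_run <- function(x, ...) {
  calls <- table(x$events$call)
  cat("<mito_run>\n")
  cat("  events:", paste(names(calls), calls, collapse = ", "), "\n")
  cat("  feature rows:", nrow(x$features), "\n")
  if (!is.null(x$forest)) {
    cat(sprintf("  forest OOB error: %.3f\n", x$forest$oob_error))
  }
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' @param run A `mito_run` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tables(run$events, run$features, out_dir)
  write_movie(run$segmentation$labels, file.path(out_dir, "labels.tif"))
  readr::write_csv(run$segmentation$thresholds,
                   file.path(out_dir, "threshold.csv"))
  if (!is.null(run$importance)) {
    readr::write_csv(run$importance, file.path(out_dir, "importance.csv"))
    readr::write_csv(run$error_curve, file.path(out_dir, "error_curve.csv"))
    readr::write_csv(run$stumps, file.path(out_dir, "stumps.csv"))
    jsonlite::write_json(
      as.list(glance(run$forest)),
      file.path(out_dir, "forest_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$traces)) {
    readr::write_csv(run$traces$summary, file.path(out_dir, "traces.csv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mitodyn")),
    r_version = R.version.string,
    seed = run$config$random_seed,
    config = run$config[!vapply(run$config, is.function, logical(1))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
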