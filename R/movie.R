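#' Time-lapse movie container
#'
#' A movie is an ordered list of 2D non-negative intensity matrices sharing
#' one shape, together with the physical pixel size (um per pixel edge) and
#' the frame interval (seconds). An optional binary ROI mask restricts
#' threshold estimation to the cell region, and an optional nucleus centroid
#' (row, col, in pixels) anchors the radial-orientation feature.
#'
#' Pixel coordinates are 1-based row/column indices (the R matrix
#' convention); a pixel is a unit square and conversion to um multiplies by
#' `pixel_size_um`.
#'
#' @param frames List of numeric matrices (all the same shape, values >= 0).
#' @param pixel_size_um Pixel edge length in um (> 0).
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @param roi_mask Optional logical matrix matching the frame shape.
#' @param nucleus_centroid Optional numeric `c(row, col)` in pixel units.
#' @return An object of class `mito_movie`.
#' @examples
#' mv <- mito_movie(list(matrix(0, 8, 8), matrix(1, 8, 8)),
#'                  pixel_size_um = 0.1, frame_interval_s = 5)
#' length(mv$frames)
#' @export
mito_movie <- function(frames, pixel_size_um, frame_interval_s,
                       roi_mask = NULL, nucleus_centroid = NULL) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("every frame must be a matrix", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same shape", call. = FALSE)
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop("frame intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0", call. = FALSE)
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stop("`frame_interval_s` must be > 0", call. = FALSE)
  }
  if (!is.null(roi_mask)) {
    roi_mask <- roi_mask != 0
    if (!identical(dim(roi_mask), dim(frames[[1]]))) {
      stop("`roi_mask` must match the frame shape", call. = FALSE)
    }
  }
  if (!is.null(nucleus_centroid)) {
    nucleus_centroid <- as.numeric(nucleus_centroid)
    if (length(nucleus_centroid) != 2L || any(!is.finite(nucleus_centroid))) {
      stop("`nucleus_centroid` must be c(row, col)", call. = FALSE)
    }
  }
  structure(
    list(frames = frames,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         roi_mask = roi_mask,
         nucleus_centroid = nucleus_centroid),
    class = "mito_movie"
  )
}

#' @export
print.mito_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<mito_movie> %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval_s))
  if (!is.null(x$roi_mask)) cat("  ROI mask present\n")
  if (!is.null(x$nucleus_centroid)) {
    cat(sprintf("  nucleus centroid (%.1f, %.1f) px\n",
                x$nucleus_centroid[1], x$nucleus_centroid[2]))
  }
  invisible(x)
}

#' Read a time-lapse movie from TIFF
#'
#' Accepts either a multi-page TIFF or a directory of single-page TIFF files
#' ordered by file name. Integer-valued inputs are recovered losslessly.
#'
#' @param path Path to a multi-page TIFF file or a directory of TIFFs.
#' @inheritParams mito_movie
#' @return A [mito_movie()].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_s,
                       roi_mask = NULL, nucleus_centroid = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop("directory contains no TIFF files: ", path, call. = FALSE)
    }
    frames <- purrr::map(files, function(f) .read_tiff_pages(f)[[1]])
  } else {
    frames <- .read_tiff_pages(path)
  }
  if (length(frames) == 0L) stop("TIFF contains zero frames", call. = FALSE)
  mito_movie(frames, pixel_size_um, frame_interval_s, roi_mask, nucleus_centroid)
}

.read_tiff_pages <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("cannot read TIFF '", path, "': ", conditionMessage(e),
                           call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  purrr::map(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # keep a single channel
    storage.mode(p) <- "double"
    p
  })
}

#' Write a movie or label stack as a multi-page TIFF
#'
#' Integer-valued stacks with a maximum below 2^16 are written as 16-bit
#' TIFF (lossless round trip); anything else is written as 32-bit float.
#'
#' @param x A [mito_movie()] or a list of numeric matrices (e.g. label frames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(x, path) {
  frames <- if (inherits(x, "mito_movie")) x$frames else x
  stopifnot(is.list(frames), length(frames) > 0L)
  vals <- unlist(frames, use.names = FALSE)
  integral <- all(vals == round(vals)) && max(vals) < 65536 && min(vals) >= 0
  if (integral) {
    pages <- purrr::map(frames, function(f) f / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    pages <- purrr::map(frames, function(f) {
      storage.mode(f) <- "double"
      f
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write event and feature tables as CSV
#'
#' Writes `events.csv` and `features.csv` (full floating-point precision)
#' under `dir`. Row order is preserved; an empty table yields a header-only
#' file.
#'
#' @param events Event tibble from [classify_events()].
#' @param features Feature tibble from [feature_table()] (optional).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_tables <- function(events, features = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"))
  readr::write_csv(events, paths[["events"]])
  if (!is.null(features)) {
    paths <- c(paths, features = file.path(dir, "features.csv"))
    readr::write_csv(features, paths[["features"]])
  }
  invisible(paths)
}
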