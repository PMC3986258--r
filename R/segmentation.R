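# Segmentation: white top-hat background flattening, mode + k*sigma
# thresholding of the square-root intensity profile, and "clean"/"separate"
# binary post-processing followed by 8-connected labeling.

#' Flatten the background of a frame with a white top-hat transform
#'
#' `output = frame - opening(frame)`, where the opening is `tophat_counts`
#' grayscale erosions with a square structuring element of side
#' `tophat_size_px`, followed by the same number of dilations. This removes
#' smooth background larger than the iterated element while preserving
#' thin bright structures at their original amplitude.
#'
#' @param frame Non-negative numeric matrix.
#' @param config A [run_config()].
#' @return Numeric matrix of the same shape, non-negative.
#' @export
preprocess_frame <- function(frame, config = run_config()) {
  stopifnot(is.matrix(frame))
  if (any(frame < 0)) stop("frame intensities must be non-negative", call. = FALSE)
  if (is.function(config$prefilter)) {
    frame <- config$prefilter(frame)
    stopifnot(is.matrix(frame), all(dim(frame) == dim(frame)))
  }
  brush <- matrix(1L, config$tophat_size_px, config$tophat_size_px)
  # replicate-pad so the border does not leak zeros into the opening, and
  # rescale to [0, 1] (grayscale morphology works on image-range data)
  pad <- config$tophat_counts * (config$tophat_size_px %/% 2L) + 1L
  mx <- max(frame)
  if (mx == 0) return(frame)
  op <- .pad_replicate(frame / mx, pad)
  for (i in seq_len(config$tophat_counts)) op <- EBImage::erode(op, brush)
  for (i in seq_len(config$tophat_counts)) op <- EBImage::dilate(op, brush)
  op <- op[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))] * mx
  out <- frame - op
  out[out < 0] <- 0
  matrix(as.numeric(out), nrow(frame), ncol(frame))
}

#' Estimate the intensity threshold from an ROI intensity profile
#'
#' Treats the square-root-transformed intensity profile as a background
#' (normal) component plus a brighter object shoulder. The background mean is
#' taken as the histogram mode of the whole profile (Freedman-Diaconis bin
#' width; counts smoothed with a 5-bin moving average so that count noise in
#' neighbouring fine bins cannot displace the mode; mode = centre of the
#' maximal smoothed bin, ties broken toward the lowest bin), and the
#' background SD as the root-mean-square deviation of the
#' values at or below the mode, mirrored about it — so the bright shoulder
#' cannot inflate the estimate. The lower threshold limit is
#' `mode + threshold_sigma_mult * sigma` in square-root space.
#'
#' @param intensities Numeric vector of raw (non-negative) intensities,
#'   at least 1000 values, not all identical.
#' @param config A [run_config()].
#' @return A list of class `mito_threshold` with elements `mode_sqrt`,
#'   `sigma_sqrt`, `lower_limit_sqrt` and `lower_limit_raw`.
#' @export
estimate_threshold <- function(intensities, config = run_config()) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1000) {
    stop("need at least 1000 intensity values", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  s <- sqrt(intensities)
  if (max(s) - min(s) < .Machine$double.eps^0.5) {
    stop("intensity profile is constant; cannot estimate a threshold",
         call. = FALSE)
  }
  bw <- 2 * stats::IQR(s) / length(s)^(1 / 3)  # Freedman-Diaconis
  if (bw <= 0) bw <- (max(s) - min(s)) / ceiling(sqrt(length(s)))
  breaks <- seq(min(s) - bw / 2, max(s) + bw, by = bw)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  counts <- h$counts
  if (length(counts) >= 5L) {
    padded <- c(0, 0, counts, 0, 0)
    counts <- vapply(seq_along(counts),
                     function(i) mean(padded[i:(i + 4L)]), numeric(1))
  }
  mode_sqrt <- h$mids[which.max(counts)]
  left <- s[s <= mode_sqrt]
  sigma_sqrt <- sqrt(mean((left - mode_sqrt)^2))
  if (!is.finite(sigma_sqrt) || sigma_sqrt <= 0) {
    stop("degenerate left flank; cannot estimate background SD", call. = FALSE)
  }
  lower_limit_sqrt <- mode_sqrt + config$threshold_sigma_mult * sigma_sqrt
  structure(list(mode_sqrt = mode_sqrt,
                 sigma_sqrt = sigma_sqrt,
                 lower_limit_sqrt = lower_limit_sqrt,
                 lower_limit_raw = lower_limit_sqrt^2),
            class = "mito_threshold")
}

#' @export
print.mito_threshold <- function(x, ...) {
  cat(sprintf(
    "<mito_threshold> mode %.3f, sigma %.3f (sqrt space); lower limit %.3f (raw %.3f)\n",
    x$mode_sqrt, x$sigma_sqrt, x$lower_limit_sqrt, x$lower_limit_raw))
  invisible(x)
}

.pad_replicate <- function(m, k) {
  ridx <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  cidx <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ridx, cidx]
}

# one round of "clean": binary opening with a 3x3 cross, then removal of
# connected components smaller than 4 px
.clean_once <- function(fg) {
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  fg <- EBImage::dilate(EBImage::erode(fg, cross), cross) > 0
  lab <- label_components(fg, connectivity = 8)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < 4L)
    if (length(small) > 0L) fg[lab %in% small] <- FALSE
  }
  fg
}

# one round of "separate": watershed on the smoothed distance transform;
# seeds closer than 2 px (ext = 2) or shallower than the tolerance merge
.separate_once <- function(fg, config) {
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  dt <- EBImage::distmap(fg)
  if (config$separate_smooth_sigma > 0) {
    dt <- EBImage::gblur(dt, sigma = config$separate_smooth_sigma)
    dt[!fg] <- 0
  }
  w <- EBImage::watershed(dt, tolerance = config$separate_tolerance, ext = 2)
  matrix(as.integer(w), nrow(fg), ncol(fg))
}

#' Threshold a preprocessed frame and label the objects
#'
#' Pixels strictly above the raw lower threshold limit are foreground. The
#' mask then goes through `clean_iterations` rounds of binary opening with a
#' 3x3 cross plus removal of components under 4 px ("clean"), and
#' `separate_iterations` rounds of watershed splitting on the smoothed
#' distance transform ("separate"). Remaining objects are labeled with
#' 8-connectivity; labels are renumbered in scan order.
#'
#' @param frame Preprocessed numeric matrix (see [preprocess_frame()]).
#' @param threshold A `mito_threshold` from [estimate_threshold()].
#' @param config A [run_config()].
#' @return Integer label matrix (0 = background).
#' @export
binarize_and_label <- function(frame, threshold, config = run_config()) {
  stopifnot(inherits(threshold, "mito_threshold"))
  fg <- frame > threshold$lower_limit_raw
  if (!any(fg)) return(matrix(0L, nrow(frame), ncol(frame)))
  for (i in seq_len(config$clean_iterations)) fg <- .clean_once(fg)
  if (!any(fg)) return(matrix(0L, nrow(frame), ncol(frame)))
  lab <- NULL
  for (i in seq_len(config$separate_iterations)) {
    lab <- .separate_once(fg, config)
    fg <- lab > 0L
  }
  # enforce 8-connectivity within each watershed basin
  out <- matrix(0L, nrow(frame), ncol(frame))
  nxt <- 0L
  for (id in sort(unique(lab[lab > 0L]))) {
    comp <- label_components(lab == id, connectivity = 8)
    k <- max(comp)
    out[comp > 0L] <- comp[comp > 0L] + nxt
    nxt <- nxt + k
  }
  .relabel_sequential(out)
}

#' Segment a whole movie
#'
#' Applies [preprocess_frame()], [estimate_threshold()] and
#' [binarize_and_label()] to every frame. By default the threshold is
#' estimated once, on the first frame (within the ROI when present), and
#' reused across the series; `config$threshold_per_frame = TRUE`
#' re-estimates it per frame.
#'
#' @param movie A [mito_movie()].
#' @param config A [run_config()].
#' @return A list of class `mito_segmentation`: `labels` (list of integer
#'   label matrices), `thresholds` (tibble with one row per estimated
#'   threshold), and `pixel_size_um`.
#' @export
segment_movie <- function(movie, config = run_config()) {
  stopifnot(inherits(movie, "mito_movie"))
  roi <- movie$roi_mask
  pick <- function(fr) if (is.null(roi)) as.numeric(fr) else fr[roi]
  pre <- purrr::map(movie$frames, preprocess_frame, config = config)
  thr_rows <- list()
  thr <- NULL
  labels <- vector("list", length(pre))
  for (t in seq_along(pre)) {
    if (is.null(thr) || config$threshold_per_frame) {
      thr <- estimate_threshold(pick(pre[[t]]), config)
      thr_rows[[length(thr_rows) + 1L]] <- tibble::tibble(
        frame = t, mode_sqrt = thr$mode_sqrt, sigma_sqrt = thr$sigma_sqrt,
        lower_limit_sqrt = thr$lower_limit_sqrt,
        lower_limit_raw = thr$lower_limit_raw)
    }
    labels[[t]] <- binarize_and_label(pre[[t]], thr, config)
  }
  structure(list(labels = labels,
                 thresholds = dplyr::bind_rows(thr_rows),
                 pixel_size_um = movie$pixel_size_um),
            class = "mito_segmentation")
}

#' @export
print.mito_segmentation <- function(x, ...) {
  n <- vapply(x$labels, max, numeric(1))
  cat(sprintf("<mito_segmentation> %d frames, %.1f objects/frame (range %d-%d)\n",
              length(x$labels), mean(n), min(n), max(n)))
  invisible(x)
}
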