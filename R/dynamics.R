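# Pre-event morphology dynamics: perimeter and solidity of event-bound
# mitochondria tracked backwards in time, normalized to the frame just
# prior to the event (P/P0, S/S0), summarized as mean +/- SE per offset.

#' Normalized perimeter/solidity traces before fission and fusion events
#'
#' Restricts confirmed events to simple 1-to-2 fissions and 2-to-1 fusions,
#' then follows each event's reference region backwards for up to
#' `config$pre_event_frames` frames. The backward step follows the unique
#' stable ancestor (a strict 1-to-1 overlap relation in the reversed frame
#' pair); a trace terminates early as soon as the backward identity is
#' ambiguous, and the per-offset n reflects the surviving traces. Perimeter
#' and solidity at each offset are divided by their values at offset 0 (the
#' frame directly preceding the event), so both ratios are exactly 1 there.
#'
#' @param events Tibble from [classify_events()].
#' @param labels List of integer label matrices.
#' @param pixel_size_um um per pixel.
#' @param config A [run_config()].
#' @return A list of class `mito_traces`: `per_event` (tibble: event id,
#'   call, offset, P_ratio, S_ratio) and `summary` (tibble: offset, call,
#'   mean_P_ratio, se_P, mean_S_ratio, se_S, n).
#' @export
pre_event_traces <- function(events, labels, pixel_size_um = 1,
                             config = run_config()) {
  ev <- dplyr::filter(events, .data$call %in% c("fission", "fusion"))
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    rel <- relate_regions(labels[[ev$frame[i]]], labels[[ev$frame[i] + 1L]])
    desc <- rel$to[rel$from == ev$region_id[i]]
    if (ev$call[i] == "fission") {
      length(desc) == 2L  # 1 -> 2 split
    } else {
      # 2 -> 1 merge: single child with exactly two ancestors
      length(desc) == 1L && sum(rel$to == desc) == 2L
    }
  }, logical(1))
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no qualifying 1-to-2 fission or 2-to-1 fusion events",
                           call. = FALSE)
  per_event <- purrr::map(seq_len(nrow(ev)), function(i) {
    t0 <- ev$frame[i]
    id <- ev$region_id[i]
    ratios <- list()
    mask <- labels[[t0]] == id
    p0 <- perimeter_px(mask, config$perimeter_edge_count) * pixel_size_um
    px <- which(mask, arr.ind = TRUE)
    s0 <- nrow(px) / .hull_pixel_count(px)
    ratios[[1]] <- tibble::tibble(event = i, call = ev$call[i], offset = 0L,
                                  P_ratio = 1, S_ratio = 1)
    cur <- id
    t <- t0
    for (off in seq_len(config$pre_event_frames)) {
      if (t - 1L < 1L) break
      # reversed frame pair: regions at t-1 are "later", so a stable
      # backward identity is a 1-to-1 relation
      rel <- relate_regions(labels[[t]], labels[[t - 1L]])
      anc <- rel$to[rel$from == cur]
      if (length(anc) != 1L || sum(rel$to == anc) != 1L) break
      mask <- labels[[t - 1L]] == anc
      p <- perimeter_px(mask, config$perimeter_edge_count) * pixel_size_um
      px <- which(mask, arr.ind = TRUE)
      s <- nrow(px) / .hull_pixel_count(px)
      ratios[[off + 1L]] <- tibble::tibble(event = i, call = ev$call[i],
                                           offset = off,
                                           P_ratio = p / p0, S_ratio = s / s0)
      cur <- anc
      t <- t - 1L
    }
    dplyr::bind_rows(ratios)
  })
  per_event <- dplyr::bind_rows(per_event)
  summary <- dplyr::summarise(
    dplyr::group_by(per_event, .data$offset, .data$call),
    mean_P_ratio = mean(.data$P_ratio),
    se_P = stats::sd(.data$P_ratio) / sqrt(dplyr::n()),
    mean_S_ratio = mean(.data$S_ratio),
    se_S = stats::sd(.data$S_ratio) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  structure(list(per_event = per_event,
                 summary = dplyr::arrange(summary, .data$call, .data$offset)),
            class = "mito_traces")
}

#' @export
print.mito_traces <- function(x, ...) {
  n_ev <- length(unique(x$per_event$event))
  cat(sprintf("<mito_traces> %d events, offsets 0-%d\n", n_ev,
              max(x$summary$offset)))
  print(x$summary)
  invisible(x)
}
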