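# Fission/fusion event detection: overlap relations between consecutive
# labeled frames, the weight-distribution score, and the skip-frame
# persistence (consistency) check.

#' Overlap relations between the regions of two labeled frames
#'
#' A region pair `(i, j)` (i in the earlier frame, j in the later) is related
#' iff they overlap in at least one pixel AND at least one of: i is (one of)
#' the earlier-frame region(s) with maximal overlap with j, or j is (one of)
#' the later-frame region(s) with maximal overlap with i. All argmax ties are
#' included.
#'
#' @param label_t,label_next Integer label matrices of the same shape
#'   (0 = background).
#' @return A tibble of class `mito_relations` with columns `from`, `to`,
#'   `overlap_px`, and attributes `regions_from` / `regions_to` listing all
#'   region ids present in each frame.
#' @export
relate_regions <- function(label_t, label_next) {
  if (!all(dim(label_t) == dim(label_next))) {
    stop("label frames must share the same shape", call. = FALSE)
  }
  both <- label_t > 0L & label_next > 0L
  if (any(both)) {
    ov <- dplyr::count(
      tibble::tibble(from = label_t[both], to = label_next[both]),
      .data$from, .data$to, name = "overlap_px")
    ov <- dplyr::mutate(
      dplyr::group_by(ov, .data$to),
      max_for_to = max(.data$overlap_px))
    ov <- dplyr::mutate(
      dplyr::group_by(ov, .data$from),
      max_for_from = max(.data$overlap_px))
    ov <- dplyr::ungroup(ov)
    rel <- dplyr::filter(ov, .data$overlap_px == .data$max_for_to |
                           .data$overlap_px == .data$max_for_from)
    rel <- dplyr::select(rel, "from", "to", "overlap_px")
  } else {
    rel <- tibble::tibble(from = integer(), to = integer(),
                          overlap_px = integer())
  }
  structure(dplyr::arrange(rel, .data$from, .data$to),
            class = c("mito_relations", class(tibble::tibble())),
            regions_from = sort(unique(label_t[label_t > 0L])),
            regions_to = sort(unique(label_next[label_next > 0L])))
}

#' Weight-distribution scores from an overlap relation graph
#'
#' Each later-frame region carries a unit weight regardless of size. The
#' weight is split among its ancestors (equally by default, or
#' proportionally to pixel overlap when `config$overlap_weighted_scores` is
#' set), and an earlier-frame region's score is the sum of the weights it
#' receives from its descendants: a score above 1 marks a region poised to
#' undergo fission, below 1 fusion, exactly 1 neither.
#'
#' @param relations A `mito_relations` from [relate_regions()].
#' @param config A [run_config()].
#' @return A list with tibbles `later` (`region`, `score` = 1/|ancestors|)
#'   and `earlier` (`region`, `score`); regions without any relation are
#'   absent (their score is undefined).
#' @export
score_regions <- function(relations, config = run_config()) {
  stopifnot(inherits(relations, "mito_relations"))
  if (nrow(relations) == 0L) {
    empty <- tibble::tibble(region = integer(), score = numeric())
    return(list(later = empty, earlier = empty))
  }
  rel <- dplyr::group_by(tibble::as_tibble(relations), .data$to)
  if (isTRUE(config$overlap_weighted_scores)) {
    rel <- dplyr::mutate(rel, weight = .data$overlap_px / sum(.data$overlap_px))
  } else {
    rel <- dplyr::mutate(rel, weight = 1 / dplyr::n())
  }
  later <- dplyr::summarise(rel, score = 1 / dplyr::n(), .groups = "drop")
  later <- dplyr::rename(later, region = "to")
  earlier <- dplyr::summarise(dplyr::group_by(dplyr::ungroup(rel), .data$from),
                              score = sum(.data$weight), .groups = "drop")
  earlier <- dplyr::rename(earlier, region = "from")
  list(later = dplyr::arrange(later, .data$region),
       earlier = dplyr::arrange(earlier, .data$region))
}

#' Classify fission/fusion/stable events across a label sequence
#'
#' For every frame `t` with `t + 2` available, computes the
#' weight-distribution score of each region against the next frame
#' (`score_next`) and against the frame after that (`score_skip`, the
#' persistence check). A region is called `fusion` when both scores are
#' strictly below 1, `fission` when both are strictly above 1, and `stable`
#' when `score_next` equals 1. Candidates whose two scores disagree — e.g. a
#' transient one-frame contact — are recorded as `unconfirmed` and excluded
#' from downstream feature analysis. Regions with no descendant are logged
#' as `disappearance`; later-frame regions with no ancestor are logged as
#' `appearance`.
#'
#' @param labels List of integer label matrices (>= 3 frames).
#' @param config A [run_config()].
#' @return A tibble with columns `frame`, `region_id`, `score_next`,
#'   `score_skip`, `call`, `area_px`.
#' @export
classify_events <- function(labels, config = run_config()) {
  if (length(labels) < 3L) {
    stop("event classification needs at least 3 frames", call. = FALSE)
  }
  tol <- 1e-9
  out <- list()
  for (t in seq_len(length(labels) - 2L)) {
    rel1 <- relate_regions(labels[[t]], labels[[t + 1L]])
    rel2 <- relate_regions(labels[[t]], labels[[t + 2L]])
    s1 <- score_regions(rel1, config)$earlier
    s2 <- score_regions(rel2, config)$earlier
    ids <- attr(rel1, "regions_from")
    if (length(ids) > 0L) {
      areas <- tabulate(labels[[t]][labels[[t]] > 0L])
      sc1 <- s1$score[match(ids, s1$region)]
      sc2 <- s2$score[match(ids, s2$region)]
      call <- dplyr::case_when(
        is.na(sc1) ~ "disappearance",
        abs(sc1 - 1) <= tol ~ "stable",
        sc1 > 1 & !is.na(sc2) & sc2 > 1 + tol ~ "fission",
        sc1 < 1 & !is.na(sc2) & sc2 < 1 - tol ~ "fusion",
        TRUE ~ "unconfirmed")
      out[[length(out) + 1L]] <- tibble::tibble(
        frame = t, region_id = ids, score_next = sc1, score_skip = sc2,
        call = call, area_px = areas[ids])
    }
    orphans <- setdiff(attr(rel1, "regions_to"), rel1$to)
    if (length(orphans) > 0L) {
      areas2 <- tabulate(labels[[t + 1L]][labels[[t + 1L]] > 0L])
      out[[length(out) + 1L]] <- tibble::tibble(
        frame = t + 1L, region_id = orphans, score_next = NA_real_,
        score_skip = NA_real_, call = "appearance",
        area_px = areas2[orphans])
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$region_id)
}

#' Compare detected events with a synthetic scene's ground truth
#'
#' Confirmed fission/fusion calls are matched to the scheduled events of a
#' [generate_movie()] scene by frame (within `frame_tol`) and type. Recall
#' is the fraction of scheduled fission/fusion events matched; precision is
#' the fraction of confirmed calls that match a scheduled event. The
#' dissolution of a scripted one-frame "passing" contact is a genuine split
#' of the transiently joined region, so confirmed fission calls at a passing
#' contact frame (or one frame after) are excluded from the precision
#' denominator rather than penalized.
#'
#' @param events Tibble from [classify_events()].
#' @param scene A `mito_scene`.
#' @param frame_tol Frame-matching tolerance. Default 1.
#' @return A list: `recall`, `precision`, `n_truth`, `n_detected`, `matched`.
#' @export
score_detection <- function(events, scene, frame_tol = 1L) {
  stopifnot(inherits(scene, "mito_scene"))
  truth <- dplyr::filter(scene$truth_events, .data$type %in% c("fission", "fusion"))
  pass_frames <- scene$truth_events$frame[scene$truth_events$type == "passing"]
  pred <- dplyr::filter(events, .data$call %in% c("fission", "fusion"))
  drop <- pred$call == "fission" &
    vapply(pred$frame, function(f) any(abs(f - (pass_frames + 1L)) <= frame_tol),
           logical(1))
  pred <- pred[!drop, , drop = FALSE]
  # a single physical event yields one record per participating
  # mitochondrion (a 2-to-1 fusion labels both parents), so records are
  # matched to events without consuming them
  rec_ok <- vapply(seq_len(nrow(pred)), function(i) {
    any(truth$type == pred$call[i] &
          abs(truth$frame - pred$frame[i]) <= frame_tol)
  }, logical(1))
  ev_ok <- vapply(seq_len(nrow(truth)), function(i) {
    any(pred$call == truth$type[i] &
          abs(pred$frame - truth$frame[i]) <= frame_tol)
  }, logical(1))
  list(recall = if (nrow(truth) > 0) mean(ev_ok) else NA_real_,
       precision = if (nrow(pred) > 0) mean(rec_ok) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(pred),
       matched = sum(ev_ok))
}
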