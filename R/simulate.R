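# Synthetic time-lapse generator. Scenes emulate peripheral snapshots of a
# fluorescently labelled mitochondrial network: tubular/branched and compact
# bright objects on a noisy unimodal background, with scripted fission,
# fusion, transient "passing" contacts and stable tracks, plus per-frame
# ground-truth instance masks and an event table.

# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic movie generator
#'
#' The defaults emulate the acquisition geometry the pipeline targets: a
#' 22 um x 22 um peripheral field (220 x 220 px at 0.1 um/px) imaged every
#' 5 s for 5 min (60 frames), with a mixture of compact and tubular
#' organelles on a noisy unimodal background whose bright objects form a
#' right shoulder of the intensity histogram.
#'
#' @param field_px Square field side in pixels. Default 220.
#' @param n_frames Number of frames. Default 60.
#' @param pixel_size_um um per pixel. Default 0.1.
#' @param frame_interval_s Seconds between frames. Default 5.
#' @param n_objects Number of organelles placed. Default 12.
#' @param frac_tubule Fraction of objects drawn as branched/tubular rather
#'   than compact. Default 0.4.
#' @param background_mean,background_sd Background intensity model
#'   (arbitrary units). Defaults 100 and 10.
#' @param object_intensity Mean object intensity; must exceed
#'   `background_mean + 6 * background_sd`. Default 220.
#' @param object_sd Intensity noise on object pixels. Default 10.
#' @param min_separation_px Minimum gap (pixels) enforced between distinct
#'   objects at placement. Default 4.
#' @param fission_growth_per_frame Fractional isotropic growth applied to a
#'   fissioning object in each of the `fission_growth_frames` frames leading
#'   up to its scheduled split (so the object reaches its largest size in
#'   the frame just before the event, emulating the morphology build-up seen
#'   before fission). Default 0 (no growth).
#' @param fission_growth_frames Length of the pre-fission growth window.
#'   Default 8.
#' @param events Event schedule tibble with columns `frame`, `type`
#'   (`"fission"`, `"fusion"`, `"passing"`) and `object` (object index; for
#'   fusion/passing a `partner` column names the second object). `NULL`
#'   means no events.
#' @return A list of class `mito_sim_params`.
#' @export
simulate_params <- function(field_px = 220L,
                            n_frames = 60L,
                            pixel_size_um = 0.1,
                            frame_interval_s = 5,
                            n_objects = 12L,
                            frac_tubule = 0.4,
                            background_mean = 100,
                            background_sd = 10,
                            object_intensity = 220,
                            object_sd = 10,
                            min_separation_px = 4L,
                            fission_growth_per_frame = 0,
                            fission_growth_frames = 8L,
                            events = NULL) {
  if (object_intensity <= background_mean + 6 * background_sd) {
    stop("`object_intensity` must exceed background_mean + 6 * background_sd",
         call. = FALSE)
  }
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("frame", "type", "object") %in% names(events)))
    if (!"partner" %in% names(events)) events$partner <- NA_integer_
    bad <- events$type %in% c("fusion", "passing") & is.na(events$partner)
    if (any(bad)) stop("fusion/passing events need a `partner` object",
                       call. = FALSE)
    refs <- c(events$object, events$partner)
    if (any(stats::na.omit(refs) > n_objects | stats::na.omit(refs) < 1)) {
      stop("event schedule references a missing object", call. = FALSE)
    }
    if (any(events$frame < 2 | events$frame > n_frames - 2)) {
      stop("event frames must lie in [2, n_frames - 2] so that the ",
           "persistence check has room", call. = FALSE)
    }
  }
  structure(list(field_px = as.integer(field_px),
                 n_frames = as.integer(n_frames),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_objects = as.integer(n_objects),
                 frac_tubule = frac_tubule,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 object_intensity = object_intensity,
                 object_sd = object_sd,
                 min_separation_px = as.integer(min_separation_px),
                 fission_growth_per_frame = fission_growth_per_frame,
                 fission_growth_frames = as.integer(fission_growth_frames),
                 events = events),
            class = "mito_sim_params")
}

#' Default event schedule for a synthetic scene
#'
#' Assigns each event to a distinct object (fusion/passing pairs use two) and
#' spreads the event frames over the middle of the series.
#'
#' @param params A [simulate_params()] object (its `events` slot is ignored).
#' @param n_fission,n_fusion,n_passing Event counts. Defaults 3, 3, 1.
#' @return The event tibble, suitable for `simulate_params(events = ...)`.
#' @export
schedule_events <- function(params, n_fission = 3L, n_fusion = 3L,
                            n_passing = 1L) {
  need <- n_fission + 2L * (n_fusion + n_passing)
  if (need > params$n_objects) {
    stop("not enough objects for the requested schedule", call. = FALSE)
  }
  ids <- seq_len(params$n_objects)
  k <- 0L
  take <- function(n) { out <- ids[k + seq_len(n)]; k <<- k + n; out }
  ev <- list()
  if (n_fission > 0) {
    ev[[length(ev) + 1L]] <- tibble::tibble(type = "fission",
                                            object = take(n_fission),
                                            partner = NA_integer_)
  }
  if (n_fusion > 0) {
    a <- take(n_fusion); b <- take(n_fusion)
    ev[[length(ev) + 1L]] <- tibble::tibble(type = "fusion", object = a,
                                            partner = b)
  }
  if (n_passing > 0) {
    a <- take(n_passing); b <- take(n_passing)
    ev[[length(ev) + 1L]] <- tibble::tibble(type = "passing", object = a,
                                            partner = b)
  }
  ev <- dplyr::bind_rows(ev)
  lo <- max(2L, round(params$n_frames * 0.15))
  hi <- max(lo, params$n_frames - max(3L, round(params$n_frames * 0.15)))
  ev$frame <- as.integer(round(seq(lo, hi, length.out = nrow(ev))))
  ev[, c("frame", "type", "object", "partner")]
}

# ---- shape primitives ------------------------------------------------------

.disc_brush <- function(radius) {
  EBImage::makeBrush(2L * max(1L, round(radius)) + 1L, shape = "disc")
}

.raster_segment <- function(canvas, p, q) {
  n <- max(2L, ceiling(4 * sqrt(sum((q - p)^2))))
  t <- seq(0, 1, length.out = n)
  r <- round(p[1] + t * (q[1] - p[1]))
  c <- round(p[2] + t * (q[2] - p[2]))
  ok <- r >= 1 & r <= nrow(canvas) & c >= 1 & c <= ncol(canvas)
  canvas[cbind(r[ok], c[ok])] <- TRUE
  canvas
}

.ellipse_mask <- function(a, b, theta) {
  ext <- ceiling(max(a, b)) + 1L
  n <- 2L * ext + 1L
  idx <- expand.grid(r = seq_len(n) - ext - 1L, c = seq_len(n) - ext - 1L)
  x <- idx$c * cos(theta) + idx$r * sin(theta)
  y <- -idx$c * sin(theta) + idx$r * cos(theta)
  matrix((x / a)^2 + (y / b)^2 <= 1, n, n)
}

# random-walk polyline dilated to a tubule; optionally one branch point
.tubule_mask <- function(length_px, thickness, branched) {
  ext <- length_px + 2L * thickness + 4L
  canvas <- matrix(FALSE, ext, ext)
  ctr <- c(ext / 2, ext / 2)
  walk <- function(start, theta, len) {
    p <- start
    pts <- list(p)
    travelled <- 0
    while (travelled < len) {
      step <- 2
      theta <<- theta + stats::runif(1, -0.45, 0.45)
      q <- p + step * c(sin(theta), cos(theta))
      q <- pmin(pmax(q, thickness + 2), ext - thickness - 1)
      pts[[length(pts) + 1L]] <- q
      travelled <- travelled + step
      p <- q
    }
    do.call(rbind, pts)
  }
  theta0 <- stats::runif(1, 0, 2 * pi)
  main <- walk(ctr, theta0, length_px)
  for (i in seq_len(nrow(main) - 1L)) {
    canvas <- .raster_segment(canvas, main[i, ], main[i + 1L, ])
  }
  if (branched) {
    bp <- main[max(2L, round(nrow(main) / 2)), ]
    side <- walk(bp, theta0 + sample(c(-1, 1), 1) * stats::runif(1, 1.0, 2.1),
                 length_px / 2)
    for (i in seq_len(nrow(side) - 1L)) {
      canvas <- .raster_segment(canvas, side[i, ], side[i + 1L, ])
    }
  }
  EBImage::dilate(canvas, .disc_brush((thickness - 1) / 2)) > 0
}

.random_object_mask <- function(tubule) {
  if (tubule) {
    .tubule_mask(length_px = round(stats::runif(1, 18, 32)), thickness = 5,
                 branched = stats::runif(1) < 0.6)
  } else {
    a <- stats::runif(1, 3.5, 6.5)
    b <- stats::runif(1, 2.0, 3.0)
    .ellipse_mask(a, b, stats::runif(1, 0, pi))
  }
}

#' Analytic test shapes
#'
#' Binary masks with known morphological properties: `disk` (solidity ~ 1, no
#' holes or necks), `bar` (no necks), `L_shape`, `Y_branch` (one branch
#' intersection), `annulus` (exactly one hole), and `two_blob_dumbbell`
#' (exactly one neck whose width equals `bridge_px`).
#'
#' @param kind One of `"disk"`, `"bar"`, `"L_shape"`, `"Y_branch"`,
#'   `"annulus"`, `"two_blob_dumbbell"`.
#' @param size_px Nominal size (>= 5).
#' @param bridge_px Bridge width for the dumbbell. Default 3.
#' @return A logical matrix.
#' @examples
#' sum(generate_shape("disk", 15))
#' @export
generate_shape <- function(kind, size_px, bridge_px = 3L) {
  if (size_px < 5) stop("`size_px` must be >= 5", call. = FALSE)
  size_px <- as.integer(size_px)
  switch(
    kind,
    disk = {
      r <- (size_px - 1) / 2
      idx <- expand.grid(r = seq_len(size_px), c = seq_len(size_px))
      matrix((idx$r - r - 1)^2 + (idx$c - r - 1)^2 <= r^2, size_px, size_px)
    },
    bar = {
      w <- max(3L, size_px %/% 5L)
      m <- matrix(FALSE, w + 4L, size_px + 4L)
      m[3:(w + 2L), 3:(size_px + 2L)] <- TRUE
      m
    },
    L_shape = {
      w <- max(3L, size_px %/% 5L)
      m <- matrix(FALSE, size_px + 4L, size_px + 4L)
      m[3:(size_px + 2L), 3:(w + 2L)] <- TRUE
      m[(size_px + 2L - w + 1L):(size_px + 2L), 3:(size_px + 2L)] <- TRUE
      m
    },
    Y_branch = {
      ext <- size_px + 8L
      ctr <- c(ext / 2, ext / 2)
      m <- matrix(FALSE, ext, ext)
      for (ang in c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)) {
        tip <- ctr + (size_px / 2) * c(sin(ang), cos(ang))
        m <- .raster_segment(m, ctr, tip)
      }
      EBImage::dilate(m, .disc_brush(1)) > 0
    },
    annulus = {
      r <- (size_px - 1) / 2
      ri <- max(1.5, r / 2)
      idx <- expand.grid(r = seq_len(size_px), c = seq_len(size_px))
      d2 <- (idx$r - r - 1)^2 + (idx$c - r - 1)^2
      matrix(d2 <= r^2 & d2 > ri^2, size_px, size_px)
    },
    two_blob_dumbbell = {
      r <- max(4L, size_px %/% 4L)
      gap <- 2L * r
      h <- 2L * r + 5L
      w <- 4L * r + gap + 5L
      m <- matrix(FALSE, h, w)
      cy <- (h + 1) / 2
      cx1 <- r + 3; cx2 <- w - r - 2
      idx <- expand.grid(r = seq_len(h), c = seq_len(w))
      m[(idx$r - cy)^2 + (idx$c - cx1)^2 <= r^2] <- TRUE
      m[(idx$r - cy)^2 + (idx$c - cx2)^2 <= r^2] <- TRUE
      half <- (as.integer(bridge_px) - 1L) %/% 2L
      rows <- round(cy - half):round(cy - half + bridge_px - 1L)
      m[rows, round(cx1):round(cx2)] <- TRUE
      m
    },
    stop("unknown shape kind: ", kind, call. = FALSE)
  )
}

#' Synthetic intensity profile with a background mode and bright shoulder
#'
#' Draws `n_pixels` intensities whose square-root transform is a normal
#' background component centred at `sqrt(mode_value)` with standard deviation
#' `sigma`, plus (optionally) a brighter object component shifted right by
#' `object_shift` in square-root units — the two-population structure the
#' threshold estimator assumes.
#'
#' @param n_pixels Number of values (>= 1000).
#' @param mode_value Raw-intensity mode of the background.
#' @param sigma Background SD in square-root intensity space.
#' @param object_fraction Fraction of object pixels, in `[0, 0.3)`.
#' @param object_shift Right shift of the object component in square-root
#'   intensity units (e.g. `8 * sigma`).
#' @param seed Integer seed.
#' @return A numeric vector of raw (squared) intensities.
#' @export
generate_intensity_profile <- function(n_pixels, mode_value, sigma,
                                       object_fraction = 0,
                                       object_shift = 0, seed = 1L) {
  if (n_pixels < 1000) stop("`n_pixels` must be >= 1000", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (object_fraction < 0 || object_fraction >= 0.3) {
    stop("`object_fraction` must lie in [0, 0.3)", call. = FALSE)
  }
  .with_seed(seed, {
    n_obj <- round(n_pixels * object_fraction)
    mu <- sqrt(mode_value)
    s <- c(stats::rnorm(n_pixels - n_obj, mu, sigma),
           stats::rnorm(n_obj, mu + object_shift, sigma))
    pmax(s, 0)^2
  })
}

# ---- placement and event rendering ----------------------------------------

.centroid <- function(mask) colMeans(which(mask, arr.ind = TRUE))

.min_gap <- function(maskA, maskB) {
  # pixel gap between two masks: nearest centre distance minus one pixel
  dt <- EBImage::distmap(!maskA)
  max(0, min(dt[maskB]) - 1)
}

.place_all <- function(params) {
  fp <- params$field_px
  ev <- params$events
  pair_of <- integer(params$n_objects)  # 0 = unpaired
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      if (!is.na(ev$partner[i])) {
        # the later-placed member of the pair is anchored near the earlier one
        hi <- max(ev$object[i], ev$partner[i])
        lo <- min(ev$object[i], ev$partner[i])
        pair_of[hi] <- lo
      }
    }
  }
  tubule <- stats::runif(params$n_objects) < params$frac_tubule
  if (!is.null(ev)) tubule[ev$object[ev$type == "fusion"]] <- FALSE
  if (!is.null(ev)) tubule[ev$partner[ev$type == "fusion"] |> stats::na.omit()] <- FALSE
  masks <- vector("list", params$n_objects)
  sep_brush <- .disc_brush(params$min_separation_px)
  occ_each <- vector("list", params$n_objects)  # dilated footprints
  for (k in seq_len(params$n_objects)) {
    local <- .random_object_mask(tubule[k])
    placed <- FALSE
    for (try in 1:400) {
      full <- matrix(FALSE, fp, fp)
      if (pair_of[k] > 0L && !is.null(masks[[pair_of[k]]])) {
        anchor <- .centroid(masks[[pair_of[k]]])
        r0 <- round(anchor[1] + stats::runif(1, -25, 25)) - nrow(local) %/% 2L
        c0 <- round(anchor[2] + stats::runif(1, -25, 25)) - ncol(local) %/% 2L
      } else {
        r0 <- sample.int(fp - nrow(local) - 4L, 1L) + 2L
        c0 <- sample.int(fp - ncol(local) - 4L, 1L) + 2L
      }
      if (r0 < 1L || c0 < 1L || r0 + nrow(local) - 1L > fp ||
          c0 + ncol(local) - 1L > fp) next
      full[r0 + seq_len(nrow(local)) - 1L, c0 + seq_len(ncol(local)) - 1L] <- local
      ok <- TRUE
      for (m in seq_len(k - 1L)) {
        if (is.null(masks[[m]])) next
        if (m == pair_of[k]) next
        if (any(full & occ_each[[m]])) { ok <- FALSE; break }
      }
      if (ok && pair_of[k] > 0L) {
        gap <- .min_gap(masks[[pair_of[k]]], full)
        if (gap < 3 || gap > 6) ok <- FALSE
      }
      if (ok) {
        masks[[k]] <- full
        occ_each[[k]] <- EBImage::dilate(full, sep_brush) > 0
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place object ", k,
           " without overlap at the requested density", call. = FALSE)
    }
  }
  masks
}

# split a mask into >= 2 children by deleting a 2-px band across its
# principal axis; crumbs below 8 px are dropped
.cut_mask <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  cc <- sweep(px, 2, colMeans(px))
  ax <- eigen(stats::cov(cc))$vectors[, 1]
  proj <- as.numeric(cc %*% ax)
  for (q in c(0.5, 0.42, 0.58, 0.34, 0.66, 0.26, 0.74)) {
    cut <- stats::quantile(proj, q)
    drop <- abs(proj - cut) <= 1
    nm <- mask
    nm[px[drop, , drop = FALSE]] <- FALSE
    lab <- label_components(nm)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= 8L)
    if (length(keep) >= 2L) {
      return(purrr::map(keep, function(id) lab == id))
    }
  }
  NULL
}

.bridge_mask <- function(maskA, maskB, width_px) {
  bA <- boundary_pixels(maskA)
  bB <- boundary_pixels(maskB)
  d2 <- outer(bA[, 1], bB[, 1], "-")^2 + outer(bA[, 2], bB[, 2], "-")^2
  hit <- arrayInd(which.min(d2), dim(d2))
  canvas <- matrix(FALSE, nrow(maskA), ncol(maskA))
  canvas <- .raster_segment(canvas, bA[hit[1], ], bB[hit[2], ])
  EBImage::dilate(canvas, .disc_brush((width_px - 1) / 2)) > 0
}

# isotropic rescaling of a mask about its centroid (nearest-neighbour
# resampling), used for the scripted pre-fission growth
.scale_mask <- function(mask, factor) {
  if (abs(factor - 1) < 1e-12) return(mask)
  ctr <- .centroid(mask)
  px <- which(mask, arr.ind = TRUE)
  pad <- ceiling(max(1, (factor - 1) * max(dim(mask)) / 2)) + 1L
  rr <- max(1L, min(px[, 1]) - pad):min(nrow(mask), max(px[, 1]) + pad)
  cc <- max(1L, min(px[, 2]) - pad):min(ncol(mask), max(px[, 2]) + pad)
  grid <- expand.grid(r = rr, c = cc)
  qr <- round(ctr[1] + (grid$r - ctr[1]) / factor)
  qc <- round(ctr[2] + (grid$c - ctr[2]) / factor)
  ok <- qr >= 1 & qr <= nrow(mask) & qc >= 1 & qc <= ncol(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  hit <- ok & mask[cbind(pmin(pmax(qr, 1L), nrow(mask)),
                         pmin(pmax(qc, 1L), ncol(mask)))]
  out[cbind(grid$r[hit], grid$c[hit])] <- TRUE
  out
}

# relaxed post-fusion shape: the centroid segment dilated to a capsule of
# near-uniform width (so the watershed "separate" step sees one ridge)
.capsule_mask <- function(maskA, maskB) {
  r <- max(max(EBImage::distmap(maskA)), max(EBImage::distmap(maskB)))
  r <- min(4, max(2, round(r)))
  canvas <- matrix(FALSE, nrow(maskA), ncol(maskA))
  canvas <- .raster_segment(canvas, .centroid(maskA), .centroid(maskB))
  EBImage::dilate(canvas, .disc_brush(r)) > 0
}

#' Generate a ground-truthed synthetic movie
#'
#' Renders the scene described by `params`: objects are placed without
#' contact, scheduled fissions delete a 2-px band across the object (children
#' persist to the end of the movie), scheduled fusions replace the pair with
#' a relaxed capsule along their centroid axis, and "passing" contacts bridge
#' a pair for exactly one frame before restoring the originals. Every frame
#' is rendered as background noise `N(background_mean, background_sd)` with
#' object pixels at `N(object_intensity, object_sd)`, truncated at zero.
#'
#' The event table records each event at its last pre-event frame (the
#' reference frame of the scoring rule).
#'
#' @param params A [simulate_params()] object.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `mito_scene`: `movie` ([mito_movie()]),
#'   `truth_labels` (list of integer label matrices), `truth_events`
#'   (tibble: frame, type, object, partner, children), and `params`.
#' @examples
#' p <- simulate_params(field_px = 120, n_frames = 12, n_objects = 4,
#'                      events = NULL)
#' sc <- generate_movie(p, seed = 7)
#' length(sc$movie$frames)
#' @export
generate_movie <- function(params = simulate_params(), seed = 1L) {
  stopifnot(inherits(params, "mito_sim_params"))
  .with_seed(seed, {
    fp <- params$field_px
    masks <- .place_all(params)
    n0 <- length(masks)
    next_id <- n0 + 1L
    ev <- params$events
    if (is.null(ev)) {
      ev <- tibble::tibble(frame = integer(), type = character(),
                           object = integer(), partner = integer())
    }
    ev <- dplyr::arrange(ev, .data$frame)
    truth_events <- tibble::tibble(frame = integer(), type = character(),
                                   object = integer(), partner = integer(),
                                   children = character())
    live <- stats::setNames(masks, as.character(seq_len(n0)))
    pass_restore <- list()  # frame -> list(remove = id, restore = ids)
    truth_labels <- vector("list", params$n_frames)
    frames <- vector("list", params$n_frames)
    for (t in seq_len(params$n_frames)) {
      # restore objects after a passing contact
      pr <- pass_restore[[as.character(t)]]
      if (!is.null(pr)) {
        live[[as.character(pr$remove)]] <- NULL
        for (id in names(pr$restore)) live[[id]] <- pr$restore[[id]]
      }
      # events scheduled at frame t - 1 take effect in this frame
      due <- ev[ev$frame == t - 1L, ]
      for (i in seq_len(nrow(due))) {
        type <- due$type[i]
        a <- as.character(due$object[i])
        b <- as.character(due$partner[i])
        if (type == "fission") {
          children <- .cut_mask(live[[a]])
          if (is.null(children)) {
            stop("scheduled fission of object ", a, " failed to split",
                 call. = FALSE)
          }
          ids <- next_id + seq_along(children) - 1L
          next_id <- next_id + length(children)
          live[[a]] <- NULL
          for (j in seq_along(children)) live[[as.character(ids[j])]] <- children[[j]]
          truth_events <- dplyr::bind_rows(truth_events, tibble::tibble(
            frame = t - 1L, type = "fission", object = due$object[i],
            partner = NA_integer_, children = paste(ids, collapse = ",")))
        } else if (type == "fusion") {
          fused <- .capsule_mask(live[[a]], live[[b]])
          id <- next_id; next_id <- next_id + 1L
          live[[a]] <- NULL; live[[b]] <- NULL
          live[[as.character(id)]] <- fused
          truth_events <- dplyr::bind_rows(truth_events, tibble::tibble(
            frame = t - 1L, type = "fusion", object = due$object[i],
            partner = due$partner[i], children = as.character(id)))
        } else if (type == "passing") {
          joined <- live[[a]] | live[[b]] | .bridge_mask(live[[a]], live[[b]], 3L)
          id <- next_id; next_id <- next_id + 1L
          pass_restore[[as.character(t + 1L)]] <-
            list(remove = id, restore = stats::setNames(
              list(live[[a]], live[[b]]), c(a, b)))
          live[[a]] <- NULL; live[[b]] <- NULL
          live[[as.character(id)]] <- joined
          truth_events <- dplyr::bind_rows(truth_events, tibble::tibble(
            frame = t - 1L, type = "passing", object = due$object[i],
            partner = due$partner[i], children = as.character(id)))
        }
      }
      # scripted pre-fission growth: the object swells isotropically over
      # the growth window and is largest in the frame preceding the split
      eff <- live
      g <- params$fission_growth_per_frame
      if (g > 0 && nrow(ev) > 0L) {
        G <- params$fission_growth_frames
        fis <- ev[ev$type == "fission", ]
        for (i in seq_len(nrow(fis))) {
          f <- fis$frame[i]
          a <- as.character(fis$object[i])
          if (t >= f - G + 1L && t <= f && !is.null(eff[[a]])) {
            eff[[a]] <- .scale_mask(live[[a]], (1 + g)^(t - (f - G + 1L)))
          }
        }
      }
      lab <- matrix(0L, fp, fp)
      for (id in names(eff)) lab[eff[[id]]] <- as.integer(id)
      truth_labels[[t]] <- lab
      img <- stats::rnorm(fp * fp, params$background_mean, params$background_sd)
      dim(img) <- c(fp, fp)
      n_obj_px <- sum(lab > 0L)
      img[lab > 0L] <- stats::rnorm(n_obj_px, params$object_intensity,
                                    params$object_sd)
      frames[[t]] <- pmax(img, 0)
    }
    movie <- mito_movie(frames, params$pixel_size_um, params$frame_interval_s,
                        nucleus_centroid = c(fp / 2, fp / 2))
    structure(list(movie = movie, truth_labels = truth_labels,
                   truth_events = truth_events, params = params, seed = seed),
              class = "mito_scene")
  })
}

#' @export
print.mito_scene <- function(x, ...) {
  cat(sprintf("<mito_scene> %d frames, %d objects, %d scheduled events\n",
              x$params$n_frames, x$params$n_objects,
              nrow(x$truth_events)))
  invisible(x)
}

#' Synthetic per-event feature table with logistic ground truth
#'
#' Draws an 11-feature table of per-mitochondrion morphology with realistic
#' correlations (large-perimeter objects tend to have larger area, more
#' necks and lower solidity), then assigns fission/fusion labels from a
#' logistic model on the standardized perimeter and solidity,
#' `P(fission) = logistic(a z(perimeter) - b z(solidity) + c)`, with the
#' intercept `c` solved so that the expected fission fraction matches
#' `fission_fraction`. This encodes the association the classifier is
#' expected to recover: branched, high-perimeter organelles fragment while
#' compact, high-solidity organelles fuse.
#'
#' @param n_events Number of events (rows). Default 800.
#' @param fission_fraction Expected fraction of fission labels. Default 0.3
#'   (the roughly 70/30 fusion/fission imbalance of live-cell data).
#' @param a,b Logistic slopes on z(perimeter) and z(solidity). Default 2.
#' @param seed Integer seed.
#' @return A tibble with the 11 feature columns plus `event_call`.
#' @export
generate_event_features <- function(n_events = 800L, fission_fraction = 0.3,
                                    a = 2, b = 2, seed = 1L) {
  .with_seed(seed, {
    n <- as.integer(n_events)
    lper <- stats::rnorm(n, log(3), 0.6)           # log perimeter (um)
    perimeter_um <- exp(lper)
    z <- function(v) (v - mean(v)) / stats::sd(v)
    solidity <- stats::plogis(1.2 - 1.1 * z(lper) + stats::rnorm(n, 0, 0.9))
    area_um2 <- exp(1.35 * lper + stats::rnorm(n, -1.8, 0.35))
    n_necks <- stats::rpois(n, lambda = exp(-0.3 + 0.8 * z(lper)))
    min_neck_width_um <- ifelse(n_necks > 0,
                                stats::rgamma(n, shape = 4, rate = 12), NA_real_)
    nn_distance_um <- stats::rexp(n, rate = 1.2)
    neighbor_surface_um <- stats::rgamma(n, shape = 2, rate = 0.4)
    extent <- stats::rbeta(n, 4, 3)
    eccentricity <- stats::rbeta(n, 5, 2)
    euler_number <- 1L - stats::rbinom(n, 1, 0.05)
    orientation_deg <- stats::runif(n, 0, 90)
    eta <- a * z(perimeter_um) - b * z(solidity)
    cint <- stats::uniroot(function(cc) mean(stats::plogis(eta + cc)) -
                             fission_fraction, c(-20, 20))$root
    y <- stats::rbinom(n, 1, stats::plogis(eta + cint))
    tibble::tibble(area_um2, perimeter_um, extent, solidity, eccentricity,
                   euler_number, n_necks, min_neck_width_um, nn_distance_um,
                   neighbor_surface_um, orientation_deg,
                   event_call = factor(ifelse(y == 1, "fission", "fusion"),
                                       levels = c("fission", "fusion")))
  })
}
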