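# Morphological and positional characterization of single mitochondria:
# the six regionprops-style shape features, the neck detector built on the
# smoothed boundary pairwise-distance matrix, and the three positional
# features (nearest neighbour, neighbour surface, radial orientation).

#' Names of the 11 per-mitochondrion features
#' @return Character vector of length 11.
#' @export
mito_feature_names <- function() {
  c("area_um2", "perimeter_um", "extent", "solidity", "eccentricity",
    "euler_number", "n_necks", "min_neck_width_um", "nn_distance_um",
    "neighbor_surface_um", "orientation_deg")
}

# pixels inside (or on) the convex hull of the region's pixel centres
.hull_pixel_count <- function(px) {
  if (nrow(px) < 3L) return(nrow(px))
  h <- grDevices::chull(px[, 2], px[, 1])
  if (length(h) < 3L) return(nrow(px))
  vx <- px[h, 2]; vy <- px[h, 1]
  n <- length(vx)
  nxt <- c(2:n, 1L)
  area2 <- sum(vx * vy[nxt] - vx[nxt] * vy)  # signed polygon area x2
  if (area2 < 0) { vx <- rev(vx); vy <- rev(vy); nxt <- c(2:n, 1L) }
  rr <- seq(min(px[, 1]), max(px[, 1]))
  cc <- seq(min(px[, 2]), max(px[, 2]))
  grid <- expand.grid(r = rr, c = cc)
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(n)) {
    k2 <- nxt[k]
    cross <- (vx[k2] - vx[k]) * (grid$r - vy[k]) -
      (vy[k2] - vy[k]) * (grid$c - vx[k])
    inside <- inside & cross >= -1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

# second-central-moment summary with the 1/12 unit-pixel correction
.moments <- function(px) {
  x <- px[, 2]; y <- px[, 1]
  uxx <- stats::var(x) * (length(x) - 1) / length(x) + 1 / 12
  uyy <- stats::var(y) * (length(y) - 1) / length(y) + 1 / 12
  uxy <- stats::cov(x, y) * (length(x) - 1) / length(x)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  # major-axis angle, in math convention (x = col, y = -row), degrees
  theta <- 0.5 * atan2(2 * -uxy, uxx - uyy) * 180 / pi
  list(l1 = l1, l2 = l2, theta = theta,
       centroid = c(mean(y), mean(x)))
}

#' Six basic shape features of a single region
#'
#' Area (um^2), perimeter (traced boundary-walk length in um), extent
#' (pixels / bounding-box pixels), solidity (pixels / convex-hull pixels),
#' eccentricity of the second-moment-matched ellipse, and the Euler number
#' (1 minus the number of 4-connected holes).
#'
#' @param mask Logical matrix containing exactly one 8-connected region.
#' @param pixel_size_um um per pixel.
#' @param config A [run_config()] (controls the perimeter variant).
#' @return A one-row tibble.
#' @export
basic_shape_features <- function(mask, pixel_size_um, config = run_config()) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) != 1L) stop("mask must contain exactly one 8-connected region",
                           call. = FALSE)
  px <- which(mask, arr.ind = TRUE)
  npx <- nrow(px)
  bbox <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
  m <- .moments(px)
  tibble::tibble(
    area_um2 = npx * pixel_size_um^2,
    perimeter_um = perimeter_px(mask, config$perimeter_edge_count) * pixel_size_um,
    extent = npx / bbox,
    solidity = npx / .hull_pixel_count(px),
    eccentricity = if (m$l1 <= 0) 0 else sqrt(pmax(0, 1 - m$l2 / m$l1)),
    euler_number = 1L - count_holes(mask)
  )
}

# cyclic separable Gaussian smoothing of an n x n matrix over both indices
.smooth_cyclic <- function(D, width) {
  n <- nrow(D)
  half <- width %/% 2L
  sigma <- width / 4
  w <- stats::dnorm(seq(-half, half), sd = sigma)
  w <- w / sum(w)
  roll <- function(M, k) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    M[idx, , drop = FALSE]
  }
  S <- matrix(0, n, n)
  for (k in seq_along(w)) S <- S + w[k] * roll(D, k - half - 1L)
  S2 <- matrix(0, n, n)
  for (k in seq_along(w)) S2 <- S2 + w[k] * t(roll(t(S), k - half - 1L))
  S2
}

#' Neck (constriction/branch-point) detection for a single region
#'
#' Orders the boundary pixels by contour tracing, forms the cyclic matrix of
#' pairwise Euclidean distances between boundary pixels, smooths it with a
#' Gaussian kernel of `neck_kernel_px` taps applied cyclically over both
#' boundary indices, and takes the local minima (entries no larger than
#' their 8 index-neighbours, with plateaus of tied minima collapsed to one
#' representative). Pairs whose shorter boundary-arc separation is below
#' `3 * neck_kernel_px` are trivial near-neighbours along the contour and
#' are excluded. The number of surviving unordered pairs is the neck count;
#' the narrowest neck width is the raw boundary-to-boundary distance at the
#' surviving minimum.
#'
#' @param mask Logical matrix of one region.
#' @param pixel_size_um um per pixel.
#' @param config A [run_config()].
#' @return A one-row tibble with `n_necks` and `min_neck_width_um` (`NA`
#'   when there is no neck).
#' @export
neck_features <- function(mask, pixel_size_um, config = run_config()) {
  ct <- trace_contour(mask != 0)
  n <- nrow(ct)
  if (n < 12L) {
    return(tibble::tibble(n_necks = 0L, min_neck_width_um = NA_real_))
  }
  D <- as.matrix(stats::dist(ct))
  S <- .smooth_cyclic(D, config$neck_kernel_px)
  tol <- 1e-9
  # weak minima: entries no larger than any of their 8 cyclic
  # index-neighbours (ties allowed, so flat valley floors are kept whole)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  idx <- seq_len(n)
  cand <- matrix(TRUE, n, n)
  for (k in seq_len(nrow(shifts))) {
    ri <- ((idx - 1L + shifts$dr[k]) %% n) + 1L
    ci <- ((idx - 1L + shifts$dc[k]) %% n) + 1L
    cand <- cand & (S <= S[ri, ci] + tol)
  }
  # arc-separation exclusion: near-diagonal pairs are trivial contour
  # neighbours, not necks
  arc <- abs(outer(idx, idx, "-"))
  arc <- pmin(arc, n - arc)
  cand[arc < 3L * config$neck_kernel_px] <- FALSE
  if (!any(cand)) {
    return(tibble::tibble(n_necks = 0L, min_neck_width_um = NA_real_))
  }
  # an isolated minimum is a connected plateau of weak minima whose every
  # outside neighbour is strictly larger: a valley running into smaller
  # values (e.g. the flat side-to-side floor of a straight bar, which
  # drains into the end caps) is not a neck
  comp <- .cyclic_components(cand)
  pairs <- list()
  keys <- character(0)
  for (id in seq_len(max(comp))) {
    hits <- which(comp == id, arr.ind = TRUE)
    vmin <- min(S[comp == id])
    ok <- TRUE
    for (k in seq_len(nrow(shifts))) {
      ri <- ((hits[, 1] - 1L + shifts$dr[k]) %% n) + 1L
      ci <- ((hits[, 2] - 1L + shifts$dc[k]) %% n) + 1L
      nb <- cbind(ri, ci)
      outsider <- comp[nb] != id
      if (any(outsider) && min(S[nb[outsider, , drop = FALSE]]) <= vmin + tol) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # canonical (unordered) entry set, so a component and its mirror across
    # the matrix diagonal count as the same neck
    can <- cbind(pmin(hits[, 1], hits[, 2]), pmax(hits[, 1], hits[, 2]))
    keyset <- can[order(can[, 1], can[, 2]), , drop = FALSE]
    key <- paste(keyset[, 1], keyset[, 2], sep = "-", collapse = ";")
    if (key %in% keys) next
    keys <- c(keys, key)
    raw <- D[hits]
    ord <- order(raw, can[, 1], can[, 2])
    pairs[[length(pairs) + 1L]] <- c(can[ord[1], ], min(raw))
  }
  if (length(pairs) == 0L) {
    return(tibble::tibble(n_necks = 0L, min_neck_width_um = NA_real_))
  }
  tab <- do.call(rbind, pairs)
  tibble::tibble(n_necks = nrow(tab),
                 min_neck_width_um = min(tab[, 3]) * pixel_size_um)
}

# connected components of a logical matrix treating both indices as cyclic
.cyclic_components <- function(mask) {
  n <- nrow(mask)
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) > 1L) {
    # merge components that touch across the cyclic wrap of either index
    pairs <- NULL
    a <- lab[1, ]; b <- lab[n, ]
    keep <- a > 0L & b > 0L & a != b
    pairs <- rbind(pairs, cbind(a[keep], b[keep]))
    a <- lab[, 1]; b <- lab[, n]
    keep <- a > 0L & b > 0L & a != b
    pairs <- rbind(pairs, cbind(a[keep], b[keep]))
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      g <- igraph::make_graph(edges = as.vector(t(pairs)), n = max(lab),
                              directed = FALSE)
      memb <- igraph::components(g)$membership
      lab[lab > 0L] <- memb[lab[lab > 0L]]
      lab <- .relabel_sequential(lab)
    }
  }
  lab
}

#' Positional features of one region within a labeled frame
#'
#' Nearest-neighbour distance (um of cytosol between boundaries), total
#' boundary length of other regions within `neighbor_radius_um`, and the
#' acute angle between the region's second-moment major axis and the radial
#' line from the nucleus centroid to the region centroid.
#'
#' @param region_id Label of the region of interest.
#' @param labels Integer label matrix.
#' @param pixel_size_um um per pixel.
#' @param nucleus_centroid Optional `c(row, col)` in pixels; `NA` orientation
#'   when absent.
#' @param config A [run_config()].
#' @return A one-row tibble with `nn_distance_um`, `neighbor_surface_um`,
#'   `orientation_deg` (NA where undefined).
#' @export
positional_features <- function(region_id, labels, pixel_size_um,
                                nucleus_centroid = NULL,
                                config = run_config()) {
  mask <- labels == region_id
  if (!any(mask)) stop("region ", region_id, " absent from frame", call. = FALSE)
  others <- sort(setdiff(unique(labels[labels > 0L]), region_id))
  if (length(others) == 0L) {
    nn <- NA_real_; surf <- NA_real_
  } else {
    dt <- EBImage::distmap(!mask)  # distance of every pixel to the region
    nn <- max(0, min(dt[labels > 0L & !mask]) - 1) * pixel_size_um
    surf <- 0
    radius_px <- config$neighbor_radius_um / pixel_size_um
    for (id in others) {
      ct <- trace_contour(labels == id)
      m <- nrow(ct)
      if (m < 2L) {
        steps <- 0
        contrib <- rep(1, m)  # isolated pixel: unit boundary length
      } else {
        nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
        steps <- sqrt(rowSums((nxt - ct)^2))
        prev <- c(steps[m], steps[-m])
        contrib <- (steps + prev) / 2
      }
      d <- dt[ct] - 1
      surf <- surf + sum(contrib[d <= radius_px])
    }
    surf <- surf * pixel_size_um
  }
  if (is.null(nucleus_centroid)) {
    ori <- NA_real_
  } else {
    px <- which(mask, arr.ind = TRUE)
    m <- .moments(px)
    radial <- atan2(-(m$centroid[1] - nucleus_centroid[1]),
                    m$centroid[2] - nucleus_centroid[2]) * 180 / pi
    d <- abs(m$theta - radial) %% 180
    ori <- min(d, 180 - d)
  }
  tibble::tibble(nn_distance_um = nn, neighbor_surface_um = surf,
                 orientation_deg = ori)
}

#' Feature table for confirmed events
#'
#' Measures the 11 features of each confirmed fission/fusion event on its
#' reference frame — the frame directly preceding the event. Stable,
#' unconfirmed and appearance/disappearance records are excluded.
#'
#' @param events Tibble from [classify_events()].
#' @param labels List of integer label matrices aligned with the movie.
#' @param movie The [mito_movie()] the labels came from (for pixel size and
#'   nucleus centroid), or a bare pixel size.
#' @param config A [run_config()].
#' @return A tibble: the 11 feature columns plus `event_call`, `frame`,
#'   `region_id`.
#' @export
feature_table <- function(events, labels, movie, config = run_config()) {
  if (inherits(movie, "mito_movie")) {
    ps <- movie$pixel_size_um
    nuc <- movie$nucleus_centroid
  } else {
    ps <- as.numeric(movie)
    nuc <- NULL
  }
  ev <- dplyr::filter(events, .data$call %in% c("fission", "fusion"))
  rows <- purrr::pmap(list(ev$frame, ev$region_id, ev$call), function(f, id, call) {
    lab <- labels[[f]]
    if (!any(lab == id)) stop("event references missing region ", id,
                              " in frame ", f, call. = FALSE)
    mask <- lab == id
    dplyr::bind_cols(
      basic_shape_features(mask, ps, config),
      neck_features(mask, ps, config),
      positional_features(id, lab, ps, nuc, config),
      tibble::tibble(event_call = call, frame = f, region_id = id))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      as.list(rep(NA_real_, 11)), mito_feature_names()))[0, ]
    out$event_call <- character(0)
    out$frame <- integer(0)
    out$region_id <- integer(0)
  }
  out$event_call <- factor(out$event_call, levels = c("fission", "fusion"))
  out
}
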