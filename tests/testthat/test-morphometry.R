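cfg <- run_config()

test_that("basic features are exact on a solid square", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- basic_shape_features(sq, 0.1, cfg)
  expect_equal(f$area_um2, 1)
  expect_equal(f$extent, 1)
  expect_equal(f$solidity, 1)
  expect_equal(f$perimeter_um, 3.6)  # 36 boundary steps x 0.1 um
  expect_equal(f$euler_number, 1L)
  expect_equal(f$eccentricity, 0)
})

test_that("the Euler number counts holes with the complementary connectivity", {
  expect_equal(basic_shape_features(generate_shape("disk", 21), 0.1,
                                    cfg)$euler_number, 1L)
  expect_equal(basic_shape_features(generate_shape("annulus", 21), 0.1,
                                    cfg)$euler_number, 0L)
  two <- matrix(TRUE, 9, 16)
  two[4:6, 4:6] <- FALSE
  two[4:6, 11:13] <- FALSE
  expect_equal(basic_shape_features(two, 0.1, cfg)$euler_number, -1L)
  # diagonal foreground must not leak through diagonal background
  diagonal_pinch <- sketch_frame(c("AAA.AAA",
                                   "AAAA.AA",
                                   "AAA.AAA"))
  expect_equal(max(label_components(diagonal_pinch == 1)), 1L)
})

test_that("solidity matches an independent point-in-polygon hull oracle", {
  shapes <- list(generate_shape("L_shape", 24),
                 generate_shape("Y_branch", 26),
                 generate_shape("two_blob_dumbbell", 20))
  for (m in shapes) {
    px <- which(m, arr.ind = TRUE)
    h <- grDevices::chull(px[, 2], px[, 1])
    # inflate the hull polygon infinitesimally about its centroid so pixel
    # centres on the boundary are classified as inside
    cx <- mean(px[h, 2]); cy <- mean(px[h, 1])
    bx <- cx + (px[h, 2] - cx) * (1 + 1e-6)
    by <- cy + (px[h, 1] - cy) * (1 + 1e-6)
    rr <- seq(min(px[, 1]), max(px[, 1]))
    cc <- seq(min(px[, 2]), max(px[, 2]))
    grid <- as.matrix(expand.grid(x = cc, y = rr))
    inside <- mgcv::in.out(cbind(c(bx, bx[1]), c(by, by[1])), grid)
    want <- nrow(px) / max(sum(inside), nrow(px))
    got <- basic_shape_features(m, 0.1, cfg)$solidity
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("empty and multi-component masks are rejected", {
  expect_error(basic_shape_features(matrix(FALSE, 4, 4), 0.1, cfg), "empty")
  m <- matrix(FALSE, 8, 8); m[2, 2] <- TRUE; m[6, 6] <- TRUE
  expect_error(basic_shape_features(m, 0.1, cfg), "one 8-connected")
})

test_that("neck detection finds scripted constrictions and nothing else", {
  db <- generate_shape("two_blob_dumbbell", 24, bridge_px = 3)
  nf <- neck_features(db, 0.1, cfg)
  expect_equal(nf$n_necks, 1L)
  # width equals the bridge width within one pixel (0.1 um)
  expect_equal(nf$min_neck_width_um,
               oracle_min_cross_distance(db) * 0.1, tolerance = 0.1)
  expect_lt(abs(nf$min_neck_width_um - 0.3), 0.11)
  expect_equal(neck_features(generate_shape("bar", 30), 0.1, cfg)$n_necks, 0L)
  expect_equal(neck_features(generate_shape("disk", 25), 0.1, cfg)$n_necks, 0L)
  # too-small regions degrade gracefully
  tiny <- matrix(FALSE, 4, 4); tiny[2, 2:3] <- TRUE
  nt <- neck_features(tiny, 0.1, cfg)
  expect_equal(nt$n_necks, 0L)
  expect_true(is.na(nt$min_neck_width_um))
})

test_that("neck features match the explicit-loop oracle on varied fixtures", {
  fixtures <- list(generate_shape("two_blob_dumbbell", 20),
                   generate_shape("two_blob_dumbbell", 28, bridge_px = 5),
                   generate_shape("Y_branch", 24),
                   generate_shape("Y_branch", 32),
                   generate_shape("bar", 24),
                   generate_shape("L_shape", 22),
                   generate_shape("disk", 19),
                   generate_shape("annulus", 19))
  for (m in fixtures) {
    got <- neck_features(m, 1, cfg)
    want <- oracle_necks(m, cfg$neck_kernel_px, 1)
    expect_equal(got$n_necks, want$n_necks)
    if (want$n_necks > 0) {
      expect_equal(got$min_neck_width_um, want$min_width)
    }
  }
  yb <- generate_shape("Y_branch", 28)
  expect_gte(neck_features(yb, 1, cfg)$n_necks, 1L)
})

test_that("positional features use boundary-to-boundary distances", {
  lab <- matrix(0L, 24, 30)
  lab[6:15, 4:13] <- 1L   # 10x10 square
  lab[6:15, 17:26] <- 2L  # second square, 3-px gap
  pf <- positional_features(1L, lab, 0.2, nucleus_centroid = NULL, cfg)
  expect_equal(pf$nn_distance_um, 0.6)  # 3 px x 0.2 um
  expect_true(is.na(pf$orientation_deg))
  # the whole neighbour boundary lies within 10 um here
  expect_equal(pf$neighbor_surface_um, 36 * 0.2)
  lone <- matrix(0L, 10, 10); lone[3:6, 3:6] <- 1L
  pl <- positional_features(1L, lone, 0.1, NULL, cfg)
  expect_true(is.na(pl$nn_distance_um))
  expect_true(is.na(pl$neighbor_surface_um))
  expect_error(positional_features(9L, lab, 0.1, NULL, cfg), "absent")
})

test_that("neighbour surface honours the radius cutoff", {
  lab <- matrix(0L, 30, 200)
  lab[14:17, 3:6] <- 1L
  lab[14:17, 30:33] <- 2L    # ~2.3 um away at 0.1 um/px
  lab[14:17, 150:153] <- 3L  # ~14 um away: beyond the 10 um radius
  pf <- positional_features(1L, lab, 0.1, NULL, cfg)
  near_only <- positional_features(1L, lab[, 1:100, drop = FALSE], 0.1, NULL, cfg)
  expect_equal(pf$neighbor_surface_um, near_only$neighbor_surface_um)
})

test_that("orientation is the acute angle between major axis and the radial line", {
  lab <- matrix(0L, 40, 40)
  lab[19:22, 5:30] <- 1L  # horizontal bar
  # nucleus on the bar axis: radial line parallel to the major axis
  p0 <- positional_features(1L, lab, 0.1, nucleus_centroid = c(20.5, 35), cfg)
  expect_equal(p0$orientation_deg, 0, tolerance = 1e-6)
  # nucleus straight above the centroid: perpendicular
  p90 <- positional_features(1L, lab, 0.1, nucleus_centroid = c(2, 17.5), cfg)
  expect_equal(p90$orientation_deg, 90, tolerance = 1e-6)
})

test_that("features scale correctly with pixel size and are 90-degree invariant", {
  m <- generate_shape("two_blob_dumbbell", 22)
  f1 <- dplyr::bind_cols(basic_shape_features(m, 0.1, cfg),
                         neck_features(m, 0.1, cfg))
  f2 <- dplyr::bind_cols(basic_shape_features(m, 0.2, cfg),
                         neck_features(m, 0.2, cfg))
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$perimeter_um, 2 * f1$perimeter_um)
  expect_equal(f2$min_neck_width_um, 2 * f1$min_neck_width_um)
  for (nm in c("extent", "solidity", "eccentricity", "euler_number",
               "n_necks")) {
    expect_equal(f2[[nm]], f1[[nm]])
  }
  r <- t(m[nrow(m):1, , drop = FALSE])  # 90-degree rotation
  f3 <- dplyr::bind_cols(basic_shape_features(r, 0.1, cfg),
                         neck_features(r, 0.1, cfg))
  for (nm in setdiff(names(f1), "min_neck_width_um")) {
    expect_equal(f3[[nm]], f1[[nm]])
  }
})

test_that("arbitrary rotations move smooth-shape features by only a few percent", {
  # rasterize an ellipse directly at 0 and 30 degrees
  mk <- function(theta) {
    n <- 41
    idx <- expand.grid(r = seq_len(n) - 21, c = seq_len(n) - 21)
    x <- idx$c * cos(theta) + idx$r * sin(theta)
    y <- -idx$c * sin(theta) + idx$r * cos(theta)
    matrix((x / 15)^2 + (y / 7)^2 <= 1, n, n)
  }
  f0 <- basic_shape_features(mk(0), 0.1, cfg)
  f30 <- basic_shape_features(mk(pi / 6), 0.1, cfg)
  expect_lt(abs(f30$area_um2 - f0$area_um2) / f0$area_um2, 0.05)
  expect_lt(abs(f30$perimeter_um - f0$perimeter_um) / f0$perimeter_um, 0.05)
  expect_lt(abs(f30$solidity - f0$solidity) / f0$solidity, 0.05)
})

test_that("the feature table has exactly 11 features measured on the pre-event frame", {
  p0 <- simulate_params(field_px = 180, n_frames = 20, n_objects = 8)
  ev <- schedule_events(p0, n_fission = 2, n_fusion = 2, n_passing = 0)
  p <- simulate_params(field_px = 180, n_frames = 20, n_objects = 8,
                       events = ev)
  sc <- generate_movie(p, seed = 17)
  events <- classify_events(sc$truth_labels, cfg)
  ft <- feature_table(events, sc$truth_labels, sc$movie, cfg)
  expect_identical(setdiff(names(ft), c("event_call", "frame", "region_id")),
                   mito_feature_names())
  expect_length(mito_feature_names(), 11L)
  confirmed <- sum(events$call %in% c("fission", "fusion"))
  expect_equal(nrow(ft), confirmed)
  # areas match the ground-truth masks of the same frame exactly
  for (i in seq_len(nrow(ft))) {
    truth_area <- sum(sc$truth_labels[[ft$frame[i]]] == ft$region_id[i])
    expect_equal(ft$area_um2[i], truth_area * 0.1^2)
  }
  # stable regions are excluded; empty input yields an empty table
  expect_false(any(ft$event_call == "stable"))
  empty <- feature_table(events[events$call == "stable", ],
                         sc$truth_labels, sc$movie, cfg)
  expect_equal(nrow(empty), 0L)
  expect_identical(setdiff(names(empty), c("event_call", "frame", "region_id")),
                   mito_feature_names())
})
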