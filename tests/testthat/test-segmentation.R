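cfg <- run_config()

test_that("the top-hat matches a direct min/max-filter oracle and flattens background", {
  # direct oracle: replicate-pad once by the full iterated-element radius,
  # then iterated 3x3 minimum and maximum filters
  minmax_filter <- function(m, fun, times) {
    for (it in seq_len(times)) {
      out <- m
      for (r in 2:(nrow(m) - 1)) {
        for (c in 2:(ncol(m) - 1)) {
          out[r, c] <- fun(m[(r - 1):(r + 1), (c - 1):(c + 1)])
        }
      }
      m <- out
    }
    m
  }
  set.seed(7)
  frame <- matrix(runif(24 * 24, 0, 50), 24, 24)
  pad <- 6L
  ridx <- c(rep(1, pad), 1:24, rep(24, pad))
  padded <- frame[ridx, ridx]
  opened <- minmax_filter(minmax_filter(padded, min, 5), max, 5)
  opened <- opened[pad + 1:24, pad + 1:24]
  expected <- pmax(frame - opened, 0)
  expect_equal(preprocess_frame(frame, cfg), expected, tolerance = 1e-8)
  # a constant frame has no structure above its background
  expect_equal(max(preprocess_frame(matrix(5, 20, 20), cfg)), 0)
  # a lone bright pixel is thinner than the element: fully preserved
  spike <- matrix(0, 21, 21); spike[11, 11] <- 7
  expect_equal(preprocess_frame(spike, cfg)[11, 11], 7)
})

test_that("a smooth planar ramp is removed up to slope-scale residue", {
  set.seed(8)
  base <- matrix(0, 32, 32)
  base[10:13, 8:24] <- 40  # a thin bright bar
  ramp <- outer(seq_len(32), seq_len(32), function(r, c) 0.1 * r + 0.05 * c)
  out_plain <- preprocess_frame(base, cfg)
  out_ramp <- preprocess_frame(base + ramp, cfg)
  # the bar survives at nearly full amplitude, the ramp itself vanishes
  # up to slope x window-size residue
  expect_lt(max(abs(out_ramp - out_plain)), 0.15 * 11)
  expect_equal(out_ramp[12, 16], out_plain[12, 16], tolerance = 0.05)
})

test_that("threshold sits exactly threshold_sigma_mult background-SDs above the mode", {
  v <- generate_intensity_profile(100000, mode_value = 100, sigma = 1.5,
                                  seed = 13)
  th <- estimate_threshold(v, cfg)
  expect_equal((th$lower_limit_sqrt - th$mode_sqrt) / th$sigma_sqrt,
               cfg$threshold_sigma_mult)
  expect_equal(th$lower_limit_raw, th$lower_limit_sqrt^2)
  expect_gt(th$lower_limit_sqrt, th$mode_sqrt)
  # the estimator recovers the generating background SD (sqrt space)
  expect_equal(th$sigma_sqrt, 1.5, tolerance = 0.1)
  expect_equal(th$mode_sqrt, 10, tolerance = 0.15)
  k5 <- estimate_threshold(v, run_config(threshold_sigma_mult = 5))
  expect_equal((k5$lower_limit_sqrt - k5$mode_sqrt) / k5$sigma_sqrt, 5)
})

test_that("left-mirrored sigma matches the closed form on a symmetric triangular profile", {
  # triangular density on [m - h, m + h] peaked at m, sampled on a
  # deterministic quantile grid; the RMS deviation of the left half about
  # the peak has the closed form h / sqrt(6):
  # E[x^2 | x <= 0] = (int x^2 (x+h) dx) / (int (x+h) dx) = h^2 / 6
  m <- 12; h <- 2
  p <- (seq_len(20001) - 0.5) / 20001
  q <- ifelse(p < 0.5, h * (sqrt(2 * p) - 1), h * (1 - sqrt(2 * (1 - p))))
  s <- m + q
  th <- estimate_threshold(s^2, cfg)
  expect_equal(th$mode_sqrt, m, tolerance = 0.02 * h)
  expect_equal(th$sigma_sqrt, h / sqrt(6), tolerance = 0.02 * h)
})

test_that("degenerate intensity profiles are rejected", {
  expect_error(estimate_threshold(rep(4, 2000), cfg), "constant")
  expect_error(estimate_threshold(runif(500), cfg), "1000")
})

test_that("a bright shoulder cannot inflate the threshold (Monte Carlo)", {
  for (seed in 1:8) {
    bg <- generate_intensity_profile(40000, mode_value = 100, sigma = 1,
                                     object_fraction = 0, seed = seed)
    both <- generate_intensity_profile(40000, mode_value = 100, sigma = 1,
                                       object_fraction = 0.15,
                                       object_shift = 8, seed = seed)
    t_bg <- estimate_threshold(bg, cfg)$lower_limit_raw
    t_both <- estimate_threshold(both, cfg)$lower_limit_raw
    expect_lt(abs(t_both - t_bg) / t_bg, 0.05)
  }
})

test_that("binarization separates, cleans and labels as specified", {
  thr <- structure(list(mode_sqrt = 1, sigma_sqrt = 1, lower_limit_sqrt = 4,
                        lower_limit_raw = 16), class = "mito_threshold")
  # everything below threshold: no regions
  expect_equal(max(binarize_and_label(matrix(10, 30, 30), thr, cfg)), 0)
  # two disks separated by a 5-px gap: two regions
  f <- matrix(0, 30, 46)
  for (ctr in list(c(15, 12), c(15, 34))) {
    idx <- which(outer(seq_len(30), seq_len(46), function(r, c) {
      (r - ctr[1])^2 + (c - ctr[2])^2 <= 64
    }))
    f[idx] <- 100
  }
  lab <- binarize_and_label(f, thr, cfg)
  expect_equal(max(lab), 2L)
  # a dumbbell with a 2-px waist is split by the watershed
  db <- matrix(0, 24, 44)
  for (ctr in list(c(12, 11), c(12, 33))) {
    idx <- which(outer(seq_len(24), seq_len(44), function(r, c) {
      (r - ctr[1])^2 + (c - ctr[2])^2 <= 81
    }))
    db[idx] <- 100
  }
  db[11:12, 11:33] <- 100  # 2-px bridge
  lab2 <- binarize_and_label(db, thr, cfg)
  expect_equal(max(lab2), 2L)
  # speckles below 4 px are despeckled away
  sp <- matrix(0, 20, 20); sp[3, 3] <- 100; sp[10, 10] <- 100
  expect_equal(max(binarize_and_label(sp, thr, cfg)), 0L)
})

test_that("binarization is invariant under monotone intensity rescaling", {
  thr <- structure(list(mode_sqrt = 1, sigma_sqrt = 1, lower_limit_sqrt = 4,
                        lower_limit_raw = 16), class = "mito_threshold")
  set.seed(31)
  f <- matrix(runif(900, 0, 40), 30, 30)
  lab <- binarize_and_label(f, thr, cfg)
  g <- function(x) x^3 + 2 * x  # strictly monotone
  thr2 <- structure(list(mode_sqrt = 1, sigma_sqrt = 1,
                         lower_limit_sqrt = sqrt(g(16)),
                         lower_limit_raw = g(16)), class = "mito_threshold")
  expect_identical(binarize_and_label(g(f), thr2, cfg), lab)
})

test_that("segmentation recovers the object count of well-separated scenes exactly", {
  p <- simulate_params(field_px = 160, n_frames = 4, n_objects = 6,
                       events = NULL)
  for (seed in c(11, 29)) {
    sc <- generate_movie(p, seed = seed)
    seg <- segment_movie(sc$movie, cfg)
    truth_n <- vapply(sc$truth_labels,
                      function(l) length(unique(l[l > 0])), numeric(1))
    expect_equal(vapply(seg$labels, max, numeric(1)), truth_n)
  }
})

test_that("per-frame thresholding mode estimates one model per frame", {
  p <- simulate_params(field_px = 120, n_frames = 3, n_objects = 3,
                       events = NULL)
  sc <- generate_movie(p, seed = 2)
  seg1 <- segment_movie(sc$movie, cfg)
  expect_equal(nrow(seg1$thresholds), 1L)
  seg2 <- segment_movie(sc$movie, run_config(threshold_per_frame = TRUE))
  expect_equal(nrow(seg2$thresholds), 3L)
})
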