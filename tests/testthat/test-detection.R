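test_that("a single noise-free ring is found with sub-pixel accuracy", {
  im <- imaging_params(frame_size = 160L, noise_model = "none")
  p <- population_params(n_vesicles = 1, radius_median = 40, radius_shape = 0)
  v <- sample_population(p, seed = 1, frame_size = 160)
  v$x <- 74; v$y <- 77.5
  fr <- render_frame(v, im)
  det <- detect_vesicles(fr)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 74), 1)
  expect_lt(abs(det$y - 77.5), 1)
  expect_lt(abs(det$radius - 40) / 40, 0.02)
  expect_gte(det$quality, 0.5)
})

test_that("two rings are both recovered and matched to ground truth", {
  im <- imaging_params(frame_size = 256L)
  p <- population_params(n_vesicles = 2, radius_median = 35,
                         radius_shape = 0.15)
  v <- sample_population(p, seed = 13, frame_size = 256)
  fr <- render_frame(v, im, seed = 14)
  det <- detect_vesicles(fr)
  expect_equal(nrow(det), 2L)
  m <- match_truth(det, v)
  expect_setequal(m, 1:2)
  for (i in 1:2) {
    expect_lt(abs(det$radius[i] - v$radius[m[i]]) / v$radius[m[i]], 0.05)
  }
})

test_that("a blank frame yields an empty contour table, not an error", {
  im <- imaging_params(frame_size = 128L)
  v <- sample_population(population_params(n_vesicles = 1), seed = 1,
                         frame_size = 128)[0, ]
  fr <- render_frame(v, im, seed = 3)
  det <- detect_vesicles(fr)
  expect_s3_class(det, "vesicle_contours")
  expect_equal(nrow(det), 0L)
})

test_that("single-channel frames are rejected", {
  fr <- make_ring_frame()
  fr$channels <- fr$channels[, , 1, drop = FALSE]
  expect_error(detect_vesicles(fr), ">= 2 channels")
})

test_that("detection is translation-equivariant within half a pixel", {
  im <- imaging_params(frame_size = 200L, noise_model = "none")
  p <- population_params(n_vesicles = 1, radius_median = 35, radius_shape = 0)
  v <- sample_population(p, seed = 2, frame_size = 200)
  v$x <- 90; v$y <- 95
  d0 <- detect_vesicles(render_frame(v, im))
  for (shift in list(c(8, 0), c(0, -11), c(6, 5))) {
    v2 <- v; v2$x <- v$x + shift[1]; v2$y <- v$y + shift[2]
    d1 <- detect_vesicles(render_frame(v2, im))
    expect_equal(nrow(d1), 1L)
    expect_lt(abs((d1$x - d0$x) - shift[1]), 0.5)
    expect_lt(abs((d1$y - d0$y) - shift[2]), 0.5)
  }
})

test_that("detection recovers >= 95% of a dispersed noisy population", {
  im <- imaging_params(frame_size = 320L)
  p <- population_params(n_vesicles = 24, radius_median = 38,
                         radius_shape = 0.25, radius_min = 25)
  sim <- simulate_frames(p, im, seed = 17, per_frame = 3)
  found <- 0L; total <- 0L
  for (fr in sim$frames) {
    tr <- fr$truth
    det <- detect_vesicles(fr)
    total <- total + nrow(tr)
    if (nrow(det) == 0) next
    m <- match_truth(det, tr)
    ok <- abs(det$radius - tr$radius[m]) / tr$radius[m] < 0.05
    found <- found + length(unique(m[ok]))
  }
  expect_gte(found / total, 0.95)
})

test_that("angular profile of a uniform ring is flat and conservative", {
  fr <- make_ring_frame(values = c(100, 40))
  contour <- list(x = 64, y = 64, radius = 40, ring_width = 6)
  for (nb in c(12L, 36L, 72L)) {
    prof <- extract_angular_profile(fr, contour, n_bins = nb)
    expect_equal(prof$mean[, 1], rep(100, nb))
    expect_equal(prof$mean[, 2], rep(40, nb))
    # conservation: weighted bin sums equal the total annulus intensity
    xg <- matrix(0:127, 128, 128, byrow = TRUE)
    yg <- matrix(0:127, 128, 128)
    sel <- abs(sqrt((xg - 64)^2 + (yg - 64)^2) - 40) <= 3
    expect_equal(sum(prof$count * prof$mean[, 1]),
                 sum(fr$channels[, , 1][sel]))
    expect_equal(sum(prof$count), sum(sel))
  }
})

test_that("two-level rings profile into two plateaus with soft boundaries", {
  fr <- make_ring_frame(split_ch = 1, split_start = 0, split_width = pi,
                        hi = 100, lo = 20, values = c(0, 50))
  contour <- list(x = 64, y = 64, radius = 40, ring_width = 6)
  prof <- extract_angular_profile(fr, contour, n_bins = 36L)
  expect_true(all(abs(prof$mean[2:17, 1] - 100) < 1e-9))
  expect_true(all(abs(prof$mean[20:35, 1] - 20) < 1e-9))
  # boundary bins mix the two levels
  expect_true(all(prof$mean[c(1, 18, 19, 36), 1] >= 20 &
                  prof$mean[c(1, 18, 19, 36), 1] <= 100))
})

test_that("rotating the frame by pi/2 cyclically shifts the profile", {
  fr <- make_ring_frame(split_ch = 1, split_start = 0, split_width = 0.9 * pi,
                        hi = 120, lo = 30, values = c(0, 50))
  contour <- list(x = 64, y = 64, radius = 40, ring_width = 6)
  p0 <- extract_angular_profile(fr, contour, n_bins = 36L)
  # a quarter-turn about (64, 64) maps the integer pixel grid onto itself,
  # so the rotated phantom's annulus pixels are exactly congruent and the
  # profile must shift by exactly n_bins / 4 bins
  fr90 <- make_ring_frame(split_ch = 1, split_start = pi / 2,
                          split_width = 0.9 * pi, hi = 120, lo = 30,
                          values = c(0, 50))
  p1 <- extract_angular_profile(fr90, contour, n_bins = 36L)
  expect_equal(p1$mean[, 1],
               p0$mean[((seq_len(36) - 1 - 9) %% 36) + 1, 1],
               tolerance = 1e-9)
})

test_that("clipped annuli raise an error", {
  fr <- make_ring_frame()
  contour <- list(x = 64, y = 64, radius = 62, ring_width = 6)
  expect_error(extract_angular_profile(fr, contour), "clipped annulus")
})
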