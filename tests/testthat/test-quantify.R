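test_that("background is exact on noise-free frames and unbiased under Poisson noise", {
  im <- imaging_params(frame_size = 200L, noise_model = "none",
                       background = c(50, 80))
  p <- population_params(n_vesicles = 1, radius_median = 40, radius_shape = 0)
  v <- sample_population(p, seed = 3, frame_size = 200)
  fr <- render_frame(v, im)
  det <- detect_vesicles(fr)
  expect_equal(estimate_background(fr, det), c(50, 80))

  imp <- imaging_params(frame_size = 200L, background = c(50, 80))
  frp <- render_frame(v, imp, seed = 4)
  bg <- estimate_background(frp, detect_vesicles(frp))
  # median of Poisson(50) over a large area is within one count of 50
  expect_lt(abs(bg[1] - 50), 1.01)
  expect_lt(abs(bg[2] - 80), 1.01)
})

test_that("frames fully covered by vesicle masks yield a background error", {
  fr <- make_ring_frame(size = 64, cx = 32, cy = 32, R = 20, rw = 6)
  big <- data.frame(x = 32, y = 32, radius = 20, ring_width = 200,
                    quality = 1)
  expect_error(estimate_background(fr, big), "no background pixels")
})

test_that("compute_partition implements the defining fractional-intensity formula", {
  labels <- c(rep("Lo", 10), rep("excluded", 4), rep("Ld", 18),
              rep("excluded", 4))
  seg <- structure(list(labels = labels, ld_arc = c(start = 15, end = 32),
                        lo_arc = c(start = 1, end = 10),
                        boundary_exclusion = 2, separation_score = 10),
                   class = "phase_segmentation")
  mk <- function(lo, ld) {
    m <- matrix(0, 36, 2)
    m[labels == "Lo", 2] <- lo
    m[labels == "Ld", 2] <- ld
    m[, 1] <- 50
    make_profile(m)
  }
  rec <- compute_partition(mk(60, 40), seg, background = c(0, 0))
  expect_equal(rec$f_p_Lo, 0.6)
  expect_equal(rec$f_p_Lo + rec$f_p_Ld, 1)
  rec2 <- compute_partition(mk(35, 35), seg, background = c(0, 0))
  expect_equal(rec2$f_p_Lo, 0.5)
  # gain invariance: rescaling the construct channel leaves f unchanged
  rec3 <- compute_partition(mk(600, 400), seg, background = c(0, 0))
  expect_equal(rec3$f_p_Lo, rec$f_p_Lo)
  # background subtraction and clamping
  rec4 <- compute_partition(mk(60, 10), seg, background = c(0, 20))
  expect_equal(rec4$I_Ld, 0)
  expect_match(rec4$flags, "clamped_Ld")
  expect_equal(rec4$f_p_Lo, 1)
  expect_error(compute_partition(mk(5, 5), seg, background = c(0, 10)),
               "zero signal")
})

test_that("arc means are pixel-count weighted (equal to per-pixel means)", {
  labels <- c(rep("Lo", 6), rep("Ld", 6))
  seg <- structure(list(labels = labels, ld_arc = c(start = 7, end = 12),
                        lo_arc = c(start = 1, end = 6),
                        boundary_exclusion = 0, separation_score = 10),
                   class = "phase_segmentation")
  m <- matrix(0, 12, 2)
  m[, 2] <- c(10, 10, 10, 40, 40, 40, rep(20, 6))
  counts <- c(1L, 1L, 1L, 3L, 3L, 3L, rep(2L, 6))
  prof <- make_profile(m, count = counts)
  rec <- compute_partition(prof, seg, background = c(0, 0))
  I_lo_expected <- sum(counts[1:6] * m[1:6, 2]) / sum(counts[1:6])  # 30
  expect_equal(rec$I_Lo, I_lo_expected)
  expect_equal(rec$I_Ld, 20)
})

test_that("full-chain recovery hits the logistic ground truth at N = 20", {
  p <- population_params(n_vesicles = 20, dG_true = -1.4)
  sim <- simulate_frames(p, imaging_params(), seed = 11)
  recs <- quantify_sim(sim)
  expect_gte(nrow(recs), 19)
  expect_lt(abs(mean(recs$f_p_Lo) - 1 / (1 + exp(-1.4))), 0.03)
})

test_that("crosstalk estimation recovers the programmed leakage ratio", {
  # exact: off/on ratio programmed to 0.05 (row c(0.95, 0.0475)), noise off
  M_true <- matrix(c(0.95, 0.0475, 0.0475, 0.95), 2, 2, byrow = TRUE)
  im <- imaging_params(noise_model = "none", crosstalk = M_true,
                       background = c(20, 20))
  pc <- population_params(n_vesicles = 3, dG_true = 0)
  c1 <- render_frame(sample_population(pc, seed = 21), im,
                     channel_gains = c(1, 0))
  c2 <- render_frame(sample_population(pc, seed = 22), im,
                     channel_gains = c(0, 1))
  Mhat <- estimate_crosstalk(list(c1, c2))
  expect_equal(diag(Mhat), c(1, 1))
  expect_lt(abs(Mhat[1, 2] - 0.05), 1e-6)
  expect_lt(abs(Mhat[2, 1] - 0.05), 1e-6)

  # stochastic: Poisson noise at ring amplitude 1000, ratio within 0.005
  imp <- imaging_params(crosstalk = M_true, background = c(20, 20))
  c1p <- render_frame(sample_population(pc, seed = 23), imp,
                      seed = 31, channel_gains = c(1, 0))
  c2p <- render_frame(sample_population(pc, seed = 24), imp,
                      seed = 32, channel_gains = c(0, 1))
  Mp <- estimate_crosstalk(list(c1p, c2p))
  expect_lt(abs(Mp[1, 2] - 0.05), 0.005)
  expect_lt(abs(Mp[2, 1] - 0.05), 0.005)

  # identity controls (no leakage)
  im0 <- imaging_params(noise_model = "none", background = c(20, 20))
  c10 <- render_frame(sample_population(pc, seed = 25), im0,
                      channel_gains = c(1, 0))
  c20 <- render_frame(sample_population(pc, seed = 26), im0,
                      channel_gains = c(0, 1))
  expect_equal(estimate_crosstalk(list(c10, c20)), diag(2))
})

test_that("crosstalk correction round-trips and rejects singular matrices", {
  set.seed(9)
  m <- matrix(stats::runif(72 * 2, 10, 200), 72, 2)
  prof <- make_profile(m)
  expect_equal(apply_crosstalk_correction(prof, diag(2))$mean, m)
  M <- matrix(c(1, 0.12, 0.07, 1), 2, 2, byrow = TRUE)
  mixed <- prof
  mixed$mean <- m %*% M
  back <- apply_crosstalk_correction(mixed, M)
  expect_lt(max(abs(back$mean - m)), 1e-9)
  expect_error(apply_crosstalk_correction(prof, matrix(1, 2, 2)),
               "ill-conditioned")
})

test_that("10% leakage biases f toward 0.5 and unmixing removes the bias", {
  M <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  imx <- imaging_params(crosstalk = M)
  pc <- population_params(n_vesicles = 4, dG_true = 0)
  c1 <- render_frame(sample_population(pc, seed = 21), imx, seed = 41,
                     channel_gains = c(1, 0))
  c2 <- render_frame(sample_population(pc, seed = 22), imx, seed = 42,
                     channel_gains = c(0, 1))
  Mhat <- estimate_crosstalk(list(c1, c2))

  p <- population_params(n_vesicles = 20, dG_true = 1.9)
  sim <- simulate_frames(p, imx, seed = 5)
  raw <- quantify_sim(sim)
  corr <- quantify_sim(sim, crosstalk = Mhat)
  f_true <- 1 / (1 + exp(1.9))
  expect_gt(mean(raw$f_p_Lo), f_true + 0.005)       # biased toward 0.5
  expect_lt(abs(mean(corr$f_p_Lo) - f_true), 0.03)  # bias removed
})

test_that("every quantified vesicle obeys the record invariants", {
  p <- population_params(n_vesicles = 12, dG_true = 0.9)
  sim <- simulate_frames(p, imaging_params(), seed = 19)
  recs <- quantify_sim(sim)
  expect_true(all(recs$f_p_Lo + recs$f_p_Ld == 1))
  expect_true(all(recs$I_Lo >= 0 & recs$I_Ld >= 0))
  expect_true(all(recs$f_p_Lo >= 0 & recs$f_p_Lo <= 1))
})
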