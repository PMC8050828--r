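# Phantom builders used across the suite.  These construct frames directly,
# pixel by pixel, independently of the package's own renderer, so they can
# serve as oracles for the detection/profiling stages.

# Frame with a hard-edged annulus: pixels with |d - R| <= rw/2 get `values`
# (per channel); optionally a two-level angular split on channel `split_ch`
# with `hi` on [split_start, split_start + split_width) and `lo` elsewhere.
make_ring_frame <- function(size = 128L, cx = 64, cy = 64, R = 40, rw = 6,
                            values = c(100, 100), background = 0,
                            split_ch = NULL, split_start = 0,
                            split_width = pi, hi = 100, lo = 20) {
  ch <- array(background, dim = c(size, size, 2L))
  xg <- matrix(0:(size - 1), size, size, byrow = TRUE)
  yg <- matrix(0:(size - 1), size, size)
  dd <- sqrt((xg - cx)^2 + (yg - cy)^2)
  sel <- abs(dd - R) <= rw / 2
  ang <- atan2(yg - cy, xg - cx) %% (2 * pi)
  for (k in 1:2) {
    v <- matrix(values[k], size, size)
    if (!is.null(split_ch) && k == split_ch) {
      in_hi <- ((ang - split_start) %% (2 * pi)) < split_width
      v <- ifelse(in_hi, hi, lo)
    }
    m <- ch[, , k]
    m[sel] <- v[sel]
    ch[, , k] <- m
  }
  structure(list(channels = ch, pixel_size_um = 0.2, truth = NULL),
            class = "guv_frame")
}

# A synthetic angular profile object built by hand (bypasses image stages).
make_profile <- function(mean_mat, count = NULL, radius = 40, ring_width = 6) {
  n <- nrow(mean_mat)
  if (is.null(count)) count <- rep(10L, n)
  structure(list(n_bins = n,
                 bin_edges = seq(0, 2 * pi, length.out = n + 1),
                 mean = mean_mat, count = count,
                 contour = list(x = 64, y = 64, radius = radius,
                                ring_width = ring_width)),
            class = "angular_profile")
}

# Quantify all frames of a simulate_frames() result; returns pooled records.
quantify_sim <- function(sim, ...) {
  recs <- NULL
  for (fr in sim$frames) recs <- rbind(recs, quantify_frame(fr, ...)$records)
  recs
}

# Ground-truth angular phase label for a bin-center angle.
truth_label <- function(theta, lo_start, lo_frac) {
  if (((theta - lo_start) %% (2 * pi)) < 2 * pi * lo_frac) "Lo" else "Ld"
}

# Match detected contours to ground-truth vesicles by nearest center;
# returns index of the truth row for each contour.
match_truth <- function(contours, truth) {
  vapply(seq_len(nrow(contours)), function(i) {
    which.min((truth$x - contours$x[i])^2 + (truth$y - contours$y[i])^2)
  }, integer(1))
}
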