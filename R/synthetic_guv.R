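#' Imaging parameters for the synthetic GUV generator
#'
#' Describes the virtual microscope: frame geometry, point-spread blur,
#' per-channel background, noise model and spectral cross-talk.  The defaults
#' emulate a shot-noise-limited two-channel confocal acquisition at a nominal
#' 0.2 um/px; they are configuration choices, not measured instrument facts.
#'
#' @param frame_size frame side length in pixels (square frames).
#' @param psf_sigma point-spread-function standard deviation, px.
#' @param background per-channel background level, counts (recycled to 2).
#' @param noise_model `"poisson"` (shot noise on counts, applied after
#'   background), `"gaussian"` (additive, sd `gaussian_sd`), or `"none"`.
#' @param gaussian_sd sd for the Gaussian noise model, counts.
#' @param crosstalk 2x2 leakage matrix; entry \eqn{M_{kj}} is the fraction of
#'   true channel-k signal observed in channel j.  Rows must have diagonal in
#'   (0, 1], off-diagonals in \[0, 1) and sum to at most 1 (row-stochastic
#'   leakage).  Identity means no bleed-through.
#' @param ring_sigma radial thickness (Gaussian sigma) of the membrane
#'   intensity profile, px.
#' @param pixel_size_um physical pixel size, micrometres (metadata only).
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(frame_size = 320L,
                           psf_sigma = 1.5,
                           background = c(50, 50),
                           noise_model = c("poisson", "gaussian", "none"),
                           gaussian_sd = 10,
                           crosstalk = diag(2),
                           ring_sigma = 1.5,
                           pixel_size_um = 0.2) {
  noise_model <- match.arg(noise_model)
  background <- rep_len(as.numeric(background), 2L)
  crosstalk <- as.matrix(crosstalk)
  stopifnot(length(frame_size) == 1L, frame_size >= 32)
  if (psf_sigma < 0) stop("`psf_sigma` must be >= 0", call. = FALSE)
  if (ring_sigma <= 0) stop("`ring_sigma` must be > 0", call. = FALSE)
  if (any(background < 0)) stop("`background` must be >= 0", call. = FALSE)
  if (!identical(dim(crosstalk), c(2L, 2L))) {
    stop("`crosstalk` must be a 2x2 matrix", call. = FALSE)
  }
  d <- diag(crosstalk); o <- crosstalk[row(crosstalk) != col(crosstalk)]
  if (any(d <= 0) || any(d > 1) || any(o < 0) || any(o >= 1) ||
      any(rowSums(crosstalk) > 1 + 1e-12)) {
    stop("`crosstalk` rows must have diagonal in (0,1], off-diagonal in [0,1), row sums <= 1",
         call. = FALSE)
  }
  structure(list(frame_size = as.integer(frame_size), psf_sigma = psf_sigma,
                 background = background, noise_model = noise_model,
                 gaussian_sd = gaussian_sd, crosstalk = crosstalk,
                 ring_sigma = ring_sigma, pixel_size_um = pixel_size_um),
            class = "imaging_params")
}

#' Population parameters for the synthetic GUV generator
#'
#' Defines a population of phase-separated (Janus) vesicles: how many, their
#' radius distribution, the ground-truth partitioning free energy of the
#' labelled construct, the Lo arc geometry, and the lipid-dye contrast.
#' Radii are log-normal, emulating the size heterogeneity of electroformed
#' GUVs.
#'
#' @param n_vesicles number of vesicles (>= 1).
#' @param radius_median median radius, px.
#' @param radius_shape log-normal shape (sdlog); 0 gives fixed radii.
#' @param radius_min minimum accepted radius, px (resampled below this).
#' @param dG_true ground-truth partitioning free energy, kBT (Lo relative to
#'   Ld; negative = Lo preference).
#' @param lo_arc_fraction_range interval for the uniform draw of the fraction
#'   of circumference in the Lo phase, inside (0, 1).
#' @param lipid_contrast Ld:Lo intensity ratio of the lipid marker (>= 1;
#'   the marker enriches the Ld phase).
#' @param membrane_amplitude peak membrane intensity scale, counts.
#' @param dna_to_lipid_ratio dimensionless label used for density-sweep
#'   bookkeeping (carried through to records; default ~4e-4).
#' @return an object of class `population_params`.
#' @export
population_params <- function(n_vesicles = 20L,
                              radius_median = 35,
                              radius_shape = 0.3,
                              radius_min = 18,
                              dG_true = 0,
                              lo_arc_fraction_range = c(0.35, 0.6),
                              lipid_contrast = 2,
                              membrane_amplitude = 1000,
                              dna_to_lipid_ratio = 4e-4) {
  stopifnot(n_vesicles >= 1, radius_median > 0, radius_shape >= 0,
            radius_min > 0, is.finite(dG_true), lipid_contrast >= 1,
            membrane_amplitude > 0)
  r <- lo_arc_fraction_range
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2]) {
    stop("`lo_arc_fraction_range` must lie inside (0, 1)", call. = FALSE)
  }
  structure(list(n_vesicles = as.integer(n_vesicles),
                 radius_median = radius_median, radius_shape = radius_shape,
                 radius_min = radius_min, dG_true = dG_true,
                 lo_arc_fraction_range = r, lipid_contrast = lipid_contrast,
                 membrane_amplitude = membrane_amplitude,
                 dna_to_lipid_ratio = dna_to_lipid_ratio),
            class = "population_params")
}

#' Sample a ground-truth vesicle population
#'
#' Draws `n_vesicles` Janus vesicles with log-normal radii and uniform Lo-arc
#' fractions, and places them in the frame by rejection sampling so that no
#' two membrane rings overlap and every ring stays clear of the frame border.
#' Identical `seed` gives identical output.
#'
#' Pixel coordinates are 0-based with x = column, y = row; angles are in
#' radians, counter-clockwise from the +x axis (with y increasing along
#' rows).  These conventions hold throughout the package.
#'
#' @param params a [population_params()].
#' @param seed integer random seed.
#' @param frame_size frame side length, px (match the [imaging_params()]
#'   used for rendering).
#' @param margin clearance required between a ring and the frame border and
#'   between neighbouring rings, px.
#' @param max_tries rejection-sampling attempts per vesicle.
#' @return data.frame, one row per vesicle: `id`, `x`, `y`, `radius`,
#'   `lo_arc_start`, `lo_arc_fraction`, `dG_true`, `f_true`
#'   (\eqn{1/(1+e^{dG})}), `lipid_contrast`, `membrane_amplitude`,
#'   `dna_to_lipid_ratio`.
#' @export
sample_population <- function(params, seed = 1L, frame_size = 320L,
                              margin = 20, max_tries = 2000L) {
  stopifnot(inherits(params, "population_params"))
  set.seed(as.integer(seed))
  n <- params$n_vesicles
  radii <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- if (params$radius_shape == 0) params$radius_median else
        stats::rlnorm(1, meanlog = log(params$radius_median),
                      sdlog = params$radius_shape)
      if (r >= params$radius_min) break
    }
    radii[i] <- r
  }
  radii <- sort(radii, decreasing = TRUE)  # place large vesicles first
  lo_frac <- stats::runif(n, params$lo_arc_fraction_range[1],
                          params$lo_arc_fraction_range[2])
  lo_start <- stats::runif(n, 0, 2 * pi)
  xs <- ys <- numeric(n)
  placed <- 0L
  for (i in seq_len(n)) {
    lo_bound <- radii[i] + margin
    hi_bound <- frame_size - 1 - radii[i] - margin
    if (hi_bound <= lo_bound) {
      stop(sprintf("placement failure: frame too small; placed %d of %d vesicles",
                   placed, n), call. = FALSE)
    }
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, lo_bound, hi_bound)
      cy <- stats::runif(1, lo_bound, hi_bound)
      if (placed == 0L ||
          all(sqrt((xs[seq_len(placed)] - cx)^2 +
                   (ys[seq_len(placed)] - cy)^2) >
              radii[seq_len(placed)] + radii[i] + margin)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop(sprintf("placement failure: placed %d of %d non-overlapping vesicles",
                   placed, n), call. = FALSE)
    }
    xs[i] <- cx; ys[i] <- cy; placed <- placed + 1L
  }
  data.frame(id = seq_len(n), x = xs, y = ys, radius = radii,
             lo_arc_start = lo_start, lo_arc_fraction = lo_frac,
             dG_true = params$dG_true,
             f_true = dG_to_fraction(params$dG_true),
             lipid_contrast = params$lipid_contrast,
             membrane_amplitude = params$membrane_amplitude,
             dna_to_lipid_ratio = params$dna_to_lipid_ratio)
}

#' Render a two-channel equatorial frame from ground-truth vesicles
#'
#' Draws each vesicle's membrane as a circle with a Gaussian radial intensity
#' profile (sigma `ring_sigma`), split into one Lo and one Ld arc with sharp
#' boundaries.  Channel 1 carries the lipid marker with arc intensities in
#' ratio `lipid_contrast` (Ld bright); channel 2 carries the construct label
#' with Lo:Ld arc intensities in ratio \eqn{e^{-\Delta G_{true}}} (Lo bright
#' when dG < 0), normalised so the two arc amplitudes average to
#' `membrane_amplitude`.  The image then receives, in order: PSF blur,
#' cross-talk mixing, background addition, and noise.  PSF blur is the only
#' source of arc-boundary smearing, keeping the ground truth unambiguous.
#'
#' @param vesicles data.frame as produced by [sample_population()].
#' @param imaging an [imaging_params()].
#' @param seed integer seed for the noise draw (`NULL` leaves the RNG state
#'   untouched).
#' @param channel_gains length-2 multiplier on the pre-mixing amplitude of
#'   each channel; `c(1, 0)` renders a lipid-marker-only control frame,
#'   `c(0, 1)` a construct-only control (used for cross-talk estimation).
#' @return an object of class `guv_frame`: list with `channels` (array
#'   frame_size x frame_size x 2, counts), `pixel_size_um`, and `truth`
#'   (the input table, with `f_true`).
#' @export
render_frame <- function(vesicles, imaging = imaging_params(), seed = NULL,
                         channel_gains = c(1, 1)) {
  stopifnot(inherits(imaging, "imaging_params"), is.data.frame(vesicles))
  n <- imaging$frame_size
  need <- c("x", "y", "radius", "lo_arc_start", "lo_arc_fraction",
            "dG_true", "lipid_contrast", "membrane_amplitude")
  if (!all(need %in% names(vesicles))) {
    stop("`vesicles` lacks columns: ",
         paste(setdiff(need, names(vesicles)), collapse = ", "), call. = FALSE)
  }
  if (any(vesicles$radius <= 0) ||
      any(vesicles$lo_arc_fraction <= 0 | vesicles$lo_arc_fraction >= 1) ||
      any(vesicles$lipid_contrast < 1)) {
    stop("invalid vesicle ground truth (radius, lo_arc_fraction or lipid_contrast)",
         call. = FALSE)
  }
  halo <- 4 * imaging$ring_sigma
  if (any(vesicles$x - vesicles$radius - halo < 0 |
          vesicles$x + vesicles$radius + halo > n - 1 |
          vesicles$y - vesicles$radius - halo < 0 |
          vesicles$y + vesicles$radius + halo > n - 1)) {
    stop("vesicle ring does not fit inside the frame with margin", call. = FALSE)
  }

  ch <- array(0, dim = c(n, n, 2L))
  for (i in seq_len(nrow(vesicles))) {
    v <- vesicles[i, ]
    ext <- ceiling(v$radius + halo)
    rows <- max(1L, floor(v$y + 1 - ext)):min(n, ceiling(v$y + 1 + ext))
    cols <- max(1L, floor(v$x + 1 - ext)):min(n, ceiling(v$x + 1 + ext))
    dy <- (rows - 1) - v$y           # y is 0-based row coordinate
    dx <- (cols - 1) - v$x
    D <- sqrt(outer(dy^2, dx^2, `+`))
    radial <- exp(-(D - v$radius)^2 / (2 * imaging$ring_sigma^2))
    ang <- (atan2(outer(dy, rep(1, length(dx))),
                  outer(rep(1, length(dy)), dx))) %% (2 * pi)
    in_lo <- ((ang - v$lo_arc_start) %% (2 * pi)) < 2 * pi * v$lo_arc_fraction
    A <- v$membrane_amplitude
    amp1 <- ifelse(in_lo, A / v$lipid_contrast, A)          # lipid: Ld bright
    r2 <- intensity_ratio_from_dG(v$dG_true)                 # construct Lo:Ld
    amp2 <- ifelse(in_lo, A * 2 * r2 / (1 + r2), A * 2 / (1 + r2))
    ch[rows, cols, 1L] <- ch[rows, cols, 1L] + channel_gains[1] * amp1 * radial
    ch[rows, cols, 2L] <- ch[rows, cols, 2L] + channel_gains[2] * amp2 * radial
  }

  if (imaging$psf_sigma > 0) {
    for (k in 1:2) {
      ch[, , k] <- as.matrix(EBImage::gblur(EBImage::Image(ch[, , k]),
                                            sigma = imaging$psf_sigma))
    }
  }
  M <- imaging$crosstalk
  mixed1 <- M[1, 1] * ch[, , 1] + M[2, 1] * ch[, , 2]
  mixed2 <- M[1, 2] * ch[, , 1] + M[2, 2] * ch[, , 2]
  ch[, , 1] <- mixed1 + imaging$background[1]
  ch[, , 2] <- mixed2 + imaging$background[2]

  if (imaging$noise_model != "none") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    for (k in 1:2) {
      if (imaging$noise_model == "poisson") {
        ch[, , k] <- matrix(stats::rpois(n * n, lambda = pmax(ch[, , k], 0)), n, n)
      } else {
        ch[, , k] <- ch[, , k] + stats::rnorm(n * n, sd = imaging$gaussian_sd)
      }
    }
  }
  ch[ch < 0] <- 0

  truth <- vesicles
  truth$f_true <- dG_to_fraction(truth$dG_true)
  structure(list(channels = ch, pixel_size_um = imaging$pixel_size_um,
                 truth = truth),
            class = "guv_frame")
}

#' @export
print.guv_frame <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<guv_frame> %d x %d px, %d channels, %s vesicles (truth %s)\n",
              d[1], d[2], d[3],
              if (is.null(x$truth)) "?" else nrow(x$truth),
              if (is.null(x$truth)) "absent" else "attached"))
  invisible(x)
}

#' Simulate a population as a set of rendered frames
#'
#' Splits a sampled population into frames of at most `per_frame` vesicles,
#' renders each frame with a deterministically derived per-frame seed, and
#' returns the frames with a combined ground-truth table.  One master seed
#' reproduces the whole set.
#'
#' @param params a [population_params()].
#' @param imaging an [imaging_params()].
#' @param seed master integer seed.
#' @param per_frame vesicles per rendered frame.
#' @return list with `frames` (list of `guv_frame`) and `truth` (data.frame
#'   with `frame` and globally unique `id`).
#' @export
simulate_frames <- function(params, imaging = imaging_params(), seed = 1L,
                            per_frame = 4L) {
  stopifnot(inherits(params, "population_params"))
  n <- params$n_vesicles
  n_frames <- ceiling(n / per_frame)
  frames <- vector("list", n_frames)
  truth_all <- NULL
  left <- n
  for (fr in seq_len(n_frames)) {
    k <- min(per_frame, left); left <- left - k
    p_fr <- params; p_fr$n_vesicles <- k
    fseed <- (as.integer(seed) + 7919L * fr) %% .Machine$integer.max
    ves <- sample_population(p_fr, seed = fseed,
                             frame_size = imaging$frame_size)
    frames[[fr]] <- render_frame(ves, imaging, seed = fseed + 1L)
    t_fr <- frames[[fr]]$truth
    t_fr$frame <- fr
    t_fr$id <- t_fr$id + (fr - 1L) * per_frame
    frames[[fr]]$truth <- t_fr
    truth_all <- rbind(truth_all, t_fr)
  }
  list(frames = frames, truth = truth_all)
}
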