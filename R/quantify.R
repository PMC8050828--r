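#' Estimate per-channel background from the region outside all vesicles
#'
#' The background is the per-channel median intensity over pixels lying
#' outside every detected annulus (dilated by `margin`) and outside every
#' vesicle interior — i.e. farther than `radius + ring_width/2 + margin`
#' from every detected center.
#'
#' @param frame a `guv_frame`.
#' @param contours a `vesicle_contours` table.
#' @param margin dilation margin, px.
#' @return numeric vector, one background level per channel.
#' @export
estimate_background <- function(frame, contours, margin = 4) {
  stopifnot(inherits(frame, "guv_frame"))
  d <- dim(frame$channels)
  outside <- matrix(TRUE, d[1], d[2])
  if (nrow(contours) > 0) {
    xg <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
    yg <- matrix(0:(d[1] - 1), d[1], d[2])
    for (i in seq_len(nrow(contours))) {
      dd <- sqrt((xg - contours$x[i])^2 + (yg - contours$y[i])^2)
      outside <- outside &
        (dd > contours$radius[i] + contours$ring_width[i] / 2 + margin)
    }
  }
  if (!any(outside)) {
    stop("no background pixels: frame fully covered by vesicles", call. = FALSE)
  }
  vapply(seq_len(d[3]),
         function(k) stats::median(frame$channels[, , k][outside]),
         numeric(1))
}

#' Compute a per-vesicle partition record
#'
#' Forms the background-corrected mean construct-channel intensities over
#' the Lo and Ld arcs, \eqn{I_{Lo}} and \eqn{I_{Ld}}, and the fractional Lo
#' intensity
#' \deqn{f_{p,Lo} = \frac{I_{Lo}}{I_{Lo} + I_{Ld}}.}
#' Arc means are pixel-count-weighted over the non-excluded bins of each
#' phase, which equals the direct per-pixel mean over the arc.  Negative
#' background-subtracted means are clamped to 0 and flagged so that f stays
#' in \[0, 1\].
#'
#' @param profile an `angular_profile`.
#' @param seg a `phase_segmentation` for the same profile.
#' @param background per-channel background vector (see
#'   [estimate_background()]).
#' @param construct_channel index of the construct-label channel (default 2).
#' @param vesicle_id,population_label provenance carried into the record.
#' @return one-row data.frame (a partition record): `vesicle_id`,
#'   `population_label`, `I_Lo`, `I_Ld`, `f_p_Lo`, `f_p_Ld`, `radius`,
#'   `separation_score`, `flags`.
#' @export
compute_partition <- function(profile, seg, background,
                              construct_channel = 2L,
                              vesicle_id = NA_integer_,
                              population_label = NA_character_) {
  stopifnot(inherits(profile, "angular_profile"),
            inherits(seg, "phase_segmentation"))
  if (construct_channel > ncol(profile$mean)) {
    stop("construct channel not present in profile", call. = FALSE)
  }
  bg <- background[construct_channel]
  arc_mean <- function(lab) {
    bins <- which(seg$labels == lab)
    w <- profile$count[bins]
    sum(w * profile$mean[bins, construct_channel]) / sum(w) - bg
  }
  I_lo <- arc_mean("Lo")
  I_ld <- arc_mean("Ld")
  flags <- character(0)
  if (I_lo < 0) { I_lo <- 0; flags <- c(flags, "clamped_Lo") }
  if (I_ld < 0) { I_ld <- 0; flags <- c(flags, "clamped_Ld") }
  if (I_lo + I_ld <= 0) {
    stop("zero signal: I_Lo + I_Ld <= 0 after background subtraction",
         call. = FALSE)
  }
  f <- I_lo / (I_lo + I_ld)
  data.frame(vesicle_id = vesicle_id, population_label = population_label,
             I_Lo = I_lo, I_Ld = I_ld, f_p_Lo = f, f_p_Ld = 1 - f,
             radius = profile$contour$radius,
             separation_score = seg$separation_score,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Estimate the spectral cross-talk matrix from single-label controls
#'
#' Each control frame contains vesicles carrying only one fluorophore.  For
#' control k, the off-diagonal entry M\[k, j\] is the ratio of the observed
#' off-channel (j) to on-channel (k) background-corrected membrane signal;
#' diagonals are normalised to 1.  Unmixing with a diagonal-normalised
#' matrix recovers true signals up to a per-channel gain, which cancels in
#' the fractional intensity.
#'
#' @param control_frames list of two `guv_frame`s: element k has only
#'   fluorophore k present.
#' @param options detection settings used to find the control vesicles.
#' @return 2x2 cross-talk matrix (diagonal 1).
#' @export
estimate_crosstalk <- function(control_frames,
                               options = detection_options()) {
  stopifnot(is.list(control_frames), length(control_frames) == 2L)
  M <- diag(2)
  for (k in 1:2) {
    fr <- control_frames[[k]]
    contours <- detect_vesicles(fr, options)
    if (nrow(contours) == 0) {
      stop("no vesicles detected in control frame ", k, call. = FALSE)
    }
    bg <- estimate_background(fr, contours)
    tot <- c(0, 0); npx <- 0
    for (i in seq_len(nrow(contours))) {
      prof <- extract_angular_profile(fr, contours[i, ])
      for (ch in 1:2) {
        tot[ch] <- tot[ch] + sum(prof$count * (prof$mean[, ch] - bg[ch]))
      }
      npx <- npx + sum(prof$count)
    }
    sig <- tot / npx
    if (sig[k] <= 0) {
      stop("on-channel control signal at or below background in control ", k,
           call. = FALSE)
    }
    other <- 3L - k
    leak <- sig[other] / sig[k]
    M[k, other] <- max(leak, 0)
  }
  M
}

#' Correct an angular profile for spectral cross-talk
#'
#' Left-multiplies each bin's observed channel vector by the inverse of the
#' mixing matrix (observed = true %*% M per bin row), restoring the true
#' per-channel signals.  Apply before background subtraction and pass the
#' background through [correct_background()] with the same matrix.
#'
#' @param profile an `angular_profile`.
#' @param M 2x2 cross-talk matrix.
#' @param max_condition reject matrices with condition number above this.
#' @return the corrected `angular_profile`.
#' @export
apply_crosstalk_correction <- function(profile, M, max_condition = 1e6) {
  stopifnot(inherits(profile, "angular_profile"))
  M <- as.matrix(M)
  if (!identical(dim(M), c(2L, 2L)) || any(!is.finite(M))) {
    stop("`M` must be a finite 2x2 matrix", call. = FALSE)
  }
  if (kappa(M, exact = TRUE) > max_condition) {
    stop("ill-conditioned cross-talk matrix (condition number above threshold)",
         call. = FALSE)
  }
  profile$mean <- profile$mean %*% solve(M)
  profile
}

#' Pass a background estimate through the cross-talk correction
#'
#' When images are unmixed, the background measured on the mixed image must
#' be unmixed with the same matrix before subtraction.
#'
#' @param background per-channel background vector (length 2).
#' @param M 2x2 cross-talk matrix.
#' @return corrected background vector.
#' @export
correct_background <- function(background, M) {
  drop(matrix(background, nrow = 1) %*% solve(as.matrix(M)))
}

#' Quantify every vesicle in a frame
#'
#' Full per-frame chain: detect contours, estimate background, then for each
#' contour extract the angular profile, optionally unmix cross-talk, segment
#' the phases and compute the partition record.  Vesicles failing any stage
#' (not phase-separated, degenerate arc, zero signal, clipped annulus) are
#' dropped and logged with exactly one exclusion reason.
#'
#' @param frame a `guv_frame`.
#' @param population_label condition tag carried into the records.
#' @param crosstalk optional 2x2 matrix; when supplied, profiles and the
#'   background are unmixed before quantification.
#' @param detection a [detection_options()].
#' @param segmentation a [segmentation_options()].
#' @param n_bins angular bins per vesicle.
#' @param lipid_channel,construct_channel channel role indices.
#' @param min_separation quality gate on the segmentation separation score
#'   (`NULL` uses the segmentation option threshold only).
#' @return list with `records` (data.frame of partition records, possibly
#'   zero rows) and `log` (data.frame: `vesicle`, `x`, `y`, `radius`,
#'   `status`, `reason`).
#' @export
quantify_frame <- function(frame, population_label = NA_character_,
                           crosstalk = NULL,
                           detection = detection_options(),
                           segmentation = segmentation_options(),
                           n_bins = 72L,
                           lipid_channel = 1L, construct_channel = 2L,
                           min_separation = NULL) {
  contours <- detect_vesicles(frame, detection)
  rec_list <- list(); log_list <- list()
  empty_rec <- compute_partition_template()
  if (nrow(contours) == 0) {
    return(list(records = empty_rec,
                log = data.frame(vesicle = integer(0), x = numeric(0),
                                 y = numeric(0), radius = numeric(0),
                                 status = character(0), reason = character(0))))
  }
  background <- estimate_background(frame, contours)
  if (!is.null(crosstalk)) {
    background <- correct_background(background, crosstalk)
  }
  for (i in seq_len(nrow(contours))) {
    res <- tryCatch({
      prof <- extract_angular_profile(frame, contours[i, ], n_bins = n_bins)
      if (!is.null(crosstalk)) {
        prof <- apply_crosstalk_correction(prof, crosstalk)
      }
      seg <- segment_phases(prof, lipid_channel = lipid_channel,
                            options = segmentation)
      if (!is.null(min_separation) && seg$separation_score < min_separation) {
        stop("below separation-score gate", call. = FALSE)
      }
      compute_partition(prof, seg, background,
                        construct_channel = construct_channel,
                        vesicle_id = i, population_label = population_label)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log_list[[length(log_list) + 1L]] <- data.frame(
        vesicle = i, x = contours$x[i], y = contours$y[i],
        radius = contours$radius[i], status = "excluded", reason = res)
    } else {
      rec_list[[length(rec_list) + 1L]] <- res
      log_list[[length(log_list) + 1L]] <- data.frame(
        vesicle = i, x = contours$x[i], y = contours$y[i],
        radius = contours$radius[i], status = "retained", reason = "")
    }
  }
  records <- if (length(rec_list)) do.call(rbind, rec_list) else empty_rec
  list(records = records, log = do.call(rbind, log_list))
}

compute_partition_template <- function() {
  data.frame(vesicle_id = integer(0), population_label = character(0),
             I_Lo = numeric(0), I_Ld = numeric(0), f_p_Lo = numeric(0),
             f_p_Ld = numeric(0), radius = numeric(0),
             separation_score = numeric(0), flags = character(0),
             stringsAsFactors = FALSE)
}
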