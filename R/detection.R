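#' Detection settings
#'
#' @param threshold_k ring pixels are those brighter than
#'   `median + threshold_k * mad` of the channel-sum image.
#' @param min_pixels smallest connected component considered a candidate
#'   ring.
#' @param quality_min minimum fit quality (in \[0, 1\], monotone in
#'   circularity) for a contour to be returned.
#' @param ring_width annulus thickness used for sampling, px; `NULL`
#'   estimates it per vesicle as 3x the full-width (6 sigma) of the radial
#'   intensity profile, floored at 4 px.
#' @param n_refine number of sub-pixel refinement passes of the weighted
#'   circle fit.
#' @return list of class `detection_options`.
#' @export
detection_options <- function(threshold_k = 5, min_pixels = 80,
                              quality_min = 0.5, ring_width = NULL,
                              n_refine = 2L) {
  structure(list(threshold_k = threshold_k, min_pixels = min_pixels,
                 quality_min = quality_min, ring_width = ring_width,
                 n_refine = n_refine),
            class = "detection_options")
}

# Intensity-weighted algebraic (Kasa) circle fit: solves the linear least
# squares x^2 + y^2 = 2ax + 2by + c, then R^2 = c + a^2 + b^2.
circle_fit <- function(x, y, w) {
  Z <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  beta <- tryCatch(solve(crossprod(Z, Z * w), crossprod(Z, rhs * w)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  cx <- beta[1]; cy <- beta[2]
  r2 <- beta[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  R <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  rmse <- sqrt(sum(w * (d - R)^2) / sum(w))
  list(x = cx, y = cy, radius = R, rmse = rmse)
}

#' Detect vesicle membrane contours in a two-channel frame
#'
#' Detection runs on the channel sum (both fluorophores label the membrane
#' ring): pixels above a robust threshold are grouped into connected
#' components, and each component is fit with an intensity-weighted circle
#' (algebraic fit with iterative sub-pixel refinement on pixels near the
#' current circle).  Fit quality is `1 - 2.5 * rmse / radius`, clipped to
#' \[0, 1\] — a decreasing function of the relative radial scatter, i.e.
#' monotone in circularity.  Contours touching the frame border (ring
#' within one ring-width of the edge) are excluded, overlapping circles keep
#' only the higher-quality contour, and the result is sorted by quality
#' (descending).
#'
#' @param frame a `guv_frame` (two channels).
#' @param options a [detection_options()].
#' @return data.frame of class `vesicle_contours`: columns `x`, `y`
#'   (0-based, sub-pixel), `radius`, `ring_width`, `quality`.  Empty (zero
#'   rows) when nothing passes the quality gate.
#' @export
detect_vesicles <- function(frame, options = detection_options()) {
  if (!inherits(frame, "guv_frame")) stop("`frame` must be a guv_frame", call. = FALSE)
  d <- dim(frame$channels)
  if (length(d) != 3L || d[3] < 2L) {
    stop("frame must have >= 2 channels", call. = FALSE)
  }
  S <- frame$channels[, , 1] + frame$channels[, , 2]
  bg <- stats::median(S)
  sc <- stats::mad(S)
  # noise-free frames have (numerically) zero mad; fall back to a fraction
  # of the dynamic range
  thr <- if (sc > 1e-3) bg + options$threshold_k * sc else
    bg + 0.2 * (max(S) - bg)
  mask <- S > thr
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                radius = numeric(0), ring_width = numeric(0),
                                quality = numeric(0)),
                     class = c("vesicle_contours", "data.frame"))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < options$min_pixels) next
    rows <- ((idx - 1L) %% d[1]) + 1L
    cols <- ((idx - 1L) %/% d[1]) + 1L
    x <- cols - 1; y <- rows - 1            # 0-based (x = column, y = row)
    w <- pmax(S[idx] - bg, 0)
    fit <- circle_fit(x, y, w)
    if (is.null(fit)) next
    for (it in seq_len(options$n_refine)) {
      dd <- sqrt((x - fit$x)^2 + (y - fit$y)^2)
      keep <- abs(dd - fit$radius) < 3 * max(fit$rmse, 1)
      if (sum(keep) < options$min_pixels / 2) break
      fit2 <- circle_fit(x[keep], y[keep], w[keep])
      if (is.null(fit2)) break
      fit <- fit2
    }
    rw <- if (is.null(options$ring_width)) max(4, 6 * fit$rmse) else options$ring_width
    quality <- max(0, min(1, 1 - 2.5 * fit$rmse / fit$radius))
    out[[length(out) + 1L]] <- data.frame(
      x = fit$x, y = fit$y, radius = fit$radius, ring_width = rw,
      quality = quality)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[res$quality >= options$quality_min &
               res$radius > res$ring_width / 2, , drop = FALSE]
  # border exclusion: whole ring plus one ring_width of margin must fit
  ok <- with(res, x - radius - 1.5 * ring_width >= 0 &
                  x + radius + 1.5 * ring_width <= d[2] - 1 &
                  y - radius - 1.5 * ring_width >= 0 &
                  y + radius + 1.5 * ring_width <= d[1] - 1)
  res <- res[ok, , drop = FALSE]
  res <- res[order(-res$quality), , drop = FALSE]
  # overlapping rings: keep the higher-quality one
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1) {
    for (i in 2:nrow(res)) {
      for (j in seq_len(i - 1)) {
        if (!keep[j]) next
        dist <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2)
        if (dist < res$radius[i] + res$radius[j] +
                    (res$ring_width[i] + res$ring_width[j]) / 2) {
          keep[i] <- FALSE; break
        }
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("vesicle_contours", "data.frame")
  res
}

#' Extract a per-angular-bin intensity profile along a membrane annulus
#'
#' Every pixel whose radial distance from the fitted circle is within
#' `ring_width / 2` is assigned to exactly one angular bin (half-open
#' intervals partitioning \[0, 2pi), counter-clockwise from +x), and
#' per-bin, per-channel mean intensities and pixel counts are computed.
#' The pixel-count-weighted bin means conserve the total annulus intensity.
#'
#' @param frame a `guv_frame`.
#' @param contour one row of a `vesicle_contours` table (or any list with
#'   `x`, `y`, `radius`, `ring_width`).
#' @param n_bins number of angular bins (default 72, i.e. 5 degrees).
#' @return an object of class `angular_profile`: list with `n_bins`,
#'   `bin_edges` (radians, length `n_bins + 1`), `mean` (n_bins x
#'   n_channels matrix), `count` (pixels per bin), `contour`.
#' @export
extract_angular_profile <- function(frame, contour, n_bins = 72L) {
  stopifnot(inherits(frame, "guv_frame"), n_bins >= 8)
  d <- dim(frame$channels)
  cx <- contour$x; cy <- contour$y; R <- contour$radius
  rw <- contour$ring_width
  if (cx - R - rw / 2 < 0 || cx + R + rw / 2 > d[2] - 1 ||
      cy - R - rw / 2 < 0 || cy + R + rw / 2 > d[1] - 1) {
    stop("clipped annulus: ring extends beyond the frame border", call. = FALSE)
  }
  ext <- ceiling(R + rw / 2)
  rows <- max(1L, floor(cy + 1 - ext)):min(d[1], ceiling(cy + 1 + ext))
  cols <- max(1L, floor(cx + 1 - ext)):min(d[2], ceiling(cx + 1 + ext))
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  DD <- sqrt(outer(dy^2, dx^2, `+`))
  sel <- abs(DD - R) <= rw / 2
  ang <- atan2(outer(dy, rep(1, length(dx))),
               outer(rep(1, length(dy)), dx)) %% (2 * pi)
  bin <- pmin(floor(ang[sel] / (2 * pi / n_bins)) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0)) {
    stop("annulus too thin: some angular bins contain no pixels", call. = FALSE)
  }
  nc <- d[3]
  means <- matrix(0, n_bins, nc)
  for (k in seq_len(nc)) {
    sub <- frame$channels[rows, cols, k]
    sums <- as.numeric(rowsum(sub[sel], group = bin,
                              reorder = TRUE)[as.character(seq_len(n_bins)), ])
    means[, k] <- sums / counts
  }
  structure(list(n_bins = as.integer(n_bins),
                 bin_edges = seq(0, 2 * pi, length.out = n_bins + 1L),
                 mean = means, count = counts,
                 contour = as.list(contour)),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat(sprintf("<angular_profile> %d bins, %d channels, %d annulus pixels\n",
              x$n_bins, ncol(x$mean), sum(x$count)))
  invisible(x)
}
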