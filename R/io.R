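#' Write a two-channel frame as a 16-bit multi-page TIFF
#'
#' Counts are rounded, clamped to \[0, 65535\] and written as one 16-bit
#' page per channel.
#'
#' @param frame a `guv_frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "guv_frame"))
  pages <- lapply(seq_len(dim(frame$channels)[3]), function(k) {
    m <- round(frame$channels[, , k])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel frame from a multi-page TIFF
#'
#' Pages are read as raw integer counts (one page per channel).  Greyscale
#' pages only; a single-page file yields a single-channel frame, which
#' detection will reject.
#'
#' @param path TIFF file path.
#' @param pixel_size_um physical pixel size metadata to attach.
#' @return a `guv_frame` (no ground truth attached).
#' @export
read_frame_tiff <- function(path, pixel_size_um = 0.2) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p   # collapse any RGB to grey
  })
  d <- dim(pages[[1]])
  ch <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) ch[, , k] <- pages[[k]]
  structure(list(channels = ch, pixel_size_um = pixel_size_um, truth = NULL),
            class = "guv_frame")
}
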