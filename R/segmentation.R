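#' Segmentation settings
#'
#' @param boundary_exclusion bins removed from each end of each arc at the
#'   two phase boundaries (default 2, i.e. 10 degrees at 72-bin profiles):
#'   the PSF smears the domain boundary, and excluding it protects the arc
#'   means.
#' @param min_separation minimum separation score
#'   ((mean_Ld - mean_Lo) / pooled SD in the lipid channel) below which a
#'   vesicle is rejected as not phase-separated.
#' @param min_arc_bins minimum bins per arc after boundary exclusion.
#' @return list of class `segmentation_options`.
#' @export
segmentation_options <- function(boundary_exclusion = 2L,
                                 min_separation = 2,
                                 min_arc_bins = 4L) {
  stopifnot(boundary_exclusion >= 0, min_arc_bins >= 1)
  structure(list(boundary_exclusion = as.integer(boundary_exclusion),
                 min_separation = min_separation,
                 min_arc_bins = as.integer(min_arc_bins)),
            class = "segmentation_options")
}

# Otsu-style two-class threshold for a short vector of bin means: exhaustive
# search over midpoints between consecutive sorted values, minimizing the
# pooled intra-class variance.  Returns NA when the values are constant.
otsu_split <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(t) {
    a <- v[v <= t]; b <- v[v > t]
    va <- if (length(a) > 1) stats::var(a) else 0
    vb <- if (length(b) > 1) stats::var(b) else 0
    (length(a) * va + length(b) * vb) / length(v)
  }, numeric(1))
  cand[which.min(wcv)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cyclic runs of TRUE in a logical vector; returns data.frame(start, len)
# with 1-based starts, merging a wrap-around run.
cyclic_runs <- function(z) {
  n <- length(z)
  if (!any(z)) return(data.frame(start = integer(0), len = integer(0)))
  if (all(z)) return(data.frame(start = 1L, len = n))
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], len = r$lengths[r$values])
  # merge run touching the end with run starting at 1 (cyclic wrap)
  if (z[1] && z[n]) {
    first <- which(runs$start == 1L)
    last <- which(runs$start + runs$len - 1L == n)
    if (length(first) && length(last) && first != last) {
      runs$start[last] <- runs$start[last]
      runs$len[last] <- runs$len[last] + runs$len[first]
      runs <- runs[-first, , drop = FALSE]
    }
  }
  runs
}

# bins of a cyclic run
run_bins <- function(start, len, n) ((start - 1L + seq_len(len) - 1L) %% n) + 1L

#' Segment an angular profile into Lo and Ld arcs
#'
#' Classifies angular bins from the lipid-marker channel, which enriches the
#' Ld phase: the brighter class is Ld.  The two-class split minimizes the
#' intra-class variance of the bin means (Otsu-style); cyclic contiguity is
#' then enforced — the largest contiguous run of each class wins (ties
#' broken toward the run with higher mean contrast), and conflicting bins
#' are excluded — producing the Janus two-arc morphology.  Finally
#' `boundary_exclusion` bins are dropped on each side of each of the two
#' phase boundaries.
#'
#' @param profile an [extract_angular_profile()] result.
#' @param lipid_channel index of the lipid-marker channel (default 1).
#' @param options a [segmentation_options()].
#' @return object of class `phase_segmentation`: list with `labels`
#'   (character vector per bin: `"Lo"`, `"Ld"`, `"excluded"`), `ld_arc` and
#'   `lo_arc` (cyclic `(start, end)` bin indices, 1-based, after exclusion),
#'   `boundary_exclusion`, `separation_score`.
#' @export
segment_phases <- function(profile, lipid_channel = 1L,
                           options = segmentation_options()) {
  stopifnot(inherits(profile, "angular_profile"))
  v <- profile$mean[, lipid_channel]
  n <- profile$n_bins
  thr <- otsu_split(v)
  if (is.na(thr)) {
    stop("not phase-separated: lipid-channel profile has no two-level structure",
         call. = FALSE)
  }
  bright <- v > thr                       # candidate Ld (lipid marker enriches Ld)
  runs_ld <- cyclic_runs(bright)
  runs_lo <- cyclic_runs(!bright)
  pick <- function(runs, other_mean) {
    best <- which(runs$len == max(runs$len))
    if (length(best) > 1L) {
      contrast <- vapply(best, function(i) {
        mean(abs(v[run_bins(runs$start[i], runs$len[i], n)] - other_mean))
      }, numeric(1))
      best <- best[which.max(contrast)]
    }
    runs[best[1], ]
  }
  ld_run <- pick(runs_ld, mean(v[!bright]))
  lo_run <- pick(runs_lo, mean(v[bright]))

  labels <- rep("excluded", n)
  ld_bins <- run_bins(ld_run$start, ld_run$len, n)
  lo_bins <- run_bins(lo_run$start, lo_run$len, n)
  be <- options$boundary_exclusion
  trim <- function(bins) {
    if (length(bins) <= 2 * be) return(integer(0))
    if (be == 0) bins else bins[(be + 1):(length(bins) - be)]
  }
  ld_keep <- trim(ld_bins)
  lo_keep <- trim(lo_bins)
  if (length(ld_keep) < options$min_arc_bins ||
      length(lo_keep) < options$min_arc_bins) {
    stop("degenerate arc: fewer than ", options$min_arc_bins,
         " bins remain after boundary exclusion", call. = FALSE)
  }
  labels[ld_keep] <- "Ld"
  labels[lo_keep] <- "Lo"

  m_ld <- mean(v[ld_keep]); m_lo <- mean(v[lo_keep])
  s_ld <- if (length(ld_keep) > 1) stats::sd(v[ld_keep]) else 0
  s_lo <- if (length(lo_keep) > 1) stats::sd(v[lo_keep]) else 0
  pooled <- sqrt(((length(ld_keep) - 1) * s_ld^2 +
                  (length(lo_keep) - 1) * s_lo^2) /
                 max(length(ld_keep) + length(lo_keep) - 2, 1))
  sep <- if (pooled == 0) {
    if (m_ld > m_lo) Inf else 0
  } else {
    (m_ld - m_lo) / pooled
  }
  if (sep < options$min_separation) {
    stop(sprintf("not phase-separated: separation score %.2f below threshold %.2f",
                 sep, options$min_separation), call. = FALSE)
  }
  structure(list(labels = labels,
                 ld_arc = c(start = ld_keep[1], end = ld_keep[length(ld_keep)]),
                 lo_arc = c(start = lo_keep[1], end = lo_keep[length(lo_keep)]),
                 boundary_exclusion = be,
                 separation_score = sep),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> Ld %d bins, Lo %d bins, %d excluded; separation %.2f\n",
              sum(x$labels == "Ld"), sum(x$labels == "Lo"),
              sum(x$labels == "excluded"), x$separation_score))
  invisible(x)
}
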