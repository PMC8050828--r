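#' Summarize a population of partition records
#'
#' Aggregates per-vesicle fractional intensities into the population-level
#' summary used for box-scatter panels: n, mean, SD, median and quartiles of
#' f, plus the per-vesicle free energies (computed vesicle-by-vesicle via
#' [fraction_to_dG()] and then averaged; vesicles with f exactly 0 or 1 are
#' excluded from the dG average and counted).
#'
#' @param records data.frame of partition records (column `f_p_Lo`,
#'   optionally `radius`), or a numeric vector of f values.
#' @param label population label for the summary row.
#' @return one-row data.frame: `population_label`, `n`, `mean_f`, `sd_f`,
#'   `median_f`, `q1_f`, `q3_f`, `mean_dG`, `sd_dG`, `n_dG_excluded`,
#'   `flags`.
#' @export
summarize_population <- function(records, label = NA_character_) {
  f <- if (is.data.frame(records)) records$f_p_Lo else as.numeric(records)
  if (length(f) < 1L) {
    stop("no records to summarize (all vesicles removed by quality gates)",
         call. = FALSE)
  }
  q <- stats::quantile(f, c(0.25, 0.5, 0.75), names = FALSE)
  inset <- f > 0 & f < 1
  dg <- if (any(inset)) fraction_to_dG(f[inset]) else numeric(0)
  flags <- character(0)
  if (length(f) == 1L) flags <- c(flags, "n=1")
  data.frame(population_label = label, n = length(f),
             mean_f = mean(f),
             sd_f = if (length(f) > 1) stats::sd(f) else 0,
             median_f = q[2], q1_f = q[1], q3_f = q[3],
             mean_dG = if (length(dg)) mean(dg) else NA_real_,
             sd_dG = if (length(dg) > 1) stats::sd(dg) else 0,
             n_dG_excluded = sum(!inset),
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Summarize per repeat and pooled
#'
#' Computes one summary row per experimental repeat plus a pooled row over
#' all records; the pooled mean always lies between the repeat means.
#'
#' @param records data.frame with columns `f_p_Lo` and `repeat_id`.
#' @param label population label.
#' @return data.frame of summary rows with a `repeat_id` column
#'   (`"pooled"` for the pooled row).
#' @export
summarize_repeats <- function(records, label = NA_character_) {
  stopifnot("repeat_id" %in% names(records))
  reps <- sort(unique(records$repeat_id))
  out <- do.call(rbind, lapply(reps, function(r) {
    s <- summarize_population(records[records$repeat_id == r, ], label)
    s$repeat_id <- as.character(r)
    s
  }))
  pooled <- summarize_population(records, label)
  pooled$repeat_id <- "pooled"
  rbind(out, pooled)
}

#' Compare two populations with the Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the fractional
#' intensities of two populations: exact enumeration when the smaller sample
#' has at most 8 observations and there are no ties, tie-corrected normal
#' approximation otherwise.  Symmetric in its arguments.  Fully degenerate
#' input (every value identical in both samples) yields p = 1 with a flag.
#'
#' @param a,b numeric vectors of f values, or record data.frames (column
#'   `f_p_Lo`); each n >= 3.
#' @return list: `statistic` (W), `p_value`, `method`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
compare_populations <- function(a, b) {
  fa <- if (is.data.frame(a)) a$f_p_Lo else as.numeric(a)
  fb <- if (is.data.frame(b)) b$f_p_Lo else as.numeric(b)
  if (length(fa) < 3L || length(fb) < 3L) {
    stop("both samples must have n >= 3", call. = FALSE)
  }
  if (length(unique(c(fa, fb))) == 1L) {
    return(list(statistic = length(fa) * length(fb) / 2, p_value = 1,
                method = "degenerate", n_a = length(fa), n_b = length(fb),
                degenerate = TRUE))
  }
  ties <- any(duplicated(c(fa, fb)))
  use_exact <- min(length(fa), length(fb)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(fa, fb, alternative = "two.sided",
                       exact = use_exact, correct = !use_exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation, tie-corrected",
       n_a = length(fa), n_b = length(fb), degenerate = FALSE)
}

#' Test independence of partitioning from vesicle radius
#'
#' Spearman rank correlation of f against vesicle radius across a
#' radius-dispersed population.  Partitioning is a per-molecule membrane
#' property, so f should not correlate with vesicle size.
#'
#' @param records data.frame with columns `f_p_Lo` and `radius`.
#' @return list: `rho`, `p_value`, `n`.
#' @export
radius_independence <- function(records) {
  stopifnot(all(c("f_p_Lo", "radius") %in% names(records)))
  if (nrow(records) < 5L) stop("need n >= 5 records", call. = FALSE)
  if (stats::sd(records$radius) == 0) {
    stop("zero radius variance: population has no size dispersion",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(records$f_p_Lo, records$radius, method = "spearman",
                    exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(records))
}

#' Summarize a labelling-density sweep
#'
#' Groups records by their DNA-to-lipid labelling ratio and reports the
#' per-group mean and SD of f, sorted by ascending ratio, together with a
#' flatness statistic: the maximum absolute deviation of a group mean from
#' the grand mean over the stated stationary range.  No model is fitted.
#'
#' @param records data.frame with columns `f_p_Lo` and `dna_to_lipid_ratio`.
#' @param stationary_range ratios (inclusive interval) over which flatness
#'   is assessed; default spans all groups.
#' @return list with `table` (data.frame: `dna_to_lipid_ratio`, `n`,
#'   `mean_f`, `sd_f`) and `flatness`.
#' @export
density_sweep <- function(records, stationary_range = NULL) {
  stopifnot(all(c("f_p_Lo", "dna_to_lipid_ratio") %in% names(records)))
  ratios <- sort(unique(records$dna_to_lipid_ratio))
  if (length(ratios) < 2L) {
    stop("density sweep needs at least two ratio groups", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(ratios, function(r) {
    f <- records$f_p_Lo[records$dna_to_lipid_ratio == r]
    data.frame(dna_to_lipid_ratio = r, n = length(f), mean_f = mean(f),
               sd_f = if (length(f) > 1) stats::sd(f) else 0)
  }))
  if (is.null(stationary_range)) stationary_range <- range(ratios)
  in_range <- tab$dna_to_lipid_ratio >= stationary_range[1] &
              tab$dna_to_lipid_ratio <= stationary_range[2]
  grand <- mean(tab$mean_f[in_range])
  flatness <- max(abs(tab$mean_f[in_range] - grand))
  list(table = tab, flatness = flatness)
}
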