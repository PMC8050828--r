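#' Default run configuration
#'
#' Nested configuration for the four pipeline commands, YAML-serializable
#' and mergeable with a user file via [read_config()].  Channel roles:
#' channel 1 is the lipid-phase marker (enriches Ld), channel 2 the
#' construct label.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    channels = list(lipid = 1L, construct = 2L),
    simulate = list(
      frame_size = 320L, psf_sigma = 1.5, ring_sigma = 1.5,
      background = c(50, 50), noise_model = "poisson",
      crosstalk = c(1, 0, 0, 1),          # row-major 2x2
      per_frame = 4L,
      populations = list(
        list(label = "sC", n_vesicles = 20L, dG_true = -0.4),
        list(label = "sT", n_vesicles = 20L, dG_true = 1.9)
      )
    ),
    detect = list(threshold_k = 5, min_pixels = 80, quality_min = 0.5,
                  n_bins = 72L),
    segment = list(boundary_exclusion = 2L, min_separation = 2,
                   min_arc_bins = 4L),
    analyze = list(
      anchor_library = NULL,              # NULL = default_anchor_library()
      designs = list(
        list(name = "dC", anchors = c("sC", "sC"), measured_label = "dC")
      )
    ),
    dynamics = list(tau = 5, state2_mode = "additive", hysteresis = 0,
                    dt = 0.1)
  )
}

#' Read a YAML run configuration, merged over the defaults
#'
#' Keys present in the file override the defaults of [default_config()];
#' missing keys keep their default values.  The channel-role mapping is
#' validated (roles must be distinct).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    config <- modify_list_deep(config, user)
  }
  validate_config(config)
  config
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  ch <- config$channels
  if (is.null(ch$lipid) || is.null(ch$construct) ||
      ch$lipid == ch$construct || !all(c(ch$lipid, ch$construct) %in% 1:2)) {
    stop("invalid channel mapping: lipid and construct roles must be distinct channels 1/2",
         call. = FALSE)
  }
  invisible(config)
}

config_imaging <- function(config) {
  s <- config$simulate
  imaging_params(frame_size = s$frame_size, psf_sigma = s$psf_sigma,
                 background = s$background, noise_model = s$noise_model,
                 crosstalk = matrix(as.numeric(s$crosstalk), 2, 2, byrow = TRUE),
                 ring_sigma = s$ring_sigma)
}

#' Simulate all configured populations to disk
#'
#' Renders every population in `config$simulate$populations` into 16-bit
#' two-channel TIFF frames, one ground-truth CSV per population and a
#' manifest CSV listing every artifact with its per-frame seed and
#' checksum.  Identical config + seed reproduce identical files.
#'
#' @param config configuration list (see [read_config()]).
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = 1L) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  imaging <- config_imaging(config)
  manifest <- NULL
  for (ip in seq_along(config$simulate$populations)) {
    pop <- config$simulate$populations[[ip]]
    params <- do.call(population_params, pop[setdiff(names(pop), "label")])
    pop_seed <- (as.integer(seed) + 104729L * ip) %% .Machine$integer.max
    sim <- simulate_frames(params, imaging, seed = pop_seed,
                           per_frame = config$simulate$per_frame)
    for (fr in seq_along(sim$frames)) {
      file <- file.path(out_dir, sprintf("%s_frame%03d.tif", pop$label, fr))
      write_frame_tiff(sim$frames[[fr]], file)
      manifest <- rbind(manifest, data.frame(
        file = basename(file), population_label = pop$label, frame = fr,
        seed = pop_seed, md5 = unname(tools::md5sum(file))))
    }
    truth_file <- file.path(out_dir, sprintf("%s_truth.csv", pop$label))
    utils::write.csv(sim$truth, truth_file, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      file = basename(truth_file), population_label = pop$label, frame = NA,
      seed = pop_seed, md5 = unname(tools::md5sum(truth_file))))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Quantify every TIFF frame in a directory
#'
#' Runs detect -> profile -> segment -> partition on each two-channel TIFF,
#' labelling records from the simulation manifest when present (otherwise
#' from the file-name prefix before `_frame`).  Unreadable files are
#' reported and skipped; the run continues.  An empty result is a valid
#' outcome and yields a header-only CSV.
#'
#' @param config configuration list.
#' @param image_dir directory of TIFF frames.
#' @param out_dir where to write `records.csv` and `quantify_log.csv`
#'   (`NULL` skips writing).
#' @param crosstalk optional 2x2 matrix applied as cross-talk correction.
#' @return list with `records`, `log` and `file_errors` (character vector).
#' @export
run_quantify <- function(config, image_dir, out_dir = NULL, crosstalk = NULL) {
  validate_config(config)
  det <- detection_options(threshold_k = config$detect$threshold_k,
                           min_pixels = config$detect$min_pixels,
                           quality_min = config$detect$quality_min)
  seg <- segmentation_options(boundary_exclusion = config$segment$boundary_exclusion,
                              min_separation = config$segment$min_separation,
                              min_arc_bins = config$segment$min_arc_bins)
  files <- sort(list.files(image_dir, pattern = "\\.tiff?$", full.names = TRUE))
  labels <- sub("_frame.*$", "", basename(files))
  manifest_path <- file.path(image_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    m <- match(basename(files), man$file)
    labels[!is.na(m)] <- man$population_label[m[!is.na(m)]]
  }
  records <- compute_partition_template()
  records$frame_file <- character(0)
  logs <- NULL; file_errors <- character(0)
  for (i in seq_along(files)) {
    res <- tryCatch({
      frame <- read_frame_tiff(files[i])
      q <- quantify_frame(frame, population_label = labels[i],
                          crosstalk = crosstalk,
                          detection = det, segmentation = seg,
                          n_bins = config$detect$n_bins,
                          lipid_channel = config$channels$lipid,
                          construct_channel = config$channels$construct)
      if (nrow(q$records)) q$records$frame_file <- basename(files[i])
      if (nrow(q$log)) q$log$frame_file <- basename(files[i])
      q
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      file_errors <- c(file_errors,
                       sprintf("%s: %s", basename(files[i]), res))
    } else {
      records <- rbind(records, res$records)
      if (nrow(res$log)) logs <- rbind(logs, res$log)
    }
  }
  if (length(file_errors)) {
    message("skipped ", length(file_errors), " unreadable file(s):\n  ",
            paste(file_errors, collapse = "\n  "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    if (!is.null(logs)) {
      utils::write.csv(logs, file.path(out_dir, "quantify_log.csv"),
                       row.names = FALSE)
    }
  }
  list(records = records, log = logs, file_errors = file_errors)
}

#' Analyze partition records into population-level outputs
#'
#' Produces per-population summaries, all pairwise Mann-Whitney comparisons,
#' and (when the configuration lists multi-anchor designs) the additive
#' free-energy prediction report: predicted vs measured dG and the
#' nonadditivity for each design whose measured population is present.
#' Designs naming an unknown population are listed and skipped.  When more
#' than 3 pairwise comparisons are run an uncorrected-multiplicity flag is
#' attached.
#'
#' @param records data.frame of partition records (or path to records CSV).
#' @param config configuration list.
#' @param out_dir optional directory for `summaries.csv`,
#'   `comparisons.csv`, `predictions.csv` and the two figure files.
#' @return list: `summaries`, `comparisons`, `predictions`,
#'   `skipped_designs`, `multiplicity_flag`.
#' @export
run_analyze <- function(records, config = default_config(), out_dir = NULL) {
  if (is.character(records)) {
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  if (!nrow(records)) stop("no records to analyze", call. = FALSE)
  labels <- unique(records$population_label)
  summaries <- do.call(rbind, lapply(labels, function(l) {
    summarize_population(records[records$population_label == l, ], l)
  }))
  comparisons <- NULL
  if (length(labels) > 1) {
    prs <- utils::combn(labels, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      a <- records$f_p_Lo[records$population_label == prs[1, j]]
      b <- records$f_p_Lo[records$population_label == prs[2, j]]
      ct <- compare_populations(a, b)
      data.frame(population_a = prs[1, j], population_b = prs[2, j],
                 statistic = ct$statistic, p_value = ct$p_value,
                 method = ct$method)
    }))
  }
  multiplicity_flag <- !is.null(comparisons) && nrow(comparisons) > 3

  lib <- config$analyze$anchor_library
  if (is.null(lib)) lib <- default_anchor_library()
  if (!is.data.frame(lib)) lib <- as.data.frame(lib, stringsAsFactors = FALSE)
  predictions <- NULL; skipped <- character(0)
  for (ds in config$analyze$designs) {
    if (!ds$measured_label %in% labels) {
      skipped <- c(skipped, ds$name)
      next
    }
    dg_i <- vapply(ds$anchors, function(a) anchor_dG(lib, a), numeric(1))
    design <- construct_design(ds$name, dg_i)
    dg_pred <- predict_additive(design)
    s <- summaries[summaries$population_label == ds$measured_label, ]
    predictions <- rbind(predictions, data.frame(
      design = ds$name, dG_pred = dg_pred, dG_measured = s$mean_dG,
      nonadditivity = nonadditivity(s$mean_dG, dg_pred),
      f_pred = dG_to_fraction(dg_pred), f_measured = s$mean_f))
  }
  if (length(skipped)) {
    message("designs skipped (population label not in records): ",
            paste(skipped, collapse = ", "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    if (!is.null(predictions)) {
      utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
    }
    save_figure(plot_box_scatter(records),
                file.path(out_dir, "box_scatter.png"))
    if (!is.null(predictions)) {
      save_figure(plot_measured_vs_predicted(predictions),
                  file.path(out_dir, "measured_vs_predicted.png"))
    }
  }
  list(summaries = summaries, comparisons = comparisons,
       predictions = predictions, skipped_designs = skipped,
       multiplicity_flag = multiplicity_flag)
}

#' Run a fuel/antifuel protocol and write the annotated trace
#'
#' @param protocol data.frame (`time_min`, `cue`) or path to a YAML/CSV
#'   protocol file (YAML: list of `{time_min, cue}`; CSV: two columns).
#' @param config configuration list (section `dynamics`).
#' @param out_csv optional path for the trace CSV.
#' @return the `protocol_trace` data.frame.
#' @export
run_dynamics <- function(protocol, config = default_config(), out_csv = NULL) {
  if (is.character(protocol)) {
    protocol <- if (grepl("\\.ya?ml$", protocol)) {
      steps <- yaml::read_yaml(protocol)
      do.call(rbind, lapply(steps, function(s) {
        data.frame(time_min = as.numeric(s$time_min), cue = s$cue)
      }))
    } else {
      utils::read.csv(protocol, stringsAsFactors = FALSE)
    }
  }
  dy <- config$dynamics
  trace <- simulate_protocol(protocol,
                             state2_mode = dy$state2_mode,
                             hysteresis = dy$hysteresis,
                             tau = dy$tau, dt = dy$dt)
  if (!is.null(out_csv)) {
    utils::write.csv(trace, out_csv, row.names = FALSE)
  }
  trace
}
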