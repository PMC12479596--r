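#' Default analysis configuration
#'
#' Returns the full nested configuration with the standard analysis
#' parameters: cluster range 1-12 with 300 restarts, merge threshold 0.80,
#' back-fit threshold 0.5 with smoothing window half-size 3 and strength 10,
#' 5000 permutations and 5000 bootstrap resamples; the simulation block
#' encodes the emulated study design (two groups of 18, 250 Hz, 4 maps,
#' snr 4).
#'
#' @return Nested named list, see [validate_config()] for the documented
#'   ranges.
#' @export
default_config <- function() {
  list(
    simulation = list(n_per_group = 18L, n_channels = 64L, duration_s = 240,
                      sfreq = 250, n_maps = 4L, snr = 4,
                      dwell_mean_ms = 80, dwell_effect = 1.3,
                      effect_map = 3L, transition_effect = 1.5,
                      transition_from = 2L, transition_to = 3L),
    preprocessing = list(low_hz = 1, high_hz = 40, notch_hz = 50,
                         target_hz = 250),
    clustering = list(k_range = c(1L, 12L), restarts = 300L,
                      merge_threshold = 0.80, subject_k = NULL,
                      group_k = NULL),
    backfit = list(threshold = 0.5, half_window = 3L, strength = 10),
    statistics = list(alpha = 0.05, n_perm = 5000L, n_boot = 5000L),
    spectral = list(max_resolution_hz = 0.034),
    seed = 1L)
}

config_ranges <- function() {
  list(
    "simulation.n_per_group"   = c(2, Inf),
    "simulation.n_channels"    = c(8, 512),
    "simulation.duration_s"    = c(1, Inf),
    "simulation.sfreq"         = c(50, 10000),
    "simulation.n_maps"        = c(2, 7),
    "simulation.snr"           = c(1e-6, Inf),
    "simulation.dwell_mean_ms" = c(1, 10000),
    "preprocessing.low_hz"     = c(1e-6, Inf),
    "preprocessing.high_hz"    = c(1e-6, Inf),
    "preprocessing.target_hz"  = c(1, Inf),
    "clustering.restarts"      = c(1, Inf),
    "clustering.merge_threshold" = c(0, 1),
    "backfit.threshold"        = c(0, 1),
    "backfit.half_window"      = c(0, Inf),
    "backfit.strength"         = c(0, Inf),
    "statistics.alpha"         = c(1e-12, 1),
    "statistics.n_perm"        = c(10, Inf),
    "statistics.n_boot"        = c(10, Inf))
}

#' Validate an analysis configuration
#'
#' Checks every documented field against its allowed range and returns the
#' violations (an empty character vector means the configuration is valid).
#' Missing required blocks/fields are reported too.
#'
#' @param config nested configuration list (see [default_config()]).
#' @return Character vector of violations, empty when valid.
#' @export
validate_config <- function(config) {
  viol <- character(0)
  required <- c("preprocessing", "clustering", "backfit", "statistics", "seed")
  for (blk in required) {
    if (is.null(config[[blk]]))
      viol <- c(viol, sprintf("missing required field `%s`", blk))
  }
  if (is.null(config$simulation) && is.null(config$input))
    viol <- c(viol, "missing required field `simulation` (or `input`)")
  rng <- config_ranges()
  for (key in names(rng)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- config[[parts[1]]][[parts[2]]]
    if (is.null(val)) next
    lo <- rng[[key]][1]; hi <- rng[[key]][2]
    if (!is.numeric(val) || any(val < lo | val > hi))
      viol <- c(viol, sprintf("`%s` = %s outside allowed range [%g, %g]",
                              key, paste(val, collapse = ","), lo, hi))
  }
  kr <- config$clustering$k_range
  if (!is.null(kr) && (length(kr) != 2 || kr[1] < 1 || kr[2] < kr[1] ||
                       kr[2] > 20))
    viol <- c(viol, "`clustering.k_range` must be c(min, max) with 1 <= min <= max <= 20")
  lh <- c(config$preprocessing$low_hz, config$preprocessing$high_hz)
  if (length(lh) == 2 && is.numeric(lh) && lh[1] >= lh[2])
    viol <- c(viol, "`preprocessing.low_hz` must be below `preprocessing.high_hz`")
  viol
}

#' Hash a configuration for provenance
#'
#' MD5 of the canonical JSON serialization; any parameter change changes the
#' hash, which is stamped into every pipeline output.
#'
#' @param config configuration list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tf))
}

read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

load_input_recordings <- function(input) {
  files <- sort(list.files(input$recordings_dir, full.names = TRUE,
                           pattern = input$pattern %||% "\\.(txt|tsv|edf)$"))
  if (!length(files))
    stop("no input recordings found in `", input$recordings_dir, "`")
  meta <- NULL
  if (!is.null(input$metadata_csv)) {
    if (!file.exists(input$metadata_csv))
      stop("metadata file not found: `", input$metadata_csv, "`")
    meta <- read.csv(input$metadata_csv, stringsAsFactors = FALSE)
  }
  recs <- lapply(files, function(f) {
    rec <- if (grepl("\\.edf$", f)) read_edf(f) else read_recording_txt(f)
    if (!is.null(meta) && rec$subject_id %in% meta$subject_id)
      rec$group <- meta$group[match(rec$subject_id, meta$subject_id)]
    rec
  })
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}

#' Run the full microstate analysis pipeline
#'
#' Orchestrates simulation (or reading of input recordings), preprocessing
#' (band-pass + notch, common average reference, downsampling), the
#' microstate model fit, group statistics (Mann-Whitney parameter tests with
#' the Li-Ji/Sidak-adjusted alpha, transition t tests, per-map TANOVA) and
#' band-power analysis, and writes a deterministic directory of CSV/JSON
#' outputs plus a log. Re-running with the same configuration and seed
#' reproduces the summary byte for byte.
#'
#' @param config nested configuration list (see [default_config()]) or a
#'   path to a YAML/JSON file. A `simulation` block generates the cohort; an
#'   `input` block (`recordings_dir`, optional `metadata_csv`) reads
#'   recordings from disk instead.
#' @param output_dir results directory (created if needed).
#' @return Invisibly, a list with the fitted model, summary tables, band
#'   powers and the output directory.
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile("msrun")) {
  if (is.character(config)) config <- read_config(config)
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  logf <- file.path(output_dir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), " ",
                               sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("config hash %s, seed %d", hash, seed)

  if (!is.null(config$input)) {
    recs <- load_input_recordings(config$input)
    montage <- if (!is.null(config$input$montage_xyz))
      read_montage_xyz(config$input$montage_xyz) else NULL
    logline("loaded %d recordings", length(recs))
  } else {
    sim <- config$simulation
    montage <- make_montage(sim$n_channels)
    tm <- make_template_maps(sim$n_maps, montage, seed = child_seed(seed, 101))
    truth <- simulation_truth(
      tm, dwell_mean_ms = sim$dwell_mean_ms, snr = sim$snr,
      group_effects = list(dwell_map = sim$effect_map,
                           dwell_factor = sim$dwell_effect,
                           transition_from = sim$transition_from,
                           transition_to = sim$transition_to,
                           transition_factor = sim$transition_effect),
      seed = seed)
    coh <- simulate_cohort(sim$n_per_group, truth,
                           duration_s = sim$duration_s, sfreq = sim$sfreq,
                           montage = montage, seed = child_seed(seed, 102))
    recs <- coh$recordings
    write_truth_json(truth, file.path(output_dir, "truth.json"))
    write.csv(coh$truth_metrics, file.path(output_dir, "truth_metrics.csv"),
              row.names = FALSE)
    logline("simulated %d recordings (%g s at %g Hz, snr %g)",
            length(recs), sim$duration_s, sim$sfreq, sim$snr)
  }

  pp <- config$preprocessing
  recs <- lapply(recs, function(r) {
    r <- bandpass_notch(r, pp$low_hz, pp$high_hz, pp$notch_hz)
    r <- average_reference(r)
    if (r$sfreq > pp$target_hz) r <- downsample(r, pp$target_hz)
    r
  })
  logline("preprocessed (%g-%g Hz, notch %g, %g Hz)", pp$low_hz, pp$high_hz,
          pp$notch_hz, pp$target_hz)

  clu <- config$clustering
  bf <- config$backfit
  fit <- microstate_fit(recs,
                        k = clu$group_k,
                        k_range = seq(clu$k_range[1], clu$k_range[2]),
                        subject_k = clu$subject_k,
                        restarts = clu$restarts,
                        merge_threshold = clu$merge_threshold,
                        threshold = bf$threshold,
                        half_window = bf$half_window,
                        strength = bf$strength,
                        seed = child_seed(seed, 103))
  logline("fitted %d maps, GEV %.2f%%", fit$k, 100 * fit$gev_total)

  tmpl <- as.data.frame(fit$templates$maps)
  names(tmpl) <- recs[[1]]$channel_labels
  write.csv(cbind(map = fit$map_labels, tmpl),
            file.path(output_dir, "templates.csv"), row.names = FALSE)
  write.csv(fit$metrics, file.path(output_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(fit$transitions, file.path(output_dir, "transitions.csv"),
            row.names = FALSE)

  st <- config$statistics
  smry <- summary(fit, alpha = st$alpha)
  if (!is.null(smry$parameter_tests))
    write.csv(smry$parameter_tests,
              file.path(output_dir, "stats_parameters.csv"),
              row.names = FALSE)
  if (!is.null(smry$transition_tests))
    write.csv(smry$transition_tests,
              file.path(output_dir, "stats_transitions.csv"),
              row.names = FALSE)

  # per-map TANOVA between groups on subject mean topographies
  groups <- vapply(recs, function(r) r$group, character(1))
  tanova_rows <- NULL
  if (length(unique(na.omit(groups))) == 2) {
    for (m in seq_len(fit$k)) {
      subj_maps <- t(vapply(names(recs), function(id) {
        seg <- fit$segmentations[[id]]
        rec <- average_reference(recs[[id]])
        sel <- seg$labels == m
        if (!any(sel)) return(rep(NA_real_, nrow(rec$data)))
        # polarity-align samples to the template before averaging
        x <- rec$data[, sel, drop = FALSE]
        sgn <- sign(as.numeric(fit$templates$maps[m, ] %*% x))
        sgn[sgn == 0] <- 1
        rowMeans(x * rep(sgn, each = nrow(x)))
      }, numeric(nrow(recs[[1]]$data))))
      ok <- apply(is.finite(subj_maps), 1, all)
      ga <- subj_maps[ok & groups == "A", , drop = FALSE]
      gb <- subj_maps[ok & groups == "B", , drop = FALSE]
      if (nrow(ga) >= 2 && nrow(gb) >= 2) {
        tv <- tanova(ga, gb, n_perm = st$n_perm,
                     seed = child_seed(seed, 200 + m))
        tanova_rows <- rbind(tanova_rows,
                             data.frame(map = fit$map_labels[m],
                                        diss = tv$statistic, p = tv$p))
      }
    }
    if (!is.null(tanova_rows))
      write.csv(tanova_rows, file.path(output_dir, "tanova.csv"),
                row.names = FALSE)
  }
  logline("group statistics done")

  # band power per subject, Mann-Whitney per band when two groups exist
  bp_rows <- lapply(names(recs), function(id) {
    sp <- power_spectrum(recs[[id]],
                         max_resolution_hz = config$spectral$max_resolution_hz %||% 0.034)
    b <- band_power(sp)
    b$subject <- id
    b$group <- recs[[id]]$group
    b
  })
  bp <- do.call(rbind, bp_rows)
  write.csv(bp, file.path(output_dir, "band_power.csv"), row.names = FALSE)
  band_tests <- NULL
  if (length(unique(na.omit(groups))) == 2) {
    for (b in unique(bp$band)) {
      xa <- bp$power[bp$band == b & bp$group == "A"]
      xb <- bp$power[bp$band == b & bp$group == "B"]
      tst <- mann_whitney(xa, xb)
      band_tests <- rbind(band_tests,
                          data.frame(band = b, U = tst$statistic, p = tst$p,
                                     cliffs_delta = tst$effect))
    }
    write.csv(band_tests, file.path(output_dir, "stats_bands.csv"),
              row.names = FALSE)
  }
  logline("spectral analysis done")

  summary_json <- list(
    config_hash = hash, seed = seed,
    n_subjects = length(recs),
    k = fit$k, gev_total = fit$gev_total,
    map_labels = fit$map_labels,
    alpha_parameters = smry$alpha_parameters %||% st$alpha,
    alpha_transitions = smry$alpha_transitions %||% st$alpha,
    parameter_tests = smry$parameter_tests,
    transition_tests = smry$transition_tests,
    tanova = tanova_rows,
    band_tests = band_tests)
  jsonlite::write_json(summary_json, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  logline("wrote %s", file.path(output_dir, "summary.json"))
  invisible(list(fit = fit, summary = smry, tanova = tanova_rows,
                 band_power = bp, band_tests = band_tests,
                 output_dir = output_dir, config_hash = hash))
}
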