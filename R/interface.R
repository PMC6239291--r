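# Allowed configuration keys per subcommand; unknown keys are rejected so
# that typos cannot silently fall back to defaults.
subcommand_keys <- list(
  `simulate-video` = c("rate", "amplitude", "fps", "duration", "jitter",
                       "noise", "drift", "seed", "frame_dim", "out"),
  respirate = c("video", "roi", "band", "min_clips", "prominence_min",
                "ibi_cv_max", "out"),
  lungct = c("volume", "units", "lo", "hi", "out"),
  `simulate-cohort` = c("doses", "n_per_dose", "ed50", "hill_slope",
                        "field_multiplier", "seed", "out"),
  cohort = c("in", "control_dose", "timepoint", "fallback", "k",
             "null_model", "out"))

#' Run a configured analysis
#'
#' Single entry point behind the `vivorate` command line. A run
#' configuration is a list (or path to a JSON file) with a `subcommand`
#' and that subcommand's parameters; unknown keys are rejected. Every
#' random operation receives an explicit seed, outputs are deterministic
#' for a fixed configuration, a run manifest (configuration, its MD5
#' hash, package and R versions, timestamp) is written beside the
#' results, and partially written outputs are removed on error.
#'
#' Subcommands: `simulate-video` (render a synthetic breathing clip with
#' ground truth), `respirate` (respiratory rate from a frame stack),
#' `lungct` (healthy-lung volume and ROI densitometry from a volume file),
#' `simulate-cohort` (synthetic cohort CSV with ground truth) and `cohort`
#' (full cohort statistics from a CSV).
#'
#' @param config A named list or the path to a JSON configuration file.
#' @return Invisibly, a list of the paths written.
#' @export
vivo_run <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$subcommand) ||
      !config$subcommand %in% names(subcommand_keys))
    stop_bad_input("config must name a subcommand: ",
                   paste(names(subcommand_keys), collapse = ", "))
  sub <- config$subcommand
  keys <- setdiff(names(config), "subcommand")
  unknown <- setdiff(keys, subcommand_keys[[sub]])
  if (length(unknown))
    stop_bad_input("unknown config key(s) for ", sub, ": ",
                   paste(unknown, collapse = ", "))
  out_dir <- config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE), add = TRUE)

  result <- switch(
    sub,
    `simulate-video` = {
      sc <- breathing_scenario(
        rate_bpm = config$rate %||% 150,
        amplitude_px = config$amplitude %||% 2,
        fps = config$fps %||% 30,
        duration_s = config$duration %||% 20,
        jitter_cv = config$jitter %||% 0,
        drift_px_per_s = config$drift %||% c(0, 0),
        noise_sd = config$noise %||% 0,
        seed = config$seed %||% 1L,
        frame_dim = config$frame_dim %||% c(256L, 256L))
      clip <- render_breathing_clip(sc)
      note(write_frames(clip$frames, file.path(out_dir, "frames")))
      tr <- clip$truth
      jsonlite::write_json(
        list(true_rate_bpm = tr$true_rate_bpm,
             breath_onsets_s = tr$breath_onsets_s,
             displacement_series = tr$displacement_series),
        note(file.path(out_dir, "ground_truth.json")),
        auto_unbox = TRUE, digits = NA)
      list(true_rate_bpm = tr$true_rate_bpm)
    },
    respirate = {
      seq <- read_frames(config$video)
      roi <- config$roi %||% "auto"
      if (is.character(roi) && !identical(roi, "auto")) {
        rj <- jsonlite::read_json(roi, simplifyVector = TRUE)
        roi <- if (is.list(rj)) lapply(rj, as.matrix) else as.matrix(rj)
      }
      band <- config$band %||% c(60, 400)
      est <- measure_respiration(seq, rois = roi, band_bpm = band,
                                 prominence_min = config$prominence_min %||% 5,
                                 ibi_cv_max = config$ibi_cv_max %||% 0.25)
      sig <- attr(est, "signal")
      write.csv(data.frame(t_s = (seq_along(sig$samples) - 1) / sig$fps,
                           amplitude = sig$samples),
                note(file.path(out_dir, "waveform.csv")), row.names = FALSE)
      jsonlite::write_json(
        list(rate_bpm = est$rate_bpm, band_bpm = est$band_bpm,
             peak_prominence = est$peak_prominence, ibi_cv = est$ibi_cv,
             qc_pass = est$qc_pass),
        note(file.path(out_dir, "rate.json")), auto_unbox = TRUE, digits = NA)
      if (!est$qc_pass)
        stop_qc_failure("clip failed quality control (prominence ",
                        signif(est$peak_prominence, 3), ", ibi_cv ",
                        signif(est$ibi_cv, 3), ")")
      list(rate_bpm = est$rate_bpm)
    },
    lungct = {
      vol <- read_volume(config$volume, units = config$units %||% "density")
      lm <- lung_metrics(vol, lo = config$lo %||% 0, hi = config$hi %||% 0.7)
      jsonlite::write_json(
        list(healthy_volume_cm3 = lm$healthy_volume_cm3,
             roi_densities = as.list(lm$roi_densities),
             mean_density = lm$mean_density),
        note(file.path(out_dir, "lung_metrics.json")),
        auto_unbox = TRUE, digits = NA)
      lm[c("healthy_volume_cm3", "mean_density")]
    },
    `simulate-cohort` = {
      cf <- cohort_config(
        doses = config$doses %||% c(0, 9, 10, 10.5, 11, 12, 13),
        n_per_dose = config$n_per_dose %||% 20L,
        ed50_gy = config$ed50 %||% 11,
        hill_slope = config$hill_slope %||% 12,
        field_multiplier = config$field_multiplier %||% 0.97,
        seed = config$seed %||% 1L)
      sim <- simulate_cohort(cf)
      note(write_cohort(sim$cohort, file.path(out_dir, "cohort.csv")))
      jsonlite::write_json(sim$truth$animals,
                           note(file.path(out_dir, "cohort_truth.json")),
                           digits = NA)
      list(n_animals = nrow(sim$truth$animals))
    },
    cohort = {
      cohort <- read_cohort(config$`in`)
      an <- analyze_cohort(cohort,
                           control_dose = config$control_dose %||% 0,
                           timepoint = config$timepoint %||% 5,
                           fallback = config$fallback %||% 4,
                           k = config$k %||% 3,
                           null_model = config$null_model %||% "shared-all")
      write.csv(an$table1, note(file.path(out_dir, "table1_survival_groups.csv")),
                row.names = FALSE)
      write.csv(an$cox_univariate,
                note(file.path(out_dir, "table2_cox_univariate.csv")),
                row.names = FALSE)
      ctrl <- do.call(rbind, lapply(names(an$control), function(m)
        data.frame(metric = m, mean = an$control[[m]]$mean,
                   sd = an$control[[m]]$sd, n = an$control[[m]]$n,
                   cutoff = an$cutoffs[[m]]$value,
                   direction = an$cutoffs[[m]]$direction)))
      write.csv(ctrl, note(file.path(out_dir, "table3_control_cutoffs.csv")),
                row.names = FALSE)
      ed <- do.call(rbind, lapply(names(an$dose_response), function(m) {
        cmp <- an$dose_response[[m]]$comparison
        if (!inherits(cmp, "ed50_comparison")) return(NULL)
        data.frame(metric = m, ed50_0t = cmp$ed50_a, ed50_15t = cmp$ed50_b,
                   f_stat = cmp$f_stat, p_value = cmp$p_value)
      }))
      if (!is.null(ed))
        write.csv(ed, note(file.path(out_dir, "ed50_comparisons.csv")),
                  row.names = FALSE)
      write.csv(an$spearman, note(file.path(out_dir, "spearman.csv")),
                row.names = FALSE)
      list(excluded = length(an$excluded))
    })

  manifest <- list(
    config = config,
    config_md5 = config_md5(config),
    package_version = as.character(utils::packageVersion("vivorate")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  ok <- TRUE
  invisible(list(written = written, result = result))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  config$out <- NULL  # the output location is not part of the parameters
  config <- config[order(names(config))]
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
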