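DAYS_PER_MONTH <- 30.4375

#' Configure a synthetic irradiation cohort
#'
#' Defaults mirror the design of a whole-thorax irradiation study in mice:
#' doses 0-13 Gy with 20 animals per dose group split evenly between a 0 T
#' and a 1.5 T arm, a steep Hill dose-response (ED50 11 Gy, slope 12), a
#' multiplicative magnetic-field effect on ED50, administrative censoring
#' at 8 months, and lung-injury metrics drifting away from control values
#' as pneumonitis develops.
#'
#' @param doses Dose levels in Gy.
#' @param n_per_dose Animals per dose group (split between the two arms).
#' @param ed50_gy,hill_slope Hill parameters of the latent dose response
#'   in the 0 T arm.
#' @param field_multiplier ED50 multiplier applied in the 1.5 T arm
#'   (`< 1` means the field sensitizes).
#' @param censor_months Administrative censoring time.
#' @param death_meanlog,death_sdlog,death_range_months Lognormal death-time
#'   model (months) for responders, clamped to the stated range.
#' @param metrics Per-metric list: control `mean`, `sd` (noise), full
#'   `shift` reached by responders after `ramp_months`.
#' @param ramp_months Months over which a responder's metric shift ramps
#'   from 0 to its full value.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(doses = c(0, 9, 10, 10.5, 11, 12, 13),
                          n_per_dose = 20L, ed50_gy = 11, hill_slope = 12,
                          field_multiplier = 0.97, censor_months = 8,
                          death_meanlog = log(5), death_sdlog = 0.2,
                          death_range_months = c(3, 7),
                          metrics = list(
                            rr_bpm = list(mean = 142, sd = 16, shift = 80),
                            density_gcc = list(mean = 0.474, sd = 0.055,
                                               shift = 0.25),
                            volume_cm3 = list(mean = 0.580, sd = 0.053,
                                              shift = -0.22)),
                          ramp_months = 4, seed = 1L) {
  if (n_per_dose < 2 || n_per_dose %% 2 != 0)
    stop_bad_input("n_per_dose must be an even number >= 2")
  assert_scalar_pos(ed50_gy, "ed50_gy")
  assert_scalar_pos(hill_slope, "hill_slope")
  assert_scalar_pos(field_multiplier, "field_multiplier")
  structure(list(doses = doses, n_per_dose = as.integer(n_per_dose),
                 ed50_gy = ed50_gy, hill_slope = hill_slope,
                 field_multiplier = field_multiplier,
                 censor_months = censor_months,
                 death_meanlog = death_meanlog, death_sdlog = death_sdlog,
                 death_range_months = death_range_months, metrics = metrics,
                 ramp_months = ramp_months, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an irradiation cohort with known ground truth
#'
#' Each animal's latent response probability comes from the Hill curve at
#' its dose, with the 1.5 T arm's ED50 scaled by the field multiplier.
#' Responders die of lung injury at a lognormally distributed time (months,
#' clamped to the configured range); non-responders are censored at the
#' study end. Monthly metric trajectories are control mean plus a
#' severity-ramped shift plus Gaussian noise, recorded while the animal is
#' alive.
#'
#' @param config A [cohort_config()].
#' @return A list: `cohort` (long data frame, one row per
#'   animal-timepoint: `id`, `dose_gy`, `field_t`, `survival_days`,
#'   `event`, `excluded`, `timepoint_m`, `rr_bpm`, `density_gcc`,
#'   `volume_cm3`) and `truth` (per-animal `responder` flag, response
#'   probability, and the arm ED50s).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cf <- config
  set.seed(cf$seed)
  rows <- list()
  truth <- list()
  aid <- 0L
  for (dose in cf$doses) {
    for (arm in c(0, 1.5)) {
      ed50 <- cf$ed50_gy * if (arm > 0) cf$field_multiplier else 1
      p <- hill_predict(dose, ed50, cf$hill_slope) / 100
      for (j in seq_len(cf$n_per_dose %/% 2L)) {
        aid <- aid + 1L
        id <- sprintf("m%03d", aid)
        z <- rbinom(1, 1, p) == 1
        if (z) {
          dm <- min(max(rlnorm(1, cf$death_meanlog, cf$death_sdlog),
                        cf$death_range_months[1]), cf$death_range_months[2])
          surv_days <- dm * DAYS_PER_MONTH
          event <- TRUE
        } else {
          dm <- cf$censor_months
          surv_days <- cf$censor_months * DAYS_PER_MONTH
          event <- FALSE
        }
        tps <- 0:floor(min(dm, cf$censor_months))
        ramp <- pmin(tps / cf$ramp_months, 1)
        vals <- lapply(cf$metrics, function(m)
          m$mean + (if (z) m$shift * ramp else 0) +
            rnorm(length(tps), sd = m$sd))
        rows[[aid]] <- data.frame(
          id = id, dose_gy = dose, field_t = arm,
          survival_days = surv_days, event = event, excluded = FALSE,
          timepoint_m = tps,
          rr_bpm = vals$rr_bpm, density_gcc = vals$density_gcc,
          volume_cm3 = vals$volume_cm3, stringsAsFactors = FALSE)
        truth[[aid]] <- data.frame(id = id, dose_gy = dose, field_t = arm,
                                   p_response = p, responder = z,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  list(cohort = do.call(rbind, rows),
       truth = list(animals = do.call(rbind, truth),
                    ed50_0t = cf$ed50_gy,
                    ed50_15t = cf$ed50_gy * cf$field_multiplier,
                    hill_slope = cf$hill_slope))
}

#' Read / write a cohort table
#'
#' Long CSV format: one row per animal-timepoint with columns `id`,
#' `dose_gy`, `field_t`, `survival_days`, `event`, `excluded`,
#' `timepoint_m`, `rr_bpm`, `density_gcc`, `volume_cm3`.
#'
#' @param cohort A cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_bad_input("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "dose_gy", "field_t", "survival_days", "event",
            "timepoint_m", "rr_bpm", "density_gcc", "volume_cm3")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_bad_input("cohort CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  df$event <- as.logical(df$event)
  df$excluded <- as.logical(df$excluded)
  df
}

#' Analyze an irradiation cohort
#'
#' Reproduces the full statistical workflow for a whole-thorax
#' irradiation study: control statistics and mean +/- k*SD cutoffs;
#' per-animal dichotomization at the measurement timepoint (with
#' fallback); survived-vs-died metric comparisons (Welch's t); univariate
#' and multivariate Cox models; per-dose log-rank comparisons of the two
#' field arms with Bonferroni adjustment; Hill dose-response fits per arm
#' with an extra sum-of-squares F-test on ED50 for each metric; and
#' Spearman correlations among the metrics.
#'
#' @param cohort Long cohort data frame (see [read_cohort()]).
#' @param control_dose Dose identifying the control group (default 0 Gy).
#' @param timepoint,fallback Measurement timepoints in months.
#' @param k Number of SDs for the dichotomization cutoffs.
#' @param null_model Null model for [compare_ed50()].
#' @return A `cohort_analysis` list: `control`, `cutoffs`, `dichotomized`,
#'   `table1`, `cox_univariate`, `cox_multivariate`, `dose_response`,
#'   `survival`, `spearman`, `excluded`.
#' @export
analyze_cohort <- function(cohort, control_dose = 0, timepoint = 5,
                           fallback = 4, k = 3,
                           null_model = c("shared-all", "shared-ed50")) {
  null_model <- match.arg(null_model)
  reg <- metric_registry()
  if (!"excluded" %in% names(cohort)) cohort$excluded <- FALSE
  excluded <- unique(cohort$id[cohort$excluded])
  cohort <- cohort[!cohort$excluded, , drop = FALSE]

  # control statistics at the measurement timepoint (both arms pooled)
  ctrl <- cohort[cohort$dose_gy == control_dose &
                   cohort$timepoint_m == timepoint, , drop = FALSE]
  if (nrow(ctrl) < 2) stop_bad_input("need >= 2 control animals at the timepoint")
  control <- lapply(seq_len(nrow(reg)), function(i) {
    v <- ctrl[[reg$metric[i]]]
    control_stats(reg$metric[i], mean(v, na.rm = TRUE), sd(v, na.rm = TRUE),
                  sum(!is.na(v)), timepoint)
  })
  names(control) <- reg$metric
  cutoffs <- lapply(seq_len(nrow(reg)), function(i) {
    rule <- cutoff_rule(reg$metric[i], reg$direction[i], k)
    list(value = compute_cutoff(control[[i]], rule),
         direction = reg$direction[i])
  })
  names(cutoffs) <- reg$metric

  dich <- dichotomize(cohort, cutoffs, timepoint, fallback)
  newly_excluded <- unique(dich$id[is.na(dich$abnormal)])
  dich_ok <- dich[!dich$id %in% newly_excluded, , drop = FALSE]

  animals <- unique(cohort[, c("id", "dose_gy", "field_t", "survival_days",
                               "event")])
  animals <- animals[!animals$id %in% newly_excluded, , drop = FALSE]

  # survived vs died comparison of the dichotomization values (Welch)
  table1 <- do.call(rbind, lapply(reg$metric, function(m) {
    dd <- merge(dich_ok[dich_ok$metric == m, ], animals, by = "id")
    a <- dd$value[!dd$event]  # survived
    b <- dd$value[dd$event]   # died
    wt <- welch_t(a, b)
    data.frame(metric = m, mean_survived = mean(a),
               sem_survived = sd(a) / sqrt(length(a)), n_survived = length(a),
               mean_died = mean(b), sem_died = sd(b) / sqrt(length(b)),
               n_died = length(b), welch_t = wt$t, welch_p = wt$p_value,
               stringsAsFactors = FALSE)
  }))

  irr <- animals[animals$dose_gy != control_dose, , drop = FALSE]
  cox_uni <- do.call(rbind, lapply(reg$metric, function(m) {
    dd <- merge(dich_ok[dich_ok$metric == m, ], irr, by = "id")
    out <- cox_univariate(dd$survival_days, dd$event, dd$value, m)
    out
  }))
  mv <- merge(unique(dich_ok[, "id", drop = FALSE]), irr, by = "id")
  cox_multi <- cox_model(mv$survival_days, mv$event,
                         data.frame(dose_gy = mv$dose_gy,
                                    field_t = mv$field_t))

  # dose-response per metric and arm
  dresp <- list()
  for (m in reg$metric) {
    dd <- merge(dich_ok[dich_ok$metric == m, ], animals, by = "id")
    tab <- stats::aggregate(abnormal ~ dose_gy + field_t, dd,
                            function(x) 100 * mean(x))
    a <- tab[tab$field_t == 0, ]
    b <- tab[tab$field_t > 0, ]
    cmp <- tryCatch(
      compare_ed50(a$dose_gy, a$abnormal, b$dose_gy, b$abnormal,
                   null_model = null_model),
      error = function(e) e)
    dresp[[m]] <- list(percent_abnormal = tab, comparison = cmp)
  }

  # per-dose log-rank between arms, Bonferroni over the tested doses
  surv <- list()
  doses <- sort(unique(irr$dose_gy))
  tested <- Filter(function(d) {
    sub <- irr[irr$dose_gy == d, ]
    sum(sub$event) > 0
  }, doses)
  for (d in tested) {
    sub <- irr[irr$dose_gy == d, ]
    a <- sub[sub$field_t == 0, ]; b <- sub[sub$field_t > 0, ]
    lr <- km_logrank(a$survival_days, a$event, b$survival_days, b$event)
    surv[[as.character(d)]] <- list(dose_gy = d, chisq = lr$chisq,
                                    p_value = lr$p_value)
  }
  n_tests <- length(surv)
  for (d in names(surv))
    surv[[d]]$p_adjusted <- min(1, surv[[d]]$p_value * n_tests)

  # Spearman among the three metrics (values at the measurement timepoint)
  wide <- stats::reshape(dich_ok[, c("id", "metric", "value")],
                         idvar = "id", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  pairs <- utils::combn(reg$metric, 2, simplify = FALSE)
  spear <- do.call(rbind, lapply(pairs, function(p) {
    sc <- spearman_cor(wide[[p[1]]], wide[[p[2]]])
    data.frame(metric_a = p[1], metric_b = p[2], rho = sc$rho,
               p_value = sc$p_value, n = sc$n, stringsAsFactors = FALSE)
  }))

  structure(list(control = control, cutoffs = cutoffs, dichotomized = dich,
                 table1 = table1, cox_univariate = cox_uni,
                 cox_multivariate = cox_multi, dose_response = dresp,
                 survival = surv, spearman = spear,
                 excluded = union(excluded, newly_excluded)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat(sprintf("  excluded animals: %d\n", length(x$excluded)))
  for (m in names(x$cutoffs))
    cat(sprintf("  cutoff %-12s %s %.4g\n", m,
                if (x$cutoffs[[m]]$direction == "upper") ">" else "<",
                x$cutoffs[[m]]$value))
  for (m in names(x$dose_response)) {
    cmp <- x$dose_response[[m]]$comparison
    if (inherits(cmp, "ed50_comparison"))
      cat(sprintf("  ED50 %-12s 0T %.3f vs 1.5T %.3f Gy (p = %.4g)\n",
                  m, cmp$ed50_a, cmp$ed50_b, cmp$p_value))
  }
  invisible(x)
}
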