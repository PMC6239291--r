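#' Control-group statistics and dichotomization cutoffs
#'
#' `control_stats()` records the control-group mean and SD of one lung
#' injury metric at one timepoint; `cutoff_rule()` states the direction in
#' which values become abnormal and the number of SDs; `compute_cutoff()`
#' returns `mean + k*sd` (upper rule) or `mean - k*sd` (lower rule).
#' Values exactly at the cutoff count as normal ("no more than k SDs").
#'
#' @param metric Metric name.
#' @param mean,sd Control mean and standard deviation (`sd >= 0`).
#' @param n Number of control animals (`>= 2`).
#' @param timepoint_months Measurement timepoint.
#' @return A `control_stats` list.
#' @export
control_stats <- function(metric, mean, sd, n, timepoint_months = 5) {
  if (sd < 0) stop_bad_input("sd must be non-negative")
  if (n < 2) stop_bad_input("control stats need n >= 2")
  structure(list(metric = metric, mean = mean, sd = sd, n = n,
                 timepoint_months = timepoint_months),
            class = "control_stats")
}

#' @rdname control_stats
#' @param direction `"upper"` (abnormal above the cutoff) or `"lower"`.
#' @param k Number of standard deviations (default 3).
#' @export
cutoff_rule <- function(metric, direction = c("upper", "lower"), k = 3) {
  direction <- match.arg(direction)
  assert_scalar_pos(k, "k")
  structure(list(metric = metric, direction = direction, k = k),
            class = "cutoff_rule")
}

#' @rdname control_stats
#' @param stats A `control_stats`.
#' @param rule A `cutoff_rule`.
#' @export
compute_cutoff <- function(stats, rule) {
  if (rule$direction == "upper") stats$mean + rule$k * stats$sd
  else stats$mean - rule$k * stats$sd
}

# metric -> (CSV column, adverse direction)
metric_registry <- function() {
  data.frame(metric = c("rr_bpm", "density_gcc", "volume_cm3"),
             direction = c("upper", "upper", "lower"),
             stringsAsFactors = FALSE)
}

#' Dichotomize animals into normal/abnormal groups
#'
#' For each animal and metric, the value measured at `timepoint` months
#' post-irradiation is compared against the cutoff; animals lacking the
#' primary timepoint fall back to `fallback` months, and animals lacking
#' both are excluded with a reason. A value is abnormal only when it lies
#' strictly beyond the cutoff in the metric's adverse direction.
#'
#' @param cohort A cohort data frame (long format, one row per
#'   animal-timepoint) with columns `id`, `timepoint_m` and the metric
#'   columns named in `cutoffs`.
#' @param cutoffs Named list: for each metric column, a list with `value`
#'   and `direction` (`"upper"`/`"lower"`), e.g. from [compute_cutoff()].
#' @param timepoint,fallback Primary and fallback timepoints in months.
#' @return A data frame with one row per animal and metric: `id`,
#'   `metric`, `value`, `timepoint_used`, `abnormal` (NA when excluded)
#'   and `exclusion_reason`.
#' @export
dichotomize <- function(cohort, cutoffs, timepoint = 5, fallback = 4) {
  ids <- unique(cohort$id)
  rows <- list()
  for (id in ids) {
    sub <- cohort[cohort$id == id, , drop = FALSE]
    for (metric in names(cutoffs)) {
      cut <- cutoffs[[metric]]
      v5 <- sub[[metric]][sub$timepoint_m == timepoint]
      v4 <- sub[[metric]][sub$timepoint_m == fallback]
      v5 <- v5[!is.na(v5)]; v4 <- v4[!is.na(v4)]
      if (length(v5)) {
        val <- v5[1]; tp <- timepoint; reason <- NA_character_
      } else if (length(v4)) {
        val <- v4[1]; tp <- fallback; reason <- NA_character_
      } else {
        val <- NA_real_; tp <- NA_real_
        reason <- sprintf("no measurement at %g or %g months",
                          timepoint, fallback)
      }
      abn <- if (is.na(val)) NA else
        if (cut$direction == "upper") val > cut$value else val < cut$value
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, metric = metric, value = val,
                   timepoint_used = tp, abnormal = abn,
                   exclusion_reason = reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- Hill dose-response machinery -----------------------------------------

hill_predict <- function(dose, ed50, h) {
  ifelse(dose <= 0, 0, 100 / (1 + (ed50 / dose)^h))
}

hill_rss <- function(par, dose, resp) {
  sum((resp - hill_predict(dose, exp(par[1]), exp(par[2])))^2)
}

#' Fit the Hill equation to a dose-response curve
#'
#' Least-squares fit of `P(D) = 100 / (1 + (ED50/D)^h)` with the bottom
#' fixed at 0% and the top at 100%, as appropriate for the percentage of
#' animals responding. Optimization is multi-start (grid of ED50 and slope
#' starting values, plus any user-supplied start) with a quasi-Newton
#' polish, on log-transformed parameters.
#'
#' @param dose Doses in Gy (at least 3 distinct positive values).
#' @param response_pct Percent responding per dose, in `[0, 100]`.
#' @param start Optional `c(ed50, h)` start added to the start grid.
#' @return A `hill_fit`: `ed50_gy`, `slope_h`, `rss`, `df`
#'   (`n - 2`), `fitted` (function of dose) and the data.
#' @export
fit_hill <- function(dose, response_pct, start = NULL) {
  if (length(dose) != length(response_pct))
    stop_bad_input("dose and response vectors must be paired")
  if (length(unique(dose[dose > 0])) < 3)
    stop_bad_input("need at least 3 distinct positive doses")
  if (any(response_pct < 0 | response_pct > 100))
    stop_bad_input("responses must be percentages in [0, 100]")
  pos <- dose > 0
  if (all(response_pct[pos] <= 0) || all(response_pct[pos] >= 100))
    stop_bad_input("all-0% or all-100% responses: ED50 is not identifiable")

  ed50_starts <- unique(c(
    quantile(dose[pos], c(0.25, 0.5, 0.75), names = FALSE),
    approx_ed50(dose[pos], response_pct[pos])))
  h_starts <- c(2, 6, 12, 30)
  starts <- expand.grid(e = ed50_starts, h = h_starts)
  if (!is.null(start)) starts <- rbind(starts, data.frame(e = start[1], h = start[2]))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(c(starts$e[i], starts$h[i]))
    fit <- tryCatch(
      optim(p0, hill_rss, dose = dose, resp = response_pct,
            method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  # quasi-Newton polish from the best start
  pol <- tryCatch(
    optim(best$par, hill_rss, dose = dose, resp = response_pct,
          method = "BFGS", control = list(reltol = 1e-14, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol

  ed50 <- exp(best$par[1]); h <- exp(best$par[2])
  structure(list(ed50_gy = ed50, slope_h = h, rss = best$value,
                 df = length(dose) - 2L,
                 fitted = function(d) hill_predict(d, ed50, h),
                 dose = dose, response_pct = response_pct),
            class = "hill_fit")
}

# crude ED50 guess: dose where the response crosses 50%
approx_ed50 <- function(dose, resp) {
  o <- order(dose)
  d <- dose[o]; r <- resp[o]
  above <- which(r >= 50)
  if (!length(above)) return(max(d))
  i <- above[1]
  if (i == 1) return(d[1])
  d[i - 1] + (50 - r[i - 1]) / (r[i] - r[i - 1] + 1e-12) * (d[i] - d[i - 1])
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> ED50 = %.4f Gy, slope = %.3f, RSS = %.4g (df %d)\n",
              x$ed50_gy, x$slope_h, x$rss, x$df))
  invisible(x)
}

#' Compare ED50 between two dose-response curves
#'
#' Extra sum-of-squares F-test between a null model in which the two
#' groups share Hill parameters and an alternative with separate ED50 and
#' slope per group. With `null_model = "shared-all"` (default) the null
#' shares both ED50 and slope; with `"shared-ed50"` it shares only the
#' ED50 and lets each group keep its own slope.
#'
#' @param dose_a,response_a,dose_b,response_b Dose and percent-response
#'   vectors for the two groups.
#' @param null_model `"shared-all"` or `"shared-ed50"`.
#' @return An `ed50_comparison`: `f_stat`, `df_num`, `df_den`, `p_value`,
#'   `ed50_a`, `ed50_b`, and the two group fits.
#' @export
compare_ed50 <- function(dose_a, response_a, dose_b, response_b,
                         null_model = c("shared-all", "shared-ed50")) {
  null_model <- match.arg(null_model)
  f0 <- fit_hill(c(dose_a, dose_b), c(response_a, response_b))
  # alternative: separate parameters, seeded also from the null optimum so
  # that RSS_alt <= RSS_null holds by construction
  fa <- fit_hill(dose_a, response_a, start = c(f0$ed50_gy, f0$slope_h))
  fb <- fit_hill(dose_b, response_b, start = c(f0$ed50_gy, f0$slope_h))
  n <- length(dose_a) + length(dose_b)
  rss1 <- fa$rss + fb$rss
  df1 <- n - 4L

  if (null_model == "shared-all") {
    rss0 <- f0$rss
    df0 <- n - 2L
  } else {
    obj <- function(par) {
      hill_rss(par[c(1, 2)], dose_a, response_a) +
        hill_rss(par[c(1, 3)], dose_b, response_b)
    }
    p0s <- list(log(c(f0$ed50_gy, f0$slope_h, f0$slope_h)),
                log(c(sqrt(fa$ed50_gy * fb$ed50_gy), fa$slope_h, fb$slope_h)))
    fits <- lapply(p0s, function(p0)
      optim(p0, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 3000)))
    rss0 <- min(vapply(fits, `[[`, 0, "value"))
    df0 <- n - 3L
  }
  if (df1 <= 0) stop_bad_input("not enough dose points for the F-test")
  f <- max(0, ((rss0 - rss1) / (df0 - df1)) / (rss1 / df1))
  p <- pf(f, df0 - df1, df1, lower.tail = FALSE)
  structure(list(f_stat = f, df_num = df0 - df1, df_den = df1, p_value = p,
                 ed50_a = fa$ed50_gy, ed50_b = fb$ed50_gy,
                 fit_a = fa, fit_b = fb, rss_null = rss0, rss_alt = rss1,
                 null_model = null_model),
            class = "ed50_comparison")
}

#' @export
print.ed50_comparison <- function(x, ...) {
  cat(sprintf("<ed50_comparison> ED50 %.3f vs %.3f Gy; F(%d,%d) = %.3f, p = %.4g\n",
              x$ed50_a, x$ed50_b, x$df_num, x$df_den, x$f_stat, x$p_value))
  invisible(x)
}

# --- survival, t-test, correlation wrappers -------------------------------

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' @param time_a,event_a,time_b,event_b Survival times and event flags
#'   (`TRUE` = death, `FALSE` = censored) for the two groups.
#' @return A list: `chisq`, `p_value`, `n_events` and a
#'   `survival::survfit` object `km` for plotting/export. With no events
#'   at all, `p_value = 1` is returned with a warning and `flagged = TRUE`.
#' @export
km_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))))
  km <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0) {
    warning("no events in either group; log-rank p set to 1")
    return(list(chisq = 0, p_value = 1, n_events = 0, km = km,
                flagged = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd$chisq, p_value = pchisq(sd$chisq, 1, lower.tail = FALSE),
       n_events = sum(event), km = km, flagged = FALSE)
}

#' Cox proportional hazards wrappers
#'
#' Thin wrappers over [survival::coxph()] (Efron tie handling) returning
#' coefficients, hazard ratios and 95% confidence intervals in a tidy
#' table.
#'
#' @param time,event Survival times and event indicator.
#' @param predictors A data frame of predictor columns (one column for the
#'   univariate model).
#' @return A data frame with one row per predictor: `term`, `coef`,
#'   `hazard_ratio`, `hr_lo`, `hr_hi`, `p_value`.
#' @export
cox_model <- function(time, event, predictors) {
  predictors <- as.data.frame(predictors)
  if (sum(event) < 1) stop_bad_input("Cox model needs at least one event")
  for (nm in names(predictors))
    if (var(predictors[[nm]]) == 0)
      stop_bad_input("predictor ", nm, " has zero variance")
  df <- cbind(data.frame(.time = time, .event = event), predictors)
  fm <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(predictors)), collapse = " + ")))
  fit <- survival::coxph(fm, data = df, ties = "efron")
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hazard_ratio = s$coefficients[, "exp(coef)"],
             hr_lo = s$conf.int[, "lower .95"],
             hr_hi = s$conf.int[, "upper .95"],
             p_value = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname cox_model
#' @param x Numeric predictor vector.
#' @param name Predictor label.
#' @export
cox_univariate <- function(time, event, x, name = "x") {
  predictors <- data.frame(x)
  names(predictors) <- name
  cox_model(time, event, predictors)
}

#' Welch's unequal-variances t-test
#'
#' @param a,b Numeric samples (each `n >= 2`).
#' @return A list: `t`, `df` (Satterthwaite), `p_value`, group means.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_bad_input("Welch's t-test needs n >= 2 per group")
  if (var(a) == 0 && var(b) == 0)
    stop_bad_input("both groups have zero variance")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Spearman rank correlation
#'
#' Midrank handling of ties; asymptotic p-value.
#'
#' @param x,y Paired numeric vectors (`n >= 3`).
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_bad_input("Spearman correlation needs >= 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop_bad_input("constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
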