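test_that("cutoffs are mean +/- k SD with an inclusive-normal boundary", {
  cs <- control_stats("rr_bpm", 150, 10, 20)
  expect_equal(compute_cutoff(cs, cutoff_rule("rr_bpm", "upper")), 180)
  expect_equal(compute_cutoff(cs, cutoff_rule("rr_bpm", "lower")), 120)
  expect_equal(compute_cutoff(control_stats("x", 7, 0, 5),
                              cutoff_rule("x", "upper")), 7)
  expect_error(control_stats("x", 1, -1, 5), "non-negative")

  cohort <- data.frame(id = c("a", "b", "c"), timepoint_m = 5,
                       rr_bpm = c(190, 191, 189.5))
  cuts <- list(rr_bpm = list(value = 190, direction = "upper"))
  d <- dichotomize(cohort, cuts)
  # exactly at the cutoff is normal; strictly beyond is abnormal
  expect_equal(d$abnormal[d$id == "a"], FALSE)
  expect_equal(d$abnormal[d$id == "b"], TRUE)
  expect_equal(d$abnormal[d$id == "c"], FALSE)
})

test_that("dichotomization falls back to 4 months and excludes with reason", {
  cohort <- data.frame(
    id = c("a", "a", "b", "b", "c"),
    timepoint_m = c(4, 5, 3, 4, 3),
    volume_cm3 = c(0.5, 0.3, 0.5, 0.40, 0.2))
  cuts <- list(volume_cm3 = list(value = 0.421, direction = "lower"))
  d <- dichotomize(cohort, cuts)
  expect_equal(d$timepoint_used[d$id == "a"], 5)  # primary preferred
  expect_true(d$abnormal[d$id == "a"])
  expect_equal(d$timepoint_used[d$id == "b"], 4)  # fallback used
  expect_true(d$abnormal[d$id == "b"])
  expect_true(is.na(d$abnormal[d$id == "c"]))
  expect_match(d$exclusion_reason[d$id == "c"], "no measurement")
})

test_that("dichotomization recovers the generator's responder labels", {
  cf <- cohort_config(seed = 17, metrics = list(
    rr_bpm = list(mean = 142, sd = 0.5, shift = 80),
    density_gcc = list(mean = 0.474, sd = 0.002, shift = 0.25),
    volume_cm3 = list(mean = 0.580, sd = 0.002, shift = -0.22)))
  sim <- simulate_cohort(cf)
  cuts <- list(rr_bpm = list(value = 142 + 3 * 0.5, direction = "upper"),
               density_gcc = list(value = 0.474 + 3 * 0.002, direction = "upper"),
               volume_cm3 = list(value = 0.580 - 3 * 0.002, direction = "lower"))
  d <- dichotomize(sim$cohort, cuts)
  d <- d[!is.na(d$abnormal), ]
  truth <- sim$truth$animals
  lab <- truth$responder[match(d$id, truth$id)]
  expect_equal(mean(d$abnormal == lab), 1)
})

test_that("noiseless Hill data are recovered exactly", {
  doses <- c(9, 10, 10.5, 11, 12, 13)
  resp <- 100 / (1 + (11 / doses)^12)
  fit <- fit_hill(doses, resp)
  expect_lt(abs(fit$ed50_gy - 11), 1e-6)
  expect_lt(abs(fit$slope_h - 12), 1e-5)
  expect_equal(fit$fitted(fit$ed50_gy), 50)
  expect_equal(fit$fitted(0), 0)
  expect_equal(fit$df, 4)

  expect_error(fit_hill(c(5, 10), c(10, 90)), "3 distinct")
  expect_error(fit_hill(doses, rep(0, 6)), "identifiable")
  expect_error(fit_hill(doses, rep(100, 6)), "identifiable")
})

test_that("binomial sampling still centres the fitted ED50 on the truth", {
  doses <- c(9, 10, 10.5, 11, 12, 13)
  p <- 1 / (1 + (11 / doses)^12)
  set.seed(41)
  ed <- replicate(150, {
    r <- 100 * rbinom(6, 10, p) / 10
    tryCatch(fit_hill(doses, r)$ed50_gy, error = function(e) NA)
  })
  expect_lt(abs(median(ed, na.rm = TRUE) / 11 - 1), 0.05)
})

test_that("fitted ED50 concentrates as the per-dose sample grows", {
  doses <- c(9, 10, 10.5, 11, 12, 13)
  p <- 1 / (1 + (11 / doses)^12)
  set.seed(43)
  mae <- sapply(c(10, 50, 200), function(n) {
    mean(abs(replicate(80, {
      r <- 100 * rbinom(6, n, p) / n
      tryCatch(fit_hill(doses, r)$ed50_gy, error = function(e) NA)
    }) - 11), na.rm = TRUE)
  })
  expect_true(all(diff(mae) < 0))
})

test_that("the extra-SS F-test is null on identical groups and properly nested", {
  doses <- c(9, 10, 10.5, 11, 12, 13)
  resp <- 100 / (1 + (11 / doses)^12)
  cmp <- compare_ed50(doses, resp, doses, resp)
  expect_lt(cmp$f_stat, 1e-6)
  expect_gt(cmp$p_value, 0.999)
  expect_equal(cmp$df_num, 2)
  expect_equal(cmp$df_den, 8)

  # nesting: the alternative never fits worse than either null variant
  set.seed(47)
  for (i in 1:15) {
    ra <- pmin(pmax(resp + rnorm(6, sd = 12), 0), 100)
    rb <- pmin(pmax(resp + rnorm(6, sd = 12), 0), 100)
    for (nm in c("shared-all", "shared-ed50")) {
      cc <- tryCatch(compare_ed50(doses, ra, doses, rb, null_model = nm),
                     error = function(e) NULL)
      if (!is.null(cc)) expect_lte(cc$rss_alt, cc$rss_null + 1e-6)
    }
  }
})

test_that("log-rank matches a brute-force risk-table computation", {
  # all events, clean separation
  a <- c(2, 4, 6); b <- c(8, 10, 12)
  lr <- km_logrank(a, rep(TRUE, 3), b, rep(TRUE, 3))
  or <- logrank_oracle(a, rep(TRUE, 3), b, rep(TRUE, 3))
  expect_equal(lr$chisq, or$chisq, tolerance = 1e-9)
  expect_equal(lr$p_value, or$p, tolerance = 1e-9)

  # identical groups carry no signal
  expect_lt(km_logrank(a, rep(TRUE, 3), a, rep(TRUE, 3))$chisq, 1e-12)

  # random small cohorts with censoring
  set.seed(31)
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    ta <- sample(1:20, na); tb <- sample(1:20, nb)
    ea <- runif(na) < 0.7; eb <- runif(nb) < 0.7
    if (!any(c(ea, eb))) next
    lr <- km_logrank(ta, ea, tb, eb)
    or <- logrank_oracle(ta, ea, tb, eb)
    expect_equal(lr$chisq, or$chisq, tolerance = 1e-9)
  }

  expect_warning(res <- km_logrank(c(5, 6), c(FALSE, FALSE),
                                   c(7, 8), c(FALSE, FALSE)), "no events")
  expect_equal(res$p_value, 1)
  expect_true(res$flagged)
})

test_that("Cox wrappers expose hazard ratios and recover a known log-hazard", {
  # coefficient recovery from exponential survival with log-linear hazard
  set.seed(53)
  n <- 300
  x <- rnorm(n)
  beta <- 0.5
  t <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- rexp(n, rate = 0.05)
  time <- pmin(t, cens); event <- t <= cens
  fit <- cox_univariate(time, event, x, "marker")
  expect_equal(fit$term, "marker")
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  se <- (log(fit$hr_hi) - log(fit$hr_lo)) / (2 * 1.96)
  expect_lt(abs(fit$coef - beta), 3 * se)

  expect_error(cox_univariate(time, rep(FALSE, n), x), "at least one event")
  expect_error(cox_univariate(time, event, rep(1, n)), "zero variance")

  mv <- cox_model(time, event, data.frame(marker = x, junk = rnorm(n)))
  expect_equal(nrow(mv), 2)
})

test_that("Welch's t-test behaves at its boundary cases", {
  a <- c(1, 2, 3, 4, 5)
  w <- welch_t(a, a)
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)

  # equal n: the Welch statistic equals the pooled Student statistic
  set.seed(59)
  b <- rnorm(10); c <- rnorm(10)
  expect_equal(welch_t(b, c)$t,
               unname(t.test(b, c, var.equal = TRUE)$statistic))

  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")

  # survived-vs-died contrast at the published group moments is decisive
  set.seed(61)
  surv <- rnorm(61, 153, 3 * sqrt(61))
  died <- rnorm(71, 191, 5 * sqrt(71))
  expect_lt(welch_t(surv, died)$p_value, 0.001)
})

test_that("Spearman correlation equals the rank-based oracle", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(67)
  a <- round(rnorm(20), 1)  # rounding induces ties; midranks must agree
  b <- round(a + rnorm(20), 1)
  expect_equal(spearman_cor(a, b)$rho, cor(rank(a), rank(b)))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("the cohort generator is seed-stable and spares low doses", {
  s1 <- simulate_cohort(cohort_config(seed = 71))
  s2 <- simulate_cohort(cohort_config(seed = 71))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth$animals, s2$truth$animals)

  # below the response threshold every animal reaches censoring
  low <- simulate_cohort(cohort_config(doses = c(0, 9, 10), ed50_gy = 12,
                                       hill_slope = 50, seed = 73))
  an <- unique(low$cohort[, c("id", "survival_days", "event")])
  expect_false(any(an$event))
  expect_true(all(an$survival_days == 8 * 30.4375))

  # structure: 20 animals per dose, half per field arm
  an1 <- unique(s1$cohort[, c("id", "dose_gy", "field_t")])
  expect_equal(nrow(an1), 140)
  expect_true(all(table(an1$dose_gy) == 20))
  expect_true(all(table(an1$dose_gy, an1$field_t) == 10))
})

test_that("ED50 comparison p-values are uniform under a null field effect", {
  # multiplier 1.0: both arms share the dose response; the full
  # simulate -> dichotomize -> fit pipeline should give uniform p
  set.seed(79)
  seeds <- sample.int(1e6, 120)
  pv <- vapply(seeds, function(s) {
    sim <- simulate_cohort(cohort_config(field_multiplier = 1, seed = s))
    co <- sim$cohort
    ctrl <- co[co$dose_gy == 0 & co$timepoint_m == 5, ]
    cut <- list(rr_bpm = list(value = mean(ctrl$rr_bpm) + 3 * sd(ctrl$rr_bpm),
                              direction = "upper"))
    d <- dichotomize(co, cut)
    d <- d[!is.na(d$abnormal), ]
    an <- unique(co[, c("id", "dose_gy", "field_t")])
    d <- merge(d, an, by = "id")
    d <- d[d$dose_gy > 0, ]
    tab <- aggregate(abnormal ~ dose_gy + field_t, d, function(x) 100 * mean(x))
    a <- tab[tab$field_t == 0, ]; b <- tab[tab$field_t > 0, ]
    tryCatch(compare_ed50(a$dose_gy, a$abnormal, b$dose_gy, b$abnormal)$p_value,
             error = function(e) NA_real_)
  }, 0)
  pv <- pv[!is.na(pv)]
  expect_gt(length(pv), 100)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})
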