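test_that("corner detection returns capped, well-separated seeds inside each ROI", {
  clip <- short_clip(duration_s = 2, dim = 128L, seed = 11)
  # rectangle well inside the speckled flank patch
  roi <- cbind(row = c(50, 50, 78, 78), col = c(40, 88, 88, 40))
  seeds <- detect_features(clip$frames, roi)
  expect_equal(nrow(seeds), 10)
  expect_true(all(seeds$row > 50 & seeds$row < 78))
  expect_true(all(seeds$col > 40 & seeds$col < 88))
  # minimum inter-point spacing
  d <- as.matrix(dist(seeds[, c("row", "col")]))
  expect_gte(min(d[upper.tri(d)]), 5)

  # two ROIs: at most 10 each, each seed inside its own polygon
  roi2 <- cbind(row = c(50, 50, 78, 78), col = c(92, 110, 110, 92))
  seeds2 <- detect_features(clip$frames, list(roi, roi2))
  expect_lte(nrow(seeds2), 20)
  expect_true(all(seeds2$col[seeds2$roi_id == 1] < 88))
  expect_true(all(seeds2$col[seeds2$roi_id == 2] > 92))
})

test_that("flat regions yield no corners (warning), all-flat input errors", {
  flat <- frame_sequence(array(128L, c(64, 64, 3)), fps = 30)
  roi <- cbind(row = c(20, 20, 44, 44), col = c(20, 44, 44, 20))
  expect_warning(expect_error(detect_features(flat, roi), "no detectable"),
                 "no detectable")

  clip <- short_clip(duration_s = 2, dim = 128L, seed = 11)
  # pair a flat synthetic ROI with a textured one: warn, keep the textured
  flat_patch <- clip$frames
  flat_patch$frames[5:30, 5:30, ] <- 128L
  roi_flat <- cbind(row = c(8, 8, 27, 27), col = c(8, 27, 27, 8))
  roi_tex <- cbind(row = c(50, 50, 78, 78), col = c(40, 88, 88, 40))
  seeds <- expect_warning(
    detect_features(flat_patch, list(roi_flat, roi_tex)), "ROI 1")
  expect_true(all(seeds$roi_id == 2))
})

test_that("Lucas-Kanade recovers the true displacement on noiseless clips", {
  clip <- short_clip(rate_bpm = 150, duration_s = 8, dim = 128L, seed = 21)
  seeds <- detect_features(clip$frames, "auto")
  tracks <- track_features(clip$frames, seeds)
  # ensemble (median across tracks) per-frame displacement vs ground truth
  nf <- n_frames(clip$frames)
  rec <- sapply(tracks, function(tr) {
    out <- rep(NA_real_, nf)
    out[tr$valid] <- tr$positions[tr$valid, 1] - tr$positions[1, 1]
    out
  })
  med <- apply(rec, 1, median, na.rm = TRUE)
  err <- med - clip$truth$displacement_series[, 1]
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("a static clip tracks to sub-0.05-px jitter", {
  still <- short_clip(amplitude_px = 0, duration_s = 3, dim = 96L, seed = 2)
  roi <- cbind(row = c(30, 30, 66, 66), col = c(25, 70, 70, 25))
  seeds <- detect_features(still$frames, roi)
  tracks <- track_features(still$frames, seeds)
  for (tr in tracks) {
    expect_true(all(tr$valid))
    drift <- sweep(tr$positions, 2, tr$positions[1, ])
    expect_lt(max(abs(drift)), 0.05)
  }
})

test_that("tracks leaving the frame are invalidated and stay invalid", {
  # strong lateral drift marches the patch out of the frame mid-clip
  clip <- short_clip(duration_s = 8, dim = 128L, seed = 31,
                     drift_px_per_s = c(0, 12))
  seeds <- detect_features(clip$frames, "auto")
  tracks <- track_features(clip$frames, seeds)
  lost <- vapply(tracks, function(tr) !all(tr$valid), TRUE)
  expect_true(any(lost))
  for (tr in tracks) {
    v <- tr$valid
    # no re-acquisition: validity is TRUE then FALSE, never TRUE again
    expect_true(all(diff(which(!v)) == 1) || all(v))
    expect_true(all(is.na(tr$positions[!v, ])))
  }
  # if every correspondence is destroyed early, tracking aborts
  broken <- short_clip(duration_s = 8, dim = 128L, seed = 31)
  seeds2 <- detect_features(broken$frames, "auto")
  arr <- broken$frames$frames
  set.seed(99)
  arr[, , 60:240] <- array(sample(0:255, 128 * 128 * 181, TRUE),
                           c(128, 128, 181))
  expect_error(track_features(frame_sequence(arr, 30), seeds2),
               "tracking lost")
})

test_that("waveform combination is robust and sign-aligns opposed tracks", {
  n <- 300; fps <- 30
  tt <- (seq_len(n) - 1) / fps
  s <- sin(2 * pi * 2.5 * tt)
  mk <- function(id, sgn = 1, noise = 0)
    toy_track(id, row = 50 + sgn * s + rnorm(n, sd = noise), col = rep(20, n))

  set.seed(1)
  same <- lapply(1:10, mk)
  wf <- build_waveform(same, fps)
  expect_s3_class(wf, "respiration_signal")
  expect_lt(abs(mean(wf$samples)), 1e-9 * sd(wf$samples))
  # the waveform carries the oscillation (sign is arbitrary); the 1-s
  # moving-average detrend leaves a slight, deterministic distortion
  expect_gt(abs(cor(wf$samples, s[seq_along(wf$samples)])), 0.99)
  expect_equal(sd(wf$samples), 1, tolerance = 0.05)

  # one pure-noise track out of ten does not corrupt the median
  set.seed(2)
  noisy <- c(lapply(1:9, mk),
             list(toy_track(10, row = 50 + rnorm(n), col = rep(20, n))))
  wf2 <- build_waveform(noisy, fps)
  expect_gt(abs(cor(wf2$samples, s[seq_along(wf2$samples)])), 0.99)

  # opposite-phase tracks (flank vs shadow) are flipped into coherence
  set.seed(3)
  mixed <- c(lapply(1:5, mk), lapply(6:10, mk, sgn = -1))
  wf3 <- build_waveform(mixed, fps)
  expect_gt(abs(cor(wf3$samples, s[seq_along(wf3$samples)])), 0.99)

  # insufficient coverage errors
  stub <- toy_track(1, row = 50 + s, col = rep(20, n),
                    valid = c(rep(TRUE, 100), rep(FALSE, n - 100)))
  expect_error(build_waveform(list(stub), fps), "50%")
})

test_that("a pure sinusoid is estimated to within 0.5 bpm and scale-invariantly", {
  fps <- 30
  tt <- (seq_len(20 * fps) - 1) / fps
  sig <- respiration_signal(sin(2 * pi * 2.5 * tt), fps)
  est <- estimate_rate(sig)
  expect_lt(abs(est$rate_bpm - 150), 0.5)
  expect_true(est$qc_pass)

  # amplitude carries no information: any positive rescaling is identical
  est2 <- estimate_rate(respiration_signal(7.3 * sin(2 * pi * 2.5 * tt), fps))
  expect_equal(est2$rate_bpm, est$rate_bpm)

  expect_error(estimate_rate(respiration_signal(sin(tt[1:30]), fps)),
               "2 seconds")
})

test_that("estimation error respects the interpolated-FFT resolution bound", {
  fps <- 30
  errs <- sapply(c(5, 10, 20), function(dur) {
    mean(sapply(c(103.7, 147.3, 201.9, 262.4), function(rate) {
      tt <- (seq_len(dur * fps) - 1) / fps
      sig <- respiration_signal(sin(2 * pi * rate / 60 * tt), fps)
      err <- abs(estimate_rate(sig)$rate_bpm - rate)
      expect_lt(err, 60 / dur)  # one FFT bin
      err
    }))
  })
  # longer clips estimate more accurately on average
  expect_true(all(diff(errs) < 0))
})

test_that("irregular breathing fails quality control", {
  pausey <- short_clip(duration_s = 20, dim = 128L, seed = 13,
                       events = list(list(kind = "pause", start_s = 8,
                                          duration_s = 4)))
  est <- measure_respiration(pausey$frames)
  expect_false(est$qc_pass)

  # white noise has no credible spectral peak or regular intervals
  set.seed(4)
  noise_est <- estimate_rate(respiration_signal(rnorm(600), 30))
  expect_false(noise_est$qc_pass)
})

test_that("per-animal summary takes the median of QC-passing clips", {
  mk_est <- function(rate, qc = TRUE)
    structure(list(rate_bpm = rate, band_bpm = c(60, 400),
                   peak_prominence = 10, ibi_cv = 0.05,
                   n_points_used = 600, qc_pass = qc),
              class = "rate_estimate")
  res <- summarize_mouse(lapply(c(150, 152, 148, 151, 149), mk_est))
  expect_equal(res$summary_bpm, 150)
  expect_equal(res$n_clips, 5)

  ests <- c(lapply(c(150, 152, 148, 151), mk_est), list(mk_est(250, FALSE)))
  expect_warning(res2 <- summarize_mouse(ests), "4 of the desired 5")
  expect_equal(res2$summary_bpm, 150.5)

  expect_error(summarize_mouse(list(mk_est(150, FALSE))),
               class = "vivorate_qc_failure")
})

test_that("reference agreement fraction counts pairs within tolerance", {
  expect_equal(validate_against_reference(c(150, 148, 160), c(152, 148, 170)),
               2 / 3)
  expect_equal(validate_against_reference(c(150, 148), c(150, 148)), 1)
  expect_error(validate_against_reference(numeric(0), numeric(0)), "paired")
})

test_that("rate estimation is invariant to a 90-degree camera rotation", {
  clip <- short_clip(rate_bpm = 170, duration_s = 8, dim = 128L, seed = 17)
  est <- measure_respiration(clip$frames)
  est_rot <- measure_respiration(rotate_frames_90(clip$frames))
  expect_lt(abs(est$rate_bpm - est_rot$rate_bpm), 0.5)
})

test_that("pipeline agrees with the rate of the ground-truth displacement", {
  for (seed in c(23, 29)) {
    clip <- short_clip(rate_bpm = 185, duration_s = 10, dim = 128L,
                       seed = seed, jitter_cv = 0.04)
    est <- measure_respiration(clip$frames)
    oracle <- estimate_rate(respiration_signal(
      clip$truth$displacement_series[, 1], 30))
    expect_lt(abs(est$rate_bpm - oracle$rate_bpm), 1)
  }
})
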