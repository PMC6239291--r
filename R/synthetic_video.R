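#' Describe a synthetic breathing clip
#'
#' A `breathing_scenario` specifies a quasi-periodic flank motion to be
#' rendered by [render_breathing_clip()]: a speckle-textured elliptical
#' "flank" patch translating over a static speckle background along a fixed
#' axis, following a per-breath raised-cosine waveform (inhale occupying
#' 40% of each cycle, exhale 60%) whose inter-breath intervals are jittered
#' with the given coefficient of variation. Optional irregularity events
#' emulate the behaviours a human screener would exclude: a `gasp` (one
#' cycle at 3x amplitude), a `pause` (flat segment of the given duration)
#' and a `sniff` (burst at 3x rate).
#'
#' @param rate_bpm Breathing rate in breaths per minute.
#' @param amplitude_px Peak flank displacement in pixels.
#' @param fps Frame rate (frames per second).
#' @param duration_s Clip duration in seconds.
#' @param jitter_cv Coefficient of variation of inter-breath intervals
#'   (must be `< 1`).
#' @param drift_px_per_s Length-2 numeric, global linear drift of the patch
#'   in pixels per second (row, col).
#' @param noise_sd Additive Gaussian intensity noise, as a fraction of the
#'   dynamic range.
#' @param events List of events, each `list(kind, start_s, duration_s)` with
#'   `kind` one of `"gasp"`, `"pause"`, `"sniff"`.
#' @param seed Integer seed; identical seeds give bit-identical frames.
#' @param frame_dim Frame size in pixels `(rows, cols)`.
#' @param axis_deg Orientation of the motion axis in degrees (0 = along
#'   image rows).
#' @return A `breathing_scenario` list.
#' @examples
#' sc <- breathing_scenario(rate_bpm = 150, duration_s = 6, seed = 1)
#' clip <- render_breathing_clip(sc)
#' clip$truth$true_rate_bpm
#' @export
breathing_scenario <- function(rate_bpm = 150, amplitude_px = 2, fps = 30,
                               duration_s = 20, jitter_cv = 0,
                               drift_px_per_s = c(0, 0), noise_sd = 0,
                               events = list(), seed = 1L,
                               frame_dim = c(256L, 256L), axis_deg = 0) {
  assert_scalar_pos(rate_bpm, "rate_bpm")
  assert_scalar_pos(fps, "fps")
  assert_scalar_pos(duration_s, "duration_s")
  if (amplitude_px < 0) stop_bad_input("amplitude_px must be non-negative")
  if (jitter_cv < 0 || jitter_cv >= 1)
    stop_bad_input("jitter_cv must be in [0, 1)")
  if (noise_sd < 0) stop_bad_input("noise_sd must be non-negative")
  if (rate_bpm / 60 >= fps / 2)
    stop_bad_input("rate_bpm/60 must be below the Nyquist frequency fps/2")
  if (duration_s * rate_bpm / 60 < 2)
    stop_bad_input("clip must contain at least 2 full breath periods")
  for (ev in events) {
    if (!ev$kind %in% c("gasp", "pause", "sniff"))
      stop_bad_input("unknown event kind: ", ev$kind)
  }
  structure(list(rate_bpm = rate_bpm, amplitude_px = amplitude_px, fps = fps,
                 duration_s = duration_s, jitter_cv = jitter_cv,
                 drift_px_per_s = drift_px_per_s, noise_sd = noise_sd,
                 events = events, seed = as.integer(seed),
                 frame_dim = as.integer(frame_dim), axis_deg = axis_deg),
            class = "breathing_scenario")
}

# Build the breath-by-breath timeline: a table of segments (breath cycles
# and pauses) covering [0, duration]. Pauses snap to the first cycle
# boundary at or after their start; sniff cycles run at 3x rate; the cycle
# containing a gasp start runs at 3x amplitude.
build_breath_timeline <- function(sc) {
  mean_t <- 60 / sc$rate_bpm
  pauses <- Filter(function(e) e$kind == "pause", sc$events)
  gasps <- Filter(function(e) e$kind == "gasp", sc$events)
  sniffs <- Filter(function(e) e$kind == "sniff", sc$events)
  pauses <- pauses[order(vapply(pauses, `[[`, 0, "start_s"))]
  used_pause <- logical(length(pauses))

  start <- numeric(0); dur <- numeric(0); amp <- numeric(0); kind <- character(0)
  t <- 0
  while (t < sc$duration_s - 1e-9) {
    pi <- which(!used_pause &
                  vapply(pauses, `[[`, 0, "start_s") <= t + 1e-9)
    if (length(pi)) {
      pi <- pi[1]
      start <- c(start, t); dur <- c(dur, pauses[[pi]]$duration_s)
      amp <- c(amp, 0); kind <- c(kind, "pause")
      t <- t + pauses[[pi]]$duration_s
      used_pause[pi] <- TRUE
      next
    }
    base_t <- mean_t
    in_sniff <- any(vapply(sniffs, function(e)
      t >= e$start_s && t < e$start_s + e$duration_s, TRUE))
    if (in_sniff) base_t <- mean_t / 3
    ti <- base_t * max(0.2, 1 + sc$jitter_cv * rnorm(1))
    a <- 1
    if (any(vapply(gasps, function(e)
      e$start_s >= t && e$start_s < t + ti, TRUE))) a <- 3
    start <- c(start, t); dur <- c(dur, ti); amp <- c(amp, a)
    kind <- c(kind, if (in_sniff) "sniff" else "breath")
    t <- t + ti
  }
  data.frame(start = start, dur = dur, amp = amp, kind = kind,
             stringsAsFactors = FALSE)
}

# Unit breathing waveform s(t) on a vector of times, from a timeline table.
breath_waveform <- function(tl, tt) {
  idx <- findInterval(tt, tl$start)
  idx[idx < 1L] <- 1L
  tau <- (tt - tl$start[idx]) / tl$dur[idx]
  tau <- pmin(pmax(tau, 0), 1)
  g <- ifelse(tau < 0.4, tau / 0.8, 0.5 + (tau - 0.4) / 1.2)
  s <- tl$amp[idx] * (0.5 - 0.5 * cos(2 * pi * g))
  s[tl$kind[idx] == "pause"] <- 0
  s
}

# Speckle texture: smoothed uniform noise rescaled to [0, 1].
speckle <- function(nr, nc, passes = 2L) {
  m <- box_blur3(matrix(runif(nr * nc), nr, nc), passes = passes)
  (m - min(m)) / (max(m) - min(m))
}

#' Render a synthetic breathing clip with ground truth
#'
#' Draws the scenario's flank patch (an ellipse carrying a speckle texture)
#' over a static speckle background and translates it according to the
#' breathing waveform plus any global drift. The returned ground truth
#' records the realized breath onsets, the realized mean rate, and the
#' patch's exact per-frame 2-D offset.
#'
#' @param scenario A [breathing_scenario()].
#' @return A list with `frames` (a [frame_sequence()]) and `truth`, a list
#'   holding `true_rate_bpm`, `breath_onsets_s`, `displacement_series`
#'   (an `n_frames x 2` matrix of (row, col) offsets in pixels) and the
#'   segment `timeline`.
#' @export
render_breathing_clip <- function(scenario) {
  sc <- scenario
  if (!inherits(sc, "breathing_scenario"))
    stop_bad_input("scenario must be a breathing_scenario")
  set.seed(sc$seed)

  tl <- build_breath_timeline(sc)
  nf <- round(sc$duration_s * sc$fps)
  tt <- (seq_len(nf) - 1) / sc$fps
  s <- breath_waveform(tl, tt)

  theta <- sc$axis_deg * pi / 180
  axis <- c(cos(theta), sin(theta))  # (row, col)
  drift <- outer(tt, sc$drift_px_per_s)
  disp <- cbind(sc$amplitude_px * s * axis[1] + drift[, 1],
                sc$amplitude_px * s * axis[2] + drift[, 2])

  h <- sc$frame_dim[1]; w <- sc$frame_dim[2]
  bg <- speckle(h, w)
  # patch texture canvas, large enough for peak displacement
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  ar <- round(0.14 * h); ac <- round(0.23 * w)
  margin <- ceiling(max(abs(disp))) + 4
  tex_h <- 2 * (ar + margin) + 1; tex_w <- 2 * (ac + margin) + 1
  tex <- speckle(tex_h, tex_w)
  tex_cr <- (tex_h + 1) / 2; tex_cc <- (tex_w + 1) / 2

  # compositing window: the patch plus its full displacement range
  r_lo <- max(1L, floor(cr - ar - margin)); r_hi <- min(h, ceiling(cr + ar + margin))
  c_lo <- max(1L, floor(cc - ac - margin)); c_hi <- min(w, ceiling(cc + ac + margin))
  rw <- r_lo:r_hi; cw <- c_lo:c_hi
  rr_w <- matrix(rw, length(rw), length(cw))
  cc_w <- matrix(cw, length(rw), length(cw), byrow = TRUE)
  bg_q <- matrix(as.integer(round(bg * 255)), h, w)

  frames <- array(0L, c(h, w, nf))
  noise_scale <- sc$noise_sd
  for (i in seq_len(nf)) {
    d <- disp[i, ]
    win <- bg[rw, cw]
    # ellipse translated by d
    er <- rr_w - (cr + d[1]); ec <- cc_w - (cc + d[2])
    inside <- (er / ar)^2 + (ec / ac)^2 <= 1
    # texture coordinates (patch-local), bilinear sample
    pr <- er[inside] + tex_cr; pc <- ec[inside] + tex_cc
    r0 <- floor(pr); c0 <- floor(pc)
    fr <- pr - r0; fc <- pc - c0
    li <- r0 + (c0 - 1) * tex_h  # linear index into the texture canvas
    v <- (1 - fr) * ((1 - fc) * tex[li] + fc * tex[li + tex_h]) +
      fr * ((1 - fc) * tex[li + 1] + fc * tex[li + tex_h + 1])
    win[inside] <- v
    if (noise_scale > 0) {
      img <- bg
      img[rw, cw] <- win
      img <- img + rnorm(h * w, sd = noise_scale)
      frames[, , i] <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
    } else {
      f <- bg_q
      f[rw, cw] <- as.integer(round(win * 255))
      frames[, , i] <- f
    }
  }

  onsets <- tl$start[tl$kind == "breath"]
  onsets <- onsets[onsets < sc$duration_s - 1e-9]
  true_rate <- if (length(onsets) >= 2) 60 / mean(diff(onsets)) else sc$rate_bpm
  list(frames = frame_sequence(frames, sc$fps),
       truth = list(true_rate_bpm = true_rate,
                    breath_onsets_s = onsets,
                    displacement_series = disp,
                    timeline = tl))
}
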