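# Shared fixtures: all synthetic, generated in code at test time.

# A small, fast breathing clip for unit tests.
short_clip <- function(rate_bpm = 150, duration_s = 8, fps = 30, dim = 128L,
                       seed = 1L, ...) {
  render_breathing_clip(breathing_scenario(
    rate_bpm = rate_bpm, duration_s = duration_s, fps = fps,
    frame_dim = c(dim, dim), seed = seed, ...))
}

# Hand-built feature track (for waveform tests that need no video).
toy_track <- function(id, row, col, valid = rep(TRUE, length(row))) {
  structure(list(point_id = id,
                 positions = cbind(row = row, col = col),
                 valid = valid),
            class = "feature_track")
}

# Brute-force two-group log-rank statistic from first principles:
# walk the risk table at every distinct event time.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(1:2, c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event]))
  obs1 <- exp1 <- v <- 0
  for (t in ts) {
    n1 <- sum(time >= t & grp == 1)
    n2 <- sum(time >= t & grp == 2)
    n <- n1 + n2
    d1 <- sum(time == t & event & grp == 1)
    d <- sum(time == t & event)
    obs1 <- obs1 + d1
    exp1 <- exp1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (obs1 - exp1)^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Dominant frequency (bpm) of a 1-D series by plain FFT argmax: the
# independent oracle for rate estimation on ground-truth displacement.
fft_peak_bpm <- function(x, fps) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  half <- 2:floor(n / 2)
  (half[which.max(p[half])] - 1) / n * fps * 60
}

# Rotate every frame of a sequence by 90 degrees (counter-clockwise).
rotate_frames_90 <- function(seq) {
  arr <- seq$frames
  h <- dim(arr)[1]
  rot <- aperm(arr, c(2, 1, 3))[dim(arr)[2]:1, , , drop = FALSE]
  frame_sequence(rot, seq$fps)
}
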