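# Internal numeric helpers shared across modules.

# Centered moving average with partial windows at the edges.
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  r <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - r - 1L)
  hi <- pmin(n, seq_len(n) + r)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# 3x3 box blur with replicated borders; `passes` repeats approximate a
# Gaussian of increasing width.
box_blur3 <- function(m, passes = 1L) {
  for (i in seq_len(passes)) {
    n <- nrow(m); p <- ncol(m)
    v <- m[c(1L, seq_len(n - 1L)), , drop = FALSE] + m +
      m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
    m <- (v[, c(1L, seq_len(p - 1L)), drop = FALSE] + v +
            v[, c(seq_len(p - 1L) + 1L, p), drop = FALSE]) / 9
  }
  m
}

stop_bad_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("vivorate_bad_input", "error")))
}

stop_qc_failure <- function(...) {
  stop(errorCondition(paste0(...), class = c("vivorate_qc_failure", "error")))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_bad_input(name, " must be a positive finite scalar")
  invisible(x)
}
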