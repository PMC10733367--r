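#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rlnorm fft cor sd aggregate lm anova pf pt
#'   quantile median coef approx acf
#' @importFrom utils write.csv read.csv head tail
NULL

# Signal a classed error so callers can condition on failure mode.
phon_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "phonmark_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

phon_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-item child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647L)
}

rms <- function(x) sqrt(mean(x^2))

db10 <- function(x, floor_val = 1e-12) 10 * log10(pmax(x, floor_val))

# Slice a signal into overlapping frames; returns a matrix frame_len x n_frames.
frame_signal <- function(x, frame_len, hop_len) {
  n <- length(x)
  if (n < frame_len) {
    return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  }
  starts <- seq(1L, n - frame_len + 1L, by = hop_len)
  vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len))
}

frame_times <- function(n, frame_len, hop_len, sample_rate_hz) {
  n_frames <- if (n < frame_len) 0L else length(seq(1L, n - frame_len + 1L, by = hop_len))
  (seq_len(n_frames) - 1L) * hop_len / sample_rate_hz
}

hann_window <- function(n) {
  # periodic Hann, the STFT convention
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# Trapezoidal integral of y(x) over [a, b], interpolating at the limits.
trapz_band <- function(x, y, a, b) {
  if (a >= b) return(0)
  keep <- x > a & x < b
  xs <- c(a, x[keep], b)
  ys <- c(approx(x, y, xout = a, rule = 2)$y, y[keep],
          approx(x, y, xout = b, rule = 2)$y)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}
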