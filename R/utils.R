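#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft nextn rnorm rlnorm rpois runif sd var cov median
#'   pf ptukey pt quantile aggregate convolve
#' @importFrom utils read.csv write.csv head tail
NULL

abort_validation <- function(msg, class = "ecosyn_validation_error") {
  stop(errorCondition(msg, class = c(class, "ecosyn_error")))
}

abort_format <- function(msg) {
  abort_validation(msg, class = "ecosyn_format_error")
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_validation(sprintf("`%s` must be > 0", name))
  invisible(x)
}

#' Analytic-signal magnitude (Hilbert envelope)
#'
#' Instantaneous amplitude of a real signal, computed from the analytic
#' signal via the FFT. The input is reflection-padded to a highly composite
#' length so edge artefacts are suppressed and the transform stays fast for
#' arbitrary window lengths.
#'
#' @param x numeric vector, the real signal.
#' @return numeric vector of the same length: the envelope (>= 0).
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' env <- hilbert_envelope(3 * sin(2 * pi * 5 * t))
#' median(env) # ~3
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) abort_validation("signal must have at least 2 samples")
  pad <- min(n - 1L, 2048L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  m0 <- length(xp)
  m <- nextn(m0, c(2, 3, 5))
  if (m > m0) xp <- c(xp, rev(xp[m0 - seq_len(m - m0) + 1L]))
  X <- fft(xp)
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[1L] <- 1; h[m / 2L + 1L] <- 1; h[2L:(m / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((m + 1L) / 2L)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / m)
  env[pad + seq_len(n)]
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise, scaled to
# a target standard deviation. Uses the current RNG stream.
pink_noise <- function(n, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  m <- nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  bin <- c(0L, seq_len(m - 1L))
  bin <- pmin(bin, m - bin)           # two-sided symmetric frequency index
  amp <- 1 / sqrt(pmax(bin, 1L))
  amp[1L] <- 0                        # no DC drift
  x <- Re(fft(W * amp, inverse = TRUE) / m)[seq_len(n)]
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * sd_target / s
}

# Zero-phase FIR low-pass by symmetric (linear-phase) filtering with exact
# group-delay compensation; reflection padding avoids edge transients.
fir_lowpass_zerophase <- function(x, fs, cutoff, transition) {
  ntaps <- ceiling(3.3 * fs / transition)          # Hamming-window rule
  ntaps <- min(max(ntaps, 33L), 4001L)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  b <- signal::fir1(ntaps - 1L, 2 * cutoff / fs, type = "low")
  b <- b / sum(b)                                  # exact unit DC gain
  n <- length(x)
  d <- (ntaps - 1L) %/% 2L
  pad <- min(n - 1L, ntaps)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  y <- fft_convolve(xp, b)
  y[pad + d + seq_len(n)]
}

# Linear ("open") convolution via FFT; returns length(x)+length(b)-1 values.
fft_convolve <- function(x, b) {
  n <- length(x) + length(b) - 1L
  m <- nextn(n, c(2, 3, 5))
  Re(fft(fft(c(x, numeric(m - length(x)))) *
           fft(c(b, numeric(m - length(b)))), inverse = TRUE) / m)[seq_len(n)]
}
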