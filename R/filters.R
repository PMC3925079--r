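#' Frequency band
#'
#' @param b_s start frequency in Hz.
#' @param b_e end frequency in Hz; must exceed \code{b_s}.
#' @return An object of class \code{band}.
#' @export
band <- function(b_s, b_e) {
  if (!is.numeric(b_s) || !is.numeric(b_e) || b_s >= b_e)
    stop("need b_s < b_e, got [", b_s, ", ", b_e, "]")
  structure(list(b_s = as.numeric(b_s), b_e = as.numeric(b_e)), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> [%g, %g] Hz\n", x$b_s, x$b_e)); invisible(x)
}

#' Squared magnitude response of the package's band-pass
#'
#' The band-pass is an order-5 Butterworth whose squared magnitude response
#' is applied with zero phase (the frequency-domain equivalent of
#' forward-backward filtering).
#'
#' @param bd a \code{band}.
#' @param fs sampling rate in Hz.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param order filter order (default 5).
#' @return numeric vector |H(f)|^2 at \code{freqs}.
#' @export
bandpass_response2 <- function(bd, fs, freqs, order = 5L) {
  if (bd$b_e >= fs / 2)
    stop("band end ", bd$b_e, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  flt <- signal::butter(order, c(bd$b_s, bd$b_e) / (fs / 2), type = "pass")
  w <- 2 * pi * freqs / fs
  z <- exp(-1i * w)
  num <- outer(z, seq_along(flt$b) - 1L, `^`) %*% flt$b
  den <- outer(z, seq_along(flt$a) - 1L, `^`) %*% flt$a
  as.numeric(Mod(num / den)^2)
}

# Zero-phase band-pass of a [time x series] real matrix: multiply the DFT by
# the (real, symmetric) squared Butterworth magnitude and invert. Circular
# convolution; no phase distortion, no startup transient handling needed.
bandpass_matrix <- function(x, fs, bd, order = 5L) {
  n <- nrow(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n            # fold to [0, fs/2]
  h2 <- bandpass_response2(bd, fs, f, order)
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * h2, inverse = TRUE)) / n
}

#' Band-pass filter a trial set
#'
#' Applies the zero-phase order-5 Butterworth band-pass per trial and channel;
#' shape, labels and order are unchanged.
#'
#' @param trials a \code{trial_set}.
#' @param bd a \code{band}; \code{b_e} must be below Nyquist.
#' @return The filtered \code{trial_set}.
#' @export
bandpass <- function(trials, bd) {
  stopifnot(inherits(trials, "trial_set"), inherits(bd, "band"))
  d <- dim(trials$trials)
  x <- matrix(aperm(trials$trials, c(3, 2, 1)), nrow = d[3])  # time x (ch*trial)
  y <- bandpass_matrix(x, trials$fs, bd)
  out <- aperm(array(y, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  trial_set(out, trials$labels, trials$fs, trials$order, trials$channels)
}
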