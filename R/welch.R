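# Welch power spectral density with Hann windows and 50% overlap.
# x: numeric vector or [time x series] matrix. Returns the one-sided PSD
# (unit^2/Hz) at the native resolution fs/nperseg, optionally interpolated
# onto a requested frequency grid (which must be a subset of the native bins).
welch_psd <- function(x, fs, nperseg, grid = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < nperseg)
    stop("signal (", n, " samples) shorter than Welch segment (", nperseg, ")")
  step <- nperseg %/% 2L
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- matrix(0, nfreq, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L), , drop = FALSE] * w
    X <- stats::mvfft(seg)
    acc <- acc + Mod(X[seq_len(nfreq), , drop = FALSE])^2
  }
  psd <- acc * (scale / length(starts))
  psd[2:(nfreq - 1L), ] <- 2 * psd[2:(nfreq - 1L), ]   # one-sided doubling
  freqs <- (seq_len(nfreq) - 1L) * fs / nperseg
  if (!is.null(grid)) {
    idx <- round(grid / (fs / nperseg)) + 1L
    if (any(idx < 1L | idx > nfreq) ||
        max(abs(freqs[idx] - grid)) > 1e-6)
      stop("requested grid is not a subset of the native Welch bins")
    psd <- psd[idx, , drop = FALSE]
    freqs <- grid
  }
  rownames(psd) <- NULL
  list(freqs = freqs, psd = psd)
}

#' Per-channel Welch power spectral density of a recording
#'
#' Power spectral densities are estimated with 2-second Hann windows at 50%
#' overlap (0.5 Hz native resolution) and evaluated on the analysis grid.
#'
#' @param rec an \code{eeg_recording} (at least 4 s long).
#' @param grid frequency grid in Hz; default 2 to 34 Hz in 0.5 Hz steps.
#' @param seg_s Welch segment length in seconds (default 2).
#' @return matrix of PSD values, frequencies in rows (named by \code{grid}),
#'   channels in columns; microvolt^2 per Hz.
#' @export
psd_estimate <- function(rec, grid = rest_grid(), seg_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 4 * rec$fs)
    stop("recording shorter than 4 s")
  if (rec$fs < 2 * max(grid))
    stop("sampling rate too low for the requested grid")
  res <- welch_psd(t(rec$data), rec$fs, nperseg = round(seg_s * rec$fs),
                   grid = grid)
  out <- res$psd
  dimnames(out) <- list(format(grid), rec$channels)
  out
}

#' Resting-state analysis grid
#'
#' @return frequencies from 2 to 34 Hz in 0.5 Hz steps.
#' @export
rest_grid <- function() seq(2, 34, by = 0.5)
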