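#' Band likelihood matrix from resting-state spectral profiles
#'
#' For each channel and each candidate band [b_s, b_e] on the grid, the
#' likelihood is the band mean of the positive part of the FRI (the rhythm
#' power above the noise floor, averaged over the grid points the band
#' covers); channel likelihoods are summed. The start domain runs to one
#' grid step below the top frequency and the end domain starts one step
#' above the bottom, and cells with start >= end carry zero.
#'
#' When the largest positive FRI is numerically indistinguishable from zero
#' relative to the spectrum scale (below 1e-8 x max PSD), the matrix is
#' returned all-zero with attribute \code{zero = TRUE}: a pure noise-floor
#' subject carries no band information.
#'
#' @param profiles list of \code{spectral_profile}s on a common grid.
#' @return matrix L with \code{attr(, "start_grid")}, \code{attr(, "end_grid")}.
#' @export
band_likelihood <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  grid <- profiles[[1]]$grid
  for (p in profiles)
    if (!isTRUE(all.equal(p$grid, grid))) stop("profiles on different grids")
  ns <- length(grid) - 1L
  start_grid <- grid[seq_len(ns)]
  end_grid <- grid[-1L]
  L <- matrix(0, ns, ns)
  scale <- max(vapply(profiles, function(p) max(p$psd), numeric(1)))
  pos_max <- max(vapply(profiles, function(p) max(p$fri), numeric(1)))
  zero <- pos_max < 1e-8 * max(scale, 1e-300)
  if (!zero) {
    counts <- outer(seq_len(ns), seq_len(ns) + 1L,
                    function(i, j) j - i + 1L)          # grid points in [s, e]
    valid <- outer(start_grid, end_grid, `<`)
    for (p in profiles) {
      cs <- c(0, cumsum(pmax(p$fri, 0)))
      sums <- outer(seq_len(ns), seq_len(ns) + 1L,
                    function(i, j) cs[j + 1L] - cs[i])
      contrib <- sums / counts       # 0/0 on degenerate cells; masked next
      contrib[!valid] <- 0
      L <- L + contrib
    }
  }
  structure(L, start_grid = start_grid, end_grid = end_grid, zero = zero)
}

#' Normalize a band likelihood matrix into a 2-D density
#'
#' Divides by the total mass; a (numerically) all-zero likelihood yields the
#' uniform density over valid cells, flagged with attribute \code{uniform}.
#'
#' @param L likelihood matrix from \code{\link{band_likelihood}}.
#' @return A \code{pdf2d} with attribute \code{uniform}.
#' @export
normalize_pdf2d <- function(L) {
  start_grid <- attr(L, "start_grid")
  end_grid <- attr(L, "end_grid")
  if (is.null(start_grid) || is.null(end_grid))
    stop("L must come from band_likelihood()")
  valid <- outer(start_grid, end_grid, `<`)
  M <- unclass(L); attributes(M) <- list(dim = dim(L))
  uniform <- isTRUE(attr(L, "zero")) || sum(M) <= 0
  if (uniform) M <- valid * 1
  p2 <- pdf2d(start_grid, end_grid, M * valid)
  attr(p2, "uniform") <- uniform
  p2
}

#' Uniform-subtracted 1-D density of a resting-state band density
#'
#' Same membership-sum and uniform-subtraction rule as in the motor-imagery
#' analysis (\code{\link{pdf_1d}}); a uniform 2-D density maps to the
#' all-zero vector.
#'
#' @param p2 a \code{pdf2d}.
#' @return A \code{pdf1d}.
#' @export
pdf1d_rest <- function(p2) pdf_1d(p2)

#' Subject weight
#'
#' The sum over channels of the maximum positive rhythm power. Computed from
#' the FRI by default, so the noise floor does not inflate the weight; set
#' \code{source = "psd"} to use the raw spectrum maxima instead.
#'
#' @param profiles list of \code{spectral_profile}s.
#' @param source \code{"fri"} (default) or \code{"psd"}.
#' @return scalar eta >= 0.
#' @export
subject_weight <- function(profiles, source = c("fri", "psd")) {
  source <- match.arg(source)
  if (!length(profiles)) stop("no profiles")
  sum(vapply(profiles, function(p) {
    max(if (source == "fri") pmax(p$fri, 0) else p$psd)
  }, numeric(1)))
}

#' Subject-and-frequency weighted resting density
#'
#' Xi(f) = eta x mixture weight(f) x pdf1d(f). Deliberately not
#' renormalized: the subject weight restores the absolute power scale that
#' normalization removed, making densities comparable across subjects.
#'
#' @param p1 uniform-subtracted \code{pdf1d}.
#' @param eta subject weight.
#' @param mixture Gaussian frequency-weight mixture.
#' @return A \code{pdf1d} holding Xi.
#' @export
weighted_subject_pdf <- function(p1, eta, mixture = default_mixture()) {
  stopifnot(inherits(p1, "pdf1d"), eta >= 0)
  pdf1d(p1$grid, eta * p1$values * frequency_weight(p1$grid, mixture))
}

#' Full resting-state spectral pipeline for one subject
#'
#' PSD estimation per channel, noise-floor fitting, FRI, band likelihood,
#' 2-D and uniform-subtracted 1-D densities, subject weight, and the final
#' weighted density Xi used for performance prediction.
#'
#' @param rec an \code{eeg_recording} of (Laplacian-derived) resting EEG.
#' @param grid analysis grid (default 2-34 Hz, 0.5 Hz steps).
#' @param mixture frequency-weight mixture (default mu/beta).
#' @param exclude_bands rhythm bands excluded from the noise fit.
#' @param eta_source \code{"fri"} or \code{"psd"} for the subject weight.
#' @return An object of class \code{subject_spectrum} with fields
#'   \code{profiles}, \code{likelihood}, \code{pdf2d}, \code{pdf1d},
#'   \code{eta}, \code{xi}.
#' @export
subject_spectrum <- function(rec, grid = rest_grid(),
                             mixture = default_mixture(),
                             exclude_bands = list(c(7, 14), c(15, 25)),
                             eta_source = "fri") {
  psd <- psd_estimate(rec, grid)
  profiles <- lapply(seq_len(ncol(psd)), function(j)
    spectral_profile(psd[, j], grid, channel = colnames(psd)[j],
                     exclude_bands = exclude_bands))
  L <- band_likelihood(profiles)
  p2 <- normalize_pdf2d(L)
  p1 <- pdf1d_rest(p2)
  eta <- subject_weight(profiles, eta_source)
  structure(list(profiles = profiles, likelihood = L, pdf2d = p2,
                 pdf1d = p1, eta = eta,
                 xi = weighted_subject_pdf(p1, eta, mixture),
                 grid = grid),
            class = "subject_spectrum")
}

#' @export
print.subject_spectrum <- function(x, ...) {
  cat(sprintf(
    "<subject_spectrum> %d channels; eta = %.3g; Xi peak %.3g at %.1f Hz\n",
    length(x$profiles), x$eta, max(x$xi$values),
    x$xi$grid[which.max(x$xi$values)]))
  invisible(x)
}
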