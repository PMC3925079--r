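#' Fit the 1/f noise-floor model to a power spectrum
#'
#' Fits g(f) = k1 + k2 / f^lambda by least squares on grid points outside the
#' excluded rhythm bands, so the floor is fitted to the spectrum's skirts and
#' not to the mu/beta peaks. For a fixed lambda the model is linear in
#' (k1, k2), so lambda is profiled out: (k1, k2) are solved in closed form
#' and lambda is optimized on [0.1, 3] by 1-D minimization. k2 is
#' constrained to be non-negative.
#'
#' @param psd power spectral density values on \code{grid}.
#' @param grid frequencies in Hz.
#' @param exclude_bands list of length-2 vectors; grid points inside any of
#'   them are excluded from the fit. Defaults to the mu (7-14 Hz) and beta
#'   (15-25 Hz) ranges.
#' @return list with \code{k1}, \code{k2}, \code{lambda}, and
#'   \code{lambda_identifiable} (FALSE when k2 is essentially zero, e.g. a
#'   flat spectrum, in which case lambda is arbitrary).
#' @export
fit_noise_model <- function(psd, grid,
                            exclude_bands = list(c(7, 14), c(15, 25))) {
  keep <- rep(TRUE, length(grid))
  for (b in exclude_bands) keep <- keep & !(grid >= b[1] & grid <= b[2])
  if (sum(keep) < 5L)
    stop("fewer than 5 grid points outside the excluded bands")
  f <- grid[keep]; y <- psd[keep]
  solve_lin <- function(lambda) {
    X <- cbind(1, f^(-lambda))
    beta <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), 0))
    if (beta[2] < 0) beta <- c(mean(y), 0)
    list(beta = beta, sse = sum((y - X %*% beta)^2))
  }
  sse <- function(lambda) solve_lin(lambda)$sse
  opt <- tryCatch(stats::optimize(sse, c(0.1, 3), tol = 1e-10),
                  error = function(e) NULL)
  lambda <- if (is.null(opt)) {
    warning("noise-model optimization failed; falling back to lambda = 1")
    1
  } else opt$minimum
  # optimize() cannot return the exact interval ends; check them explicitly
  for (lb in c(0.1, 3)) if (sse(lb) < sse(lambda)) lambda <- lb
  beta <- solve_lin(lambda)$beta
  list(k1 = beta[1], k2 = beta[2], lambda = lambda,
       lambda_identifiable = beta[2] > 1e-8 * max(abs(y), 1e-300))
}

#' Evaluate the fitted noise model
#' @param params list with \code{k1}, \code{k2}, \code{lambda}.
#' @param f frequencies in Hz (> 0).
#' @return g(f) = k1 + k2 / f^lambda.
#' @export
noise_model_value <- function(params, f) {
  params$k1 + params$k2 / f^params$lambda
}

#' Per-channel spectral profile
#'
#' Bundles a channel's PSD on the analysis grid with the fitted noise model
#' and the frequency-related information (FRI), the PSD minus the noise
#' floor. Negative FRI values are preserved: they mark frequencies carrying
#' less power than the floor, i.e. no rhythm information.
#'
#' @param psd PSD values on \code{grid} (microvolt^2/Hz).
#' @param grid frequencies in Hz.
#' @param channel channel label.
#' @param exclude_bands rhythm bands excluded from the noise fit.
#' @return An object of class \code{spectral_profile} with fields
#'   \code{channel}, \code{grid}, \code{psd}, \code{noise_params}, \code{fri}.
#' @export
spectral_profile <- function(psd, grid, channel = "ch",
                             exclude_bands = list(c(7, 14), c(15, 25))) {
  if (length(psd) != length(grid)) stop("psd/grid length mismatch")
  if (any(psd < 0)) stop("psd must be non-negative")
  params <- fit_noise_model(psd, grid, exclude_bands)
  structure(list(channel = channel, grid = grid, psd = as.numeric(psd),
                 noise_params = params,
                 fri = as.numeric(psd) - noise_model_value(params, grid)),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  p <- x$noise_params
  cat(sprintf(
    "<spectral_profile> %s: %d points [%g, %g] Hz; floor k1=%.3g k2=%.3g lambda=%.3g; max FRI %.3g\n",
    x$channel, length(x$grid), min(x$grid), max(x$grid),
    p$k1, p$k2, p$lambda, max(x$fri)))
  invisible(x)
}

#' Frequency-related information of a profile
#'
#' @param profile a \code{spectral_profile}.
#' @return numeric vector psd - noise model, unclipped.
#' @export
fri_compute <- function(profile) {
  stopifnot(inherits(profile, "spectral_profile"))
  profile$psd - noise_model_value(profile$noise_params, profile$grid)
}
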