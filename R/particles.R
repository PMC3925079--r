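#' Particle representation of a frequency-band distribution
#'
#' @param particles numeric matrix with columns \code{b_s}, \code{b_e}
#'   (one band hypothesis per row).
#' @param weights non-negative weights; normalized to sum to 1.
#' @param f_min,f_max analysis range in Hz.
#' @param step frequency grid step in Hz.
#' @param min_bandwidth minimum band width in Hz.
#' @param iteration iteration counter.
#' @return An object of class \code{particle_set}.
#' @export
particle_set <- function(particles, weights = NULL, f_min = 4, f_max = 40,
                         step = 0.5, min_bandwidth = 2, iteration = 0L) {
  particles <- matrix(as.numeric(particles), ncol = 2,
                      dimnames = list(NULL, c("b_s", "b_e")))
  n <- nrow(particles)
  if (any(particles[, 1] >= particles[, 2]))
    stop("every particle needs b_s < b_e")
  if (any(particles < f_min - 1e-9) || any(particles > f_max + 1e-9))
    stop("particles outside [f_min, f_max]")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum, one per particle")
  structure(list(particles = particles, weights = weights / sum(weights),
                 f_min = f_min, f_max = f_max, step = step,
                 min_bandwidth = min_bandwidth, iteration = iteration),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  mu <- particle_mean_band(x)
  cat(sprintf(
    "<particle_set> %d particles on [%g, %g] Hz (step %g), iteration %d; mean band [%.2f, %.2f]\n",
    nrow(x$particles), x$f_min, x$f_max, x$step, x$iteration, mu[1], mu[2]))
  invisible(x)
}

#' Weighted mean band of a particle set
#' @param ps a \code{particle_set}.
#' @return length-2 numeric (mean start, mean end frequency).
#' @export
particle_mean_band <- function(ps) {
  as.numeric(crossprod(ps$weights, ps$particles))
}

# All valid (b_s, b_e) grid pairs with b_e - b_s >= min_bandwidth.
valid_band_grid <- function(f_min, f_max, step = 0.5, min_bandwidth = 0) {
  f <- seq(f_min, f_max, by = step)
  idx <- which(outer(f, f, function(s, e) e - s >= max(min_bandwidth, step / 2)),
               arr.ind = TRUE)
  cbind(b_s = f[idx[, 1]], b_e = f[idx[, 2]])
}

#' Sample band particles from the uniform prior
#'
#' Bands are drawn uniformly over all valid (start, end) pairs on the
#' frequency grid with at least \code{min_bandwidth} between the endpoints;
#' all particles get equal weight.
#'
#' @param n_particles number of particles.
#' @param f_min,f_max analysis range in Hz (defaults 4 and 40, the usual
#'   motor-imagery range).
#' @param min_bandwidth minimum band width in Hz (default 2).
#' @param step grid step (default 0.5 Hz).
#' @param seed optional RNG seed.
#' @return A \code{particle_set}.
#' @export
sample_prior <- function(n_particles, f_min = 4, f_max = 40,
                         min_bandwidth = 2, step = 0.5, seed = NULL) {
  if (n_particles < 1L) stop("need at least one particle")
  if (f_min >= f_max) stop("f_min must be below f_max")
  cells <- valid_band_grid(f_min, f_max, step, min_bandwidth)
  if (!nrow(cells)) stop("no valid band on the grid")
  pick <- with_seed(seed, sample.int(nrow(cells), n_particles, replace = TRUE))
  particle_set(cells[pick, , drop = FALSE], f_min = f_min, f_max = f_max,
               step = step, min_bandwidth = min_bandwidth)
}

#' Accumulate particles into a 2-D band probability density
#'
#' Particle weights are assigned to the nearest (start, end) grid cell. Cells
#' with start >= end carry no mass.
#'
#' @param ps a \code{particle_set}.
#' @return A \code{pdf2d}: \code{start_grid}, \code{end_grid}, \code{mass}
#'   (start x end matrix summing to 1 over valid cells).
#' @export
pdf2d_from_particles <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  start_grid <- seq(ps$f_min, ps$f_max - ps$step, by = ps$step)
  end_grid <- seq(ps$f_min + ps$step, ps$f_max, by = ps$step)
  mass <- matrix(0, length(start_grid), length(end_grid))
  si <- pmin(pmax(round((ps$particles[, 1] - start_grid[1]) / ps$step) + 1L, 1L),
             length(start_grid))
  ei <- pmin(pmax(round((ps$particles[, 2] - end_grid[1]) / ps$step) + 1L, 1L),
             length(end_grid))
  for (i in seq_along(si))
    mass[si[i], ei[i]] <- mass[si[i], ei[i]] + ps$weights[i]
  pdf2d(start_grid, end_grid, mass)
}

#' Construct a 2-D band density on explicit grids
#'
#' @param start_grid,end_grid frequency grids (Hz) for the band start and end.
#' @param mass non-negative start x end matrix; entries at cells with
#'   start >= end must be zero. Normalized to sum to 1.
#' @return A \code{pdf2d}.
#' @export
pdf2d <- function(start_grid, end_grid, mass) {
  valid <- outer(start_grid, end_grid, `<`)
  if (any(mass[!valid] != 0)) stop("mass on invalid cells (start >= end)")
  if (any(mass < 0)) stop("negative mass")
  total <- sum(mass)
  if (total <= 0) stop("zero total mass")
  structure(list(start_grid = start_grid, end_grid = end_grid,
                 mass = mass / total, valid = valid),
            class = "pdf2d")
}

#' Collapse a 2-D band density to the uniform-subtracted 1-D frequency density
#'
#' The value at frequency f sums, over all valid band cells [s, e] containing
#' f, the difference between the estimated density and the uniform density
#' over the same cells. A uniform 2-D input therefore maps to the all-zero
#' vector, and frequencies covered by more mass than a uniform spread of band
#' hypotheses come out positive.
#'
#' @param p2 a \code{pdf2d}.
#' @return A \code{pdf1d}: \code{grid} and (possibly negative) \code{values}.
#' @export
pdf_1d <- function(p2) {
  stopifnot(inherits(p2, "pdf2d"))
  step <- min(diff(sort(unique(c(p2$start_grid, p2$end_grid)))))
  grid <- seq(min(p2$start_grid), max(p2$end_grid), by = step)
  u <- 1 / sum(p2$valid)
  D <- (p2$mass - u) * p2$valid
  values <- vapply(grid, function(f) {
    rows <- p2$start_grid <= f + 1e-9
    cols <- p2$end_grid >= f - 1e-9
    sum(D[rows, cols])
  }, numeric(1))
  pdf1d(grid, values)
}

#' Construct a 1-D frequency density
#' @param grid strictly increasing, uniformly spaced frequencies (Hz).
#' @param values density values (may be negative after uniform subtraction).
#' @return A \code{pdf1d}.
#' @export
pdf1d <- function(grid, values) {
  if (length(grid) != length(values)) stop("grid/values length mismatch")
  d <- diff(grid)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9)
    stop("grid must be strictly increasing with uniform spacing")
  structure(list(grid = grid, values = as.numeric(values)), class = "pdf1d")
}

#' Neurophysiological frequency weight
#'
#' A mixture of Gaussian densities expressing where discriminative
#' sensorimotor rhythms are expected; the default places components at the mu
#' (10 Hz) and beta (19 Hz) rhythms.
#'
#' @param f frequencies in Hz.
#' @param mixture data frame with columns \code{alpha} (>= 0), \code{mu},
#'   \code{sigma} (> 0); an empty mixture yields weight 1 everywhere.
#' @return numeric weights >= 0.
#' @export
frequency_weight <- function(f, mixture = default_mixture()) {
  if (is.null(mixture) || !nrow(mixture)) return(rep(1, length(f)))
  if (any(mixture$alpha < 0) || any(mixture$sigma <= 0))
    stop("mixture needs alpha >= 0 and sigma > 0")
  w <- rep(0, length(f))
  for (k in seq_len(nrow(mixture)))
    w <- w + mixture$alpha[k] * stats::dnorm(f, mixture$mu[k], mixture$sigma[k])
  w
}

#' Default mu/beta frequency-weight mixture
#'
#' Components (0.6, 10 Hz, 4 Hz) and (0.4, 19 Hz, 5 Hz), covering the mu
#' (8-12 Hz) and beta (16-22 Hz) rhythm ranges. The widths are deliberately
#' generous: the weight should prefer the canonical rhythm regions without
#' overriding where a subject's own spectral evidence peaks — with much
#' narrower components the weight visibly drags the maximum of a weighted
#' density toward the component centers.
#'
#' @return data frame with columns \code{alpha}, \code{mu}, \code{sigma}.
#' @export
default_mixture <- function() {
  data.frame(alpha = c(0.6, 0.4), mu = c(10, 19), sigma = c(4, 5))
}

#' Apply the frequency weight to a 1-D density
#' @param p1 a \code{pdf1d}.
#' @param mixture Gaussian mixture (see \code{\link{frequency_weight}}).
#' @return The point-wise weighted \code{pdf1d}.
#' @export
weighted_pdf1d <- function(p1, mixture = default_mixture()) {
  stopifnot(inherits(p1, "pdf1d"))
  pdf1d(p1$grid, p1$values * frequency_weight(p1$grid, mixture))
}

#' Area under the positive part of a 1-D density
#'
#' Trapezoidal integral of \code{max(value, 0)} over the frequency grid; the
#' uniform-subtracted density is negative where band evidence is
#' sub-uniform, and only super-uniform evidence counts toward the area.
#'
#' @param p1 a \code{pdf1d}.
#' @return scalar area.
#' @export
auc_of_pdf <- function(p1) {
  stopifnot(inherits(p1, "pdf1d"))
  y <- pmax(p1$values, 0)
  n <- length(y)
  if (n < 2L) return(0)
  sum(diff(p1$grid) * (y[-1] + y[-n]) / 2)
}
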