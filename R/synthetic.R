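#' Synthetic subject specification
#'
#' Ground-truth description of one simulated subject: rhythm components
#' (spectral peaks), 1/f noise-floor parameters, event-related
#' desynchronization (ERD) depths, a source-to-channel mixing matrix, and
#' the subject's true BCI performance.
#'
#' @param components data frame with columns \code{center} (Hz), \code{width}
#'   (Hz, Gaussian spectral width) and \code{amplitude} (peak PSD height,
#'   microvolt^2/Hz) — one row per rhythm.
#' @param noise length-3 numeric (k1, k2, lambda) of the floor
#'   k1 + k2 / f^lambda.
#' @param depth ERD depth in [0, 1] per component: the fraction of rhythm
#'   power suppressed in the hemisphere contralateral to the imagined hand.
#' @param mixing sources x channels matrix (two lateralized sources per
#'   component, left first); \code{NULL} builds the default geometric mixing.
#' @param true_performance accuracy in [0, 1] (NA if not assigned).
#' @param n_channels channel count used when \code{mixing} is NULL.
#' @param seed RNG seed; every generator output is a pure function of
#'   (spec, seed).
#' @return An object of class \code{subject_spec}.
#' @export
subject_spec <- function(components, noise = c(0.5, 15, 1.2),
                         depth = rep(0.8, nrow(components)), mixing = NULL,
                         true_performance = NA_real_, n_channels = 16L,
                         seed = 1L) {
  components <- as.data.frame(components)
  stopifnot(all(c("center", "width", "amplitude") %in% names(components)),
            all(components$amplitude >= 0), all(components$width > 0),
            all(depth >= 0 & depth <= 1),
            length(depth) == nrow(components), length(noise) == 3L)
  if (is.null(mixing)) mixing <- default_mixing(nrow(components), n_channels)
  if (nrow(components) > 0 && nrow(mixing) != 2L * nrow(components))
    stop("mixing needs 2 rows (left/right source) per rhythm component")
  if (nrow(mixing) > 0 && qr(mixing)$rank < nrow(mixing))
    stop("mixing matrix must have full row rank")
  structure(list(components = components, noise = as.numeric(noise),
                 depth = as.numeric(depth), mixing = mixing,
                 true_performance = true_performance, seed = as.integer(seed)),
            class = "subject_spec")
}

# Geometric source-to-channel mixing: channels on a roughly square grid,
# each component driven by a left and a right hemisphere source ("C3"/"C4"
# like positions) with Gaussian spatial falloff.
default_mixing <- function(n_components, n_channels = 16L) {
  if (n_components == 0L) return(matrix(0, 0, n_channels))
  ncol_grid <- max(2L, ceiling(sqrt(n_channels)))
  nrow_grid <- ceiling(n_channels / ncol_grid)
  pos <- cbind(row = ((seq_len(n_channels) - 1L) %/% ncol_grid) + 1L,
               col = ((seq_len(n_channels) - 1L) %% ncol_grid) + 1L)
  mid_row <- (nrow_grid + 1) / 2
  left <- c(mid_row, 1 + 0.25 * (ncol_grid - 1))
  right <- c(mid_row, 1 + 0.75 * (ncol_grid - 1))
  gain <- function(src, jitter) {
    exp(-((pos[, 1] - src[1] - jitter[1])^2 +
          (pos[, 2] - src[2] - jitter[2])^2) / (2 * 1.0^2))
  }
  do.call(rbind, lapply(seq_len(n_components), function(k) {
    j <- c(0.1, 0.1) * (k - 1)      # offset higher rhythms slightly
    rbind(gain(left, j), gain(right, j))
  }))
}

# Real colored-noise signals via frequency-domain amplitude shaping: the
# expected one-sided periodogram equals psd_fun(f) exactly. The 1/f target
# is clamped below `f_floor` so the sub-delta divergence does not pump
# unbounded power into the lowest bins (real EEG is amplifier high-passed).
# Returns an n x n_series matrix.
shaped_noise <- function(n, fs, psd_fun, n_series = 1L, f_floor = 0.5) {
  freqs <- (0:(n %/% 2)) * fs / n
  target <- psd_fun(pmax(freqs, f_floor))
  target[1] <- 0                            # no DC power
  amp <- sqrt(target * fs * n / 2)
  nb <- length(freqs)
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    Z <- complex(real = stats::rnorm(nb), imaginary = stats::rnorm(nb)) / sqrt(2)
    Z[1] <- 0
    if (n %% 2L == 0L) Z[nb] <- stats::rnorm(1)
    X <- amp * Z
    full <- c(X, Conj(rev(X[2:(nb - 1L + n %% 2L)])))
    out[, j] <- Re(stats::fft(full, inverse = TRUE)) / n
  }
  out
}

# Gaussian spectral peak, height A at center c, width w (Hz).
peak_psd <- function(f, center, width, amplitude) {
  amplitude * exp(-(f - center)^2 / (2 * width^2))
}

#' Analytic target resting PSD of a synthetic subject
#'
#' The per-channel PSD the generator aims at: the 1/f floor plus each
#' rhythm's Gaussian peak scaled by the squared mixing gains of its two
#' sources.
#'
#' @param spec a \code{subject_spec}.
#' @param f frequencies in Hz.
#' @return matrix, frequencies x channels.
#' @export
resting_target_psd <- function(spec, f) {
  n_ch <- ncol(spec$mixing)
  floor_psd <- spec$noise[1] + spec$noise[2] / f^spec$noise[3]
  out <- matrix(floor_psd, length(f), max(n_ch, 1L))
  for (k in seq_len(nrow(spec$components))) {
    pk <- peak_psd(f, spec$components$center[k], spec$components$width[k],
                   spec$components$amplitude[k] / 2)  # split over 2 sources
    for (src in (2L * k - 1L):(2L * k))
      out <- out + outer(pk, spec$mixing[src, ]^2)
  }
  out
}

#' Generate a resting-state recording
#'
#' Per channel: 1/f-floor colored noise; per rhythm component: two
#' lateralized narrow-band sources (Gaussian spectral envelope around the
#' component center) mixed into the channels. The expected per-channel PSD
#' equals \code{\link{resting_target_psd}}. Seed-deterministic.
#'
#' @param spec a \code{subject_spec}.
#' @param duration seconds (default 150, i.e. ten 15-s resting periods).
#' @param fs sampling rate (default 100 Hz).
#' @return An \code{eeg_recording} with channels \code{S01, S02, ...}.
#' @export
gen_resting <- function(spec, duration = 150, fs = 100) {
  if (duration < 10) stop("resting duration must be at least 10 s")
  n <- round(duration * fs)
  n_ch <- ncol(spec$mixing)
  with_seed(spec$seed, {
    noise <- spec$noise
    data <- t(shaped_noise(n, fs, function(f) noise[1] + noise[2] / f^noise[3],
                           n_series = n_ch))
    for (k in seq_len(nrow(spec$components))) {
      cmp <- spec$components[k, ]
      src <- shaped_noise(n, fs, function(f)
        peak_psd(f, cmp$center, cmp$width, cmp$amplitude / 2), n_series = 2L)
      data <- data + t(src %*% spec$mixing[(2L * k - 1L):(2L * k), , drop = FALSE])
    }
    recording(data, sprintf("S%02d", seq_len(n_ch)), fs)
  })
}

#' Generate a two-class motor-imagery trial set
#'
#' Each trial carries the subject's rhythm sources mixed into the channels on
#' top of fresh 1/f noise. Event-related desynchronization suppresses the
#' source contralateral to the imagined hand: label "L" attenuates the
#' right-hemisphere source power by the component's ERD depth, label "R" the
#' left. Labels are a seeded random permutation of the two classes.
#'
#' @param spec a \code{subject_spec}.
#' @param n_per_class trials per class (default 75).
#' @param fs sampling rate (default 100 Hz).
#' @param trial_s trial length in seconds (default 4, the cue duration).
#' @return A \code{trial_set} with labels "L"/"R".
#' @export
gen_motor_imagery <- function(spec, n_per_class = 75L, fs = 100, trial_s = 4) {
  if (n_per_class < 2L) stop("need at least 2 trials per class")
  nt <- round(trial_s * fs)
  n_ch <- ncol(spec$mixing)
  n_trials <- 2L * n_per_class
  with_seed(spec$seed + 1L, {
    labels <- sample(rep(c("L", "R"), n_per_class))
    trials <- array(0, dim = c(n_trials, n_ch, nt))
    noise <- spec$noise
    for (i in seq_len(n_trials)) {
      x <- t(shaped_noise(nt, fs, function(f) noise[1] + noise[2] / f^noise[3],
                          n_series = n_ch))
      for (k in seq_len(nrow(spec$components))) {
        cmp <- spec$components[k, ]
        src <- shaped_noise(nt, fs, function(f)
          peak_psd(f, cmp$center, cmp$width, cmp$amplitude / 2), n_series = 2L)
        # power scale: contralateral source keeps (1 - depth) of its power
        att <- sqrt(1 - spec$depth[k])
        if (labels[i] == "L") src[, 2] <- src[, 2] * att else
          src[, 1] <- src[, 1] * att
        x <- x + t(src %*% spec$mixing[(2L * k - 1L):(2L * k), , drop = FALSE])
      }
      trials[i, , ] <- x
    }
    trial_set(trials, labels, fs, channels = sprintf("S%02d", seq_len(n_ch)))
  })
}

# Type-specific parameter distributions of the synthetic cohort. Amplitudes
# and depths are drawn so that the logistic performance link lands near 0.9
# (mu type), 0.8 (beta type) and 0.55 (flat type) on average.
draw_type_spec <- function(type, seed, n_channels = 16L) {
  with_seed(seed, {
    noise <- c(stats::runif(1, 0.3, 1), stats::runif(1, 5, 20),
               stats::runif(1, 0.8, 1.5))
    par <- switch(type,
      mu = list(center = stats::runif(1, 9, 11.5),
                width = stats::runif(1, 0.8, 1.5),
                amplitude = stats::runif(1, 2, 6),
                depth = stats::runif(1, 0.6, 0.9)),
      beta = list(center = stats::runif(1, 17, 21),
                  width = stats::runif(1, 1, 2),
                  amplitude = stats::runif(1, 1.5, 4),
                  depth = stats::runif(1, 0.5, 0.8)),
      flat = list(center = stats::runif(1, 8, 22),
                  width = stats::runif(1, 1, 2),
                  amplitude = stats::runif(1, 0, 0.3),
                  depth = stats::runif(1, 0, 0.3)),
      stop("unknown type: ", type))
    subject_spec(data.frame(center = par$center, width = par$width,
                            amplitude = par$amplitude),
                 noise = noise, depth = par$depth,
                 n_channels = n_channels, seed = seed)
  })
}

# Logistic link from planted rhythm strength (sum of amplitude x ERD depth)
# to expected BCI accuracy.
performance_link <- function(strength) {
  0.5 + 0.45 * stats::plogis((strength - 1.2) / 0.55)
}

#' Generate a synthetic cohort with linked resting and imagery data
#'
#' Subjects are drawn from three prototypes — mu-rhythm, beta-rhythm and
#' flat-spectrum ("BCI-illiterate") — in the requested proportions. Each
#' subject's true performance is a logistic function of total rhythm
#' amplitude x ERD depth plus Gaussian noise, and the resting recording is
#' generated from the same spec, so resting spectra and imagery performance
#' share the statistical structure the predictor assumes.
#'
#' @param n_subjects cohort size (default 80); at least 3.
#' @param mixture proportions of (mu, beta, flat) subjects, summing to 1.
#' @param sigma standard deviation of the performance noise (default 0.05).
#' @param seed cohort RNG seed.
#' @param n_channels channels per subject (default 16).
#' @param resting_duration seconds of resting EEG (default 150).
#' @param resting if TRUE (default), generate the resting recordings.
#' @param imagery if TRUE, also generate the motor-imagery trial sets
#'   (default FALSE; for an 80-subject cohort the trial arrays are large, so
#'   they are opt-in or can be produced per subject with
#'   \code{\link{gen_motor_imagery}} from the returned specs).
#' @param n_per_class imagery trials per class when \code{imagery} is TRUE.
#' @return list with \code{specs}, \code{types}, \code{performance},
#'   \code{recordings} (or NULL), \code{trialsets} (or NULL).
#' @export
gen_cohort <- function(n_subjects = 80L, mixture = c(0.5, 0.3, 0.2),
                       sigma = 0.05, seed = 1L, n_channels = 16L,
                       resting_duration = 150, resting = TRUE,
                       imagery = FALSE, n_per_class = 75L) {
  if (n_subjects < 3L) stop("cohort needs at least 3 subjects")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  types <- with_seed(seed,
    sample(c("mu", "beta", "flat"), n_subjects, replace = TRUE,
           prob = mixture))
  specs <- vector("list", n_subjects)
  performance <- numeric(n_subjects)
  noise_draw <- with_seed(seed + 1L, stats::rnorm(n_subjects, 0, sigma))
  for (i in seq_len(n_subjects)) {
    sp <- draw_type_spec(types[i], seed = seed + 100L + i,
                         n_channels = n_channels)
    strength <- sum(sp$components$amplitude * sp$depth)
    perf <- min(max(performance_link(strength) + noise_draw[i], 0), 1)
    sp$true_performance <- perf
    specs[[i]] <- sp
    performance[i] <- perf
  }
  recordings <- if (resting)
    lapply(specs, gen_resting, duration = resting_duration) else NULL
  trialsets <- if (imagery)
    lapply(specs, gen_motor_imagery, n_per_class = n_per_class) else NULL
  list(specs = specs, types = types, performance = performance,
       recordings = recordings, trialsets = trialsets)
}
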