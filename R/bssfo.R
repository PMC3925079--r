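#' BSSFO configuration
#'
#' Tunable parameters of the particle-based frequency-band posterior
#' estimation.
#'
#' @param n_particles particle count (default 100).
#' @param f_min,f_max analysis range in Hz (defaults 4 and 40).
#' @param step frequency grid step (default 0.5 Hz).
#' @param min_bandwidth minimum band width (default 2 Hz).
#' @param m CSP filter pairs per particle (default NULL: 2 pairs, or 1 for
#'   montages of at most 4 channels).
#' @param inner_folds chronological folds of the inner likelihood
#'   cross-validation (default 4).
#' @param max_iter maximum importance-resampling iterations (default 20).
#' @param min_iter iterations before the convergence tolerance is consulted
#'   (default 8): the particle cloud needs several selection rounds before a
#'   stable mean indicates convergence rather than a still-diffuse posterior.
#' @param tol convergence tolerance on the change of the weighted mean band
#'   endpoints, in Hz (default 0.25).
#' @param tau weight-sharpening exponent: particle weights are proportional
#'   to accuracy^tau. Raw accuracies live in [0.5, 1], so unsharpened weights
#'   exert almost no selection; the default 30 makes a one-percentage-point
#'   accuracy deficit cost roughly a third of a particle's weight per
#'   iteration, enough to resolve the near-plateau of bands containing the
#'   discriminative rhythm.
#' @param perturb_sd Gaussian perturbation of each endpoint after resampling,
#'   in Hz (default 1), snapped back to the grid and reflected at the range
#'   bounds.
#' @param perturb_decay multiplicative decay of the perturbation width per
#'   iteration (default 0.85). A fixed kernel leaves the particle cloud in a
#'   diffusion-selection equilibrium about one kernel width wide; annealing
#'   the kernel lets late iterations refine locally so the posterior can
#'   contract onto the most discriminative band.
#' @param seed RNG seed for sampling, resampling and perturbation.
#' @return list of class \code{bssfo_config}.
#' @export
bssfo_config <- function(n_particles = 100L, f_min = 4, f_max = 40,
                         step = 0.5, min_bandwidth = 2, m = NULL,
                         inner_folds = 4L, max_iter = 20L, min_iter = 8L,
                         tol = 0.25, tau = 30, perturb_sd = 1,
                         perturb_decay = 0.85, seed = NULL) {
  structure(as.list(environment()), class = "bssfo_config")
}

# Per-trial cross-spectral cache. For a zero-phase filter with squared
# magnitude response h2(f), the filtered per-trial covariance is
#   C = (1/n^2) * sum_k mult_k * h2(f_k)^2 * Re(X_k X_k^H),
# with mult_k = 2 for interior bins (conjugate mirror) and 1 at DC/Nyquist.
# M stores Re(X_k X_k^H) flattened per bin so any band's covariances are one
# crossprod away; exact, not an approximation.
spectral_cache <- function(ts) {
  d <- dim(ts$trials)
  n <- d[3]
  x <- matrix(aperm(ts$trials, c(3, 2, 1)), nrow = n)    # time x (ch*trial)
  Fx <- stats::mvfft(x)
  nb <- n %/% 2L + 1L
  M <- matrix(0, nb, d[2]^2 * d[1])
  ii <- rep(seq_len(d[2]), d[2])
  jj <- rep(seq_len(d[2]), each = d[2])
  for (k in seq_len(nb)) {
    A <- matrix(Fx[k, ], nrow = d[2])                    # ch x trial, complex
    R <- Re(A); I <- Im(A)
    M[k, ] <- as.vector(R[ii, , drop = FALSE] * R[jj, , drop = FALSE] +
                        I[ii, , drop = FALSE] * I[jj, , drop = FALSE])
  }
  mult <- rep(2, nb); mult[1] <- 1
  if (n %% 2L == 0L) mult[nb] <- 1
  list(M = M, freqs = (seq_len(nb) - 1L) * ts$fs / n, mult = mult,
       n_time = n, n_ch = d[2], n_trial = d[1], fs = ts$fs,
       labels = ts$labels)
}

# Band-limited per-trial covariances from the cache (list of ch x ch).
cache_band_covariances <- function(cache, bd) {
  h2 <- bandpass_response2(bd, cache$fs, cache$freqs)
  wgt <- cache$mult * h2^2 / (cache$n_time^2)
  v <- as.numeric(crossprod(cache$M, wgt))
  lapply(seq_len(cache$n_trial), function(i) {
    matrix(v[((i - 1) * cache$n_ch^2 + 1):(i * cache$n_ch^2)],
           cache$n_ch, cache$n_ch)
  })
}

#' Likelihood of a frequency band
#'
#' The probability that single-trial EEG is correctly classified given the
#' band hypothesis, estimated as the mean inner chronological
#' cross-validation accuracy of the band-pass -> CSP -> log-variance -> LDA
#' chain restricted to that band.
#'
#' @param bd a \code{band}.
#' @param trials a two-class \code{trial_set}.
#' @param m CSP pairs (default: 2, or 1 for montages of at most 4 channels).
#' @param inner_folds chronological folds (default 4).
#' @param cache optional precomputed spectral cache (internal speed-up; the
#'   result is identical to explicit filtering).
#' @return likelihood in [0, 1].
#' @export
particle_likelihood <- function(bd, trials, m = NULL, inner_folds = 4L,
                                cache = NULL) {
  covs <- if (!is.null(cache)) cache_band_covariances(cache, bd) else NULL
  mean(band_chain_cv_acc(trials, bd, m, inner_folds, covs = covs))
}

# Systematic resampling: one uniform offset, n evenly spaced pointers.
systematic_resample <- function(weights, n = length(weights)) {
  cw <- cumsum(weights) / sum(weights)
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cw, left.open = TRUE) + 1L
}

# Perturb resampled particles: Gaussian jitter on both endpoints, snapped to
# the grid, reflected into [f_min, f_max]; redrawn while the band is
# degenerate (b_e - b_s < min_bandwidth), falling back to the parent.
perturb_particles <- function(particles, cfg, sd = cfg$perturb_sd) {
  out <- particles
  for (i in seq_len(nrow(particles))) {
    for (try in 1:100) {
      p <- particles[i, ] + stats::rnorm(2, 0, sd)
      p <- snap_to_grid(reflect(p, cfg$f_min, cfg$f_max), cfg$step, cfg$f_min)
      if (p[2] - p[1] >= cfg$min_bandwidth - 1e-9) { out[i, ] <- p; break }
    }
  }
  out
}

#' Fit the Bayesian spatio-spectral filter optimization model
#'
#' Iterative importance resampling over frequency-band particles: each
#' particle's likelihood is its inner cross-validated classification
#' accuracy, weights are the sharpened likelihoods, particles are
#' systematically resampled and perturbed on the frequency grid, and the loop
#' stops when the weighted mean band moves less than \code{tol} Hz or after
#' \code{max_iter} iterations. The returned model carries the posterior
#' particle set and one CSP + LDA pipeline per distinct band, trained on all
#' trials.
#'
#' @param trials a two-class \code{trial_set}.
#' @param config a \code{\link{bssfo_config}}.
#' @return A \code{bssfo_model}.
#' @export
bssfo_fit <- function(trials, config = bssfo_config()) {
  stopifnot(inherits(trials, "trial_set"), inherits(config, "bssfo_config"))
  assert_two_classes(trials)
  cache <- spectral_cache(trials)
  m_use <- default_csp_pairs(config$m, dim(trials$trials)[2])
  memo <- new.env(parent = emptyenv())
  lik_of <- function(p) {
    key <- sprintf("%.2f_%.2f", p[1], p[2])
    if (is.null(memo[[key]]))
      memo[[key]] <- particle_likelihood(band(p[1], p[2]), trials,
                                         m = m_use,
                                         inner_folds = config$inner_folds,
                                         cache = cache)
    memo[[key]]
  }
  with_seed(config$seed, {
    ps <- sample_prior(config$n_particles, config$f_min, config$f_max,
                       config$min_bandwidth, config$step)
    converged <- FALSE
    chance_flag <- FALSE
    mu_prev <- NULL
    weights <- ps$weights
    for (iter in seq_len(config$max_iter)) {
      lik <- apply(ps$particles, 1L, lik_of)
      raw <- lik^config$tau
      if (!any(raw > 0) || diff(range(lik)) < 1e-12) {
        weights <- rep(1 / length(lik), length(lik))
        if (max(lik) <= 0.5 + 1e-9) {
          chance_flag <- TRUE
          warning("all band likelihoods at chance level; posterior left uniform")
        }
      } else {
        weights <- raw / sum(raw)
      }
      ps <- particle_set(ps$particles, weights, config$f_min, config$f_max,
                         config$step, config$min_bandwidth, iteration = iter)
      mu <- particle_mean_band(ps)
      if (!is.null(mu_prev) && iter >= config$min_iter &&
          max(abs(mu - mu_prev)) < config$tol) {
        converged <- TRUE
        break
      }
      mu_prev <- mu
      if (iter == config$max_iter) break
      idx <- systematic_resample(weights)
      sd_iter <- config$perturb_sd * config$perturb_decay^(iter - 1L)
      ps <- particle_set(perturb_particles(ps$particles[idx, , drop = FALSE],
                                           config, sd = sd_iter),
                         NULL, config$f_min, config$f_max, config$step,
                         config$min_bandwidth, iteration = iter)
    }
    # one trained pipeline per distinct posterior band, weights aggregated
    keys <- sprintf("%.2f_%.2f", ps$particles[, 1], ps$particles[, 2])
    agg <- rowsum(ps$weights, keys)
    classifiers <- lapply(rownames(agg), function(k) {
      p <- as.numeric(strsplit(k, "_")[[1]])
      bd <- band(p[1], p[2])
      covs <- cache_band_covariances(cache, bd)
      S <- class_covariances(covs, trials$labels)
      flt <- csp_from_cov(S[[1]], S[[2]], m_use)
      feat <- logvar_from_cov(covs, flt$W)
      list(band = bd, filters = flt,
           lda = lda_fit(feat, trials$labels), weight = agg[k, 1])
    })
    structure(list(posterior = ps, classifiers = classifiers, config = config,
                   converged = converged, iterations = ps$iteration,
                   chance_flag = chance_flag,
                   classes = sort(unique(trials$labels))),
              class = "bssfo_model")
  })
}

#' @export
print.bssfo_model <- function(x, ...) {
  mu <- particle_mean_band(x$posterior)
  cat(sprintf(
    "<bssfo_model> %d particles, %d distinct bands, %d iteration(s)%s; posterior mean band [%.2f, %.2f] Hz\n",
    nrow(x$posterior$particles), length(x$classifiers), x$iterations,
    if (x$converged) " (converged)" else "", mu[1], mu[2]))
  invisible(x)
}

#' Classify trials with a fitted BSSFO model
#'
#' Every distinct posterior band votes with its own CSP + LDA pipeline; votes
#' are combined by posterior weight and the majority class is returned per
#' trial.
#'
#' @param model a \code{bssfo_model}.
#' @param trials a \code{trial_set} with the training channel count.
#' @return character vector of predicted labels.
#' @export
bssfo_predict <- function(model, trials) {
  stopifnot(inherits(model, "bssfo_model"), inherits(trials, "trial_set"))
  if (!length(model$classifiers)) stop("model has no trained classifiers")
  cache <- spectral_cache(trials)
  n <- dim(trials$trials)[1]
  tally <- matrix(0, n, 2, dimnames = list(NULL, model$classes))
  for (clf in model$classifiers) {
    covs <- cache_band_covariances(cache, clf$band)
    feat <- logvar_from_cov(covs, clf$filters$W)
    pred <- lda_predict(clf$lda, feat)
    for (cl in model$classes)
      tally[, cl] <- tally[, cl] + clf$weight * (pred == cl)
  }
  model$classes[max.col(tally, ties.method = "first")]
}

#' Chronological cross-validated error of the full BSSFO pipeline
#'
#' Fits a BSSFO model on the training blocks of each chronological fold and
#' scores 0-1 loss on the held-out block.
#'
#' @param trials a two-class \code{trial_set}.
#' @param config a \code{\link{bssfo_config}}.
#' @param folds number of chronological folds (default 8).
#' @return mean 0-1 loss over folds.
#' @export
bssfo_cv_error <- function(trials, config = bssfo_config(), folds = 8L) {
  splits <- chrono_cv_split(dim(trials$trials)[1], folds)
  err <- vapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i
    model <- bssfo_fit(subset_trials(trials, sp$train), cfg)
    pred <- bssfo_predict(model, subset_trials(trials, sp$test))
    mean(pred != trials$labels[sp$test])
  }, numeric(1))
  mean(err)
}
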