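#' Chronological cross-validation folds
#'
#' Trials are partitioned into \code{k} contiguous blocks in chronological
#' order; each block serves as the test set once, all remaining blocks as the
#' training set. Remainder trials go to the earliest blocks.
#'
#' @param n_trials number of trials.
#' @param k number of folds (default 8); must satisfy \code{2 <= k <= n_trials}.
#' @return list of \code{k} lists with elements \code{train} and \code{test}.
#' @export
chrono_cv_split <- function(n_trials, k = 8L) {
  if (k < 2L) stop("chronological CV needs k >= 2")
  if (k > n_trials) stop("k = ", k, " exceeds trial count ", n_trials)
  sizes <- rep(n_trials %/% k, k)
  rem <- n_trials - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- starts[i]:ends[i]
    list(train = setdiff(seq_len(n_trials), test), test = test)
  })
}

# Chronological CV accuracies of the band-pass -> CSP -> log-variance -> LDA
# chain for one band. Works from per-trial band-limited covariances, either
# supplied directly (spectral cache path) or computed after explicit
# filtering. Folds whose training split lacks a class are dropped.
band_chain_cv_acc <- function(ts, bd, m = NULL, folds = 8L, covs = NULL) {
  assert_two_classes(ts)
  if (is.null(covs)) covs <- trial_covariances(bandpass(ts, bd))
  m <- default_csp_pairs(m, nrow(covs[[1]]))
  labels <- ts$labels
  splits <- chrono_cv_split(length(labels), folds)
  acc <- numeric(0)
  for (sp in splits) {
    if (length(unique(labels[sp$train])) < 2L) {
      warning("fold with single-class training data skipped")
      next
    }
    S <- class_covariances(covs[sp$train], labels[sp$train])
    flt <- csp_from_cov(S[[1]], S[[2]], m)
    feat <- logvar_from_cov(covs, flt$W)
    model <- lda_fit(feat[sp$train, , drop = FALSE], labels[sp$train])
    pred <- lda_predict(model, feat[sp$test, , drop = FALSE])
    acc <- c(acc, mean(pred == labels[sp$test]))
  }
  if (!length(acc)) stop("no usable folds")
  acc
}

#' Fixed-band CSP baseline with chronological cross-validation
#'
#' Band-pass -> CSP -> log-variance -> LDA, spatial filters and classifier
#' fit on the training folds only; reports the mean 0-1 loss over
#' chronological folds. Standard reference bands are the broad band (5-30 Hz),
#' the mu band (8-12 Hz) and the beta band (16-22 Hz).
#'
#' @param trials a two-class \code{trial_set}.
#' @param bd a \code{band}.
#' @param m CSP pairs (default: 2, or 1 for montages of at most 4 channels).
#' @param folds chronological folds (default 8).
#' @return cross-validated classification error in [0, 1].
#' @export
fixed_band_pipeline <- function(trials, bd, m = NULL, folds = 8L) {
  1 - mean(band_chain_cv_acc(trials, bd, m, folds))
}

#' Heuristic discriminative-band selection
#'
#' For every frequency on the scan grid the per-trial log band-power of each
#' channel is correlated with the class labels; the per-frequency score is
#' the maximum absolute Pearson correlation over channels. Starting from the
#' frequency of the maximum score, the interval is grown outward one grid
#' step at a time while the boundary frequency's score exceeds 5% of the
#' maximum score.
#'
#' @param trials a two-class \code{trial_set}.
#' @param range scan range in Hz (default 5 to 35).
#' @param step grid step in Hz (default 0.5).
#' @return A \code{band}; falls back to [8, 12] with a warning if all scores
#'   are zero.
#' @export
heuristic_band <- function(trials, range = c(5, 35), step = 0.5) {
  stopifnot(inherits(trials, "trial_set"))
  assert_two_classes(trials)
  grid <- seq(range[1], range[2], by = step)
  d <- dim(trials$trials)
  x <- matrix(aperm(trials$trials, c(3, 2, 1)), nrow = d[3])   # time x (ch*trial)
  res <- welch_psd(x, trials$fs, nperseg = min(d[3], round(2 * trials$fs)),
                   grid = grid)
  logp <- log(pmax(res$psd, 1e-300))          # grid x (ch*trial)
  y <- as.numeric(factor(trials$labels, levels = sort(unique(trials$labels))))
  score <- numeric(length(grid))
  for (ch in seq_len(d[2])) {
    cols <- ch + d[2] * (seq_len(d[1]) - 1L)
    r <- suppressWarnings(stats::cor(t(logp[, cols, drop = FALSE]), y))
    r[is.na(r)] <- 0
    score <- pmax(score, abs(r))
  }
  expand_band_from_scores(grid, score)
}

# Outward expansion from the peak score; the boundary moves while the next
# frequency's score stays strictly above 5% of the maximum.
expand_band_from_scores <- function(grid, score) {
  if (all(score == 0)) {
    warning("all band-power/label correlations are zero; returning [8, 12]")
    return(band(8, 12))
  }
  i_max <- which.max(score)
  thr <- 0.05 * score[i_max] * (1 + 1e-9)   # tolerate exact-5% boundaries
  lo <- i_max
  while (lo > 1L && score[lo - 1L] > thr) lo <- lo - 1L
  hi <- i_max
  while (hi < length(grid) && score[hi + 1L] > thr) hi <- hi + 1L
  if (lo == hi) {
    step <- if (length(grid) > 1) grid[2] - grid[1] else 0.5
    return(band(grid[lo] - step / 2, grid[lo] + step / 2))
  }
  band(grid[lo], grid[hi])
}
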