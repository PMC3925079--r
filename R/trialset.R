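#' Construct a set of epoched motor-imagery trials
#'
#' @param trials numeric array, trial x channel x time (microvolts).
#' @param labels class label per trial (two-class, e.g. "L"/"R").
#' @param fs sampling rate in Hz.
#' @param order chronological trial indices (permutation of
#'   \code{seq_len(n)}); defaults to the given order.
#' @param channels optional channel labels.
#' @return An object of class \code{trial_set}.
#' @export
trial_set <- function(trials, labels, fs, order = NULL, channels = NULL) {
  stopifnot(is.array(trials), length(dim(trials)) == 3L)
  labels <- as.character(labels)
  n <- dim(trials)[1]
  if (length(labels) != n)
    stop("labels length (", length(labels), ") != trial count (", n, ")")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(order)) order <- seq_len(n)
  if (!setequal(order, seq_len(n)))
    stop("order must be a permutation of 1..n")
  structure(list(trials = trials, labels = labels, fs = fs,
                 order = as.integer(order), channels = channels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz; classes: %s\n",
              d[1], d[2], d[3], x$fs,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

n_trials <- function(ts) dim(ts$trials)[1]

#' Subset trials by index
#' @param ts a \code{trial_set}.
#' @param idx trial indices to keep.
#' @return A \code{trial_set} with those trials, order renumbered.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$trials[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
            channels = ts$channels)
}

assert_two_classes <- function(ts) {
  if (length(unique(ts$labels)) != 2L)
    stop("operation requires exactly two classes, got: ",
         paste(unique(ts$labels), collapse = ", "))
  invisible(TRUE)
}
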