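#' Laplacian montage specification
#'
#' Maps each center channel to the set of neighbor channels whose mean is
#' subtracted when deriving the surface-Laplacian signal (a spatial high-pass
#' that sharpens focal sensorimotor rhythms).
#'
#' @param name montage identifier.
#' @param laplacian_map named list: center channel -> character vector of
#'   neighbor channels.
#' @return An object of class \code{montage_spec}.
#' @export
montage_spec <- function(name, laplacian_map) {
  if (!length(laplacian_map) || is.null(names(laplacian_map)))
    stop("laplacian_map must be a non-empty named list")
  if (any(!vapply(laplacian_map, length, 1L)))
    stop("every center needs at least one neighbor")
  structure(list(name = name,
                 laplacian_map = lapply(laplacian_map, as.character)),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> '%s': %d Laplacian centers\n",
              x$name, length(x$laplacian_map)))
  invisible(x)
}

#' Load a shipped or user-supplied Laplacian montage
#'
#' Three montages ship with the package, mirroring the usual small/large
#' sensorimotor arrangements: \code{"3lap"} (C3, Cz, C4), \code{"16lap"}
#' (motor-related channels), and \code{"39lap"}. Neighbor sets are the
#' orthogonally adjacent 10-10 electrodes (fewer at cap edges) and are an
#' approximation users can override with their own file.
#'
#' File format: one line per center, \code{center<TAB>nb1,nb2,...}.
#'
#' @param name \code{"3lap"}, \code{"16lap"}, \code{"39lap"}, or a file path.
#' @return A \code{montage_spec}.
#' @export
load_montage <- function(name) {
  path <- switch(name,
    "3lap"  = system.file("extdata/montages/lap3.tsv",  package = "bssfor"),
    "16lap" = system.file("extdata/montages/lap16.tsv", package = "bssfor"),
    "39lap" = system.file("extdata/montages/lap39.tsv", package = "bssfor"),
    name)
  if (!file.exists(path)) stop("montage not found: ", name)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  centers <- vapply(parts, `[[`, character(1), 1L)
  map <- lapply(parts, function(p) trimws(strsplit(p[[2]], ",")[[1]]))
  names(map) <- centers
  montage_spec(if (name %in% c("3lap", "16lap", "39lap")) name else basename(path),
               map)
}

#' Derive surface-Laplacian channels
#'
#' Each output channel is the center electrode minus the mean of its montage
#' neighbors, computed sample-wise. The output contains only the montage
#' centers, in montage order; annotations and sampling rate carry over.
#'
#' @param rec an \code{eeg_recording} containing every center and neighbor.
#' @param montage a \code{montage_spec}.
#' @return An \code{eeg_recording} of Laplacian-derived channels.
#' @export
laplacian_derive <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "montage_spec"))
  centers <- names(montage$laplacian_map)
  needed <- unique(c(centers, unlist(montage$laplacian_map)))
  missing <- setdiff(needed, rec$channels)
  if (length(missing))
    stop("channels required by montage '", montage$name,
         "' missing from recording: ", paste(missing, collapse = ", "))
  out <- matrix(0, nrow = length(centers), ncol = ncol(rec$data))
  for (i in seq_along(centers)) {
    nb <- montage$laplacian_map[[centers[i]]]
    ref <- if (length(nb) == 1L) rec$data[nb, ] else colMeans(rec$data[nb, , drop = FALSE])
    out[i, ] <- rec$data[centers[i], ] - ref
  }
  recording(out, centers, rec$fs, rec$annotations)
}

#' Downsample a recording with a Chebyshev anti-alias filter
#'
#' A type-I Chebyshev low-pass (order 8, 0.01 dB passband ripple, cutoff
#' 0.4 x target rate) is applied forward-backward (zero phase) before
#' decimation, so tones below 0.4 x the target rate keep their power within
#' a fraction of a percent (the two passes double the ripple in dB).
#'
#' @param rec an \code{eeg_recording}.
#' @param target_fs target sampling rate in Hz; must divide \code{rec$fs}.
#' @return The decimated \code{eeg_recording}; annotation sample indices are
#'   rescaled to the new rate.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds the recording rate")
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("decimation factor fs/target_fs = ", q, " is not an integer")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  flt <- signal::cheby1(8, 0.01, 0.4 * target_fs / (rec$fs / 2))
  filtered <- t(apply(rec$data, 1L, function(x) signal::filtfilt(flt, x)))
  keep <- seq(1L, ncol(rec$data), by = q)
  ann <- rec$annotations
  if (nrow(ann)) ann$sample <- ann$sample %/% q
  recording(filtered[, keep, drop = FALSE], rec$channels, target_fs, ann)
}

#' Cut a continuous recording into labeled trials
#'
#' One trial per retained cue event, spanning \code{window[1]} to
#' \code{window[2]} seconds relative to the cue sample. Only events whose
#' label is in \code{classes} are kept; events whose window falls outside the
#' recording are dropped with a warning. Chronological order is preserved.
#'
#' @param rec an \code{eeg_recording} with annotations (or pass \code{events}).
#' @param events optional event data frame overriding \code{rec$annotations}.
#' @param window numeric length-2, seconds relative to the cue.
#' @param classes the two class labels to retain (default \code{c("L","R")}).
#' @return A \code{trial_set}.
#' @export
epoch <- function(rec, events = NULL, window = c(0, 4), classes = c("L", "R")) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2L,
            window[2] > window[1])
  ev <- if (is.null(events)) rec$annotations else as.data.frame(events)
  ev <- ev[ev$label %in% classes, , drop = FALSE]
  ev <- ev[order(ev$sample), , drop = FALSE]
  len <- round((window[2] - window[1]) * rec$fs)
  start <- ev$sample + round(window[1] * rec$fs)   # 0-based
  ok <- start >= 0 & (start + len) <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " event(s) with out-of-bounds windows dropped")
  ev <- ev[ok, , drop = FALSE]; start <- start[ok]
  if (!nrow(ev)) stop("no events retained after windowing")
  trials <- array(0, dim = c(nrow(ev), nrow(rec$data), len))
  for (i in seq_len(nrow(ev)))
    trials[i, , ] <- rec$data[, (start[i] + 1L):(start[i] + len)]
  trial_set(trials, ev$label, rec$fs, channels = rec$channels)
}
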