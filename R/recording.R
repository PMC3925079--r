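#' Construct a continuous EEG recording
#'
#' A recording holds a channel-by-sample matrix of microvolt values, the
#' sampling rate, and an optional event (annotation) table of cue markers.
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts).
#' @param channels character vector of channel labels (10-20 names), one per row.
#' @param fs sampling rate in Hz.
#' @param annotations data frame with columns \code{sample} (0-based sample
#'   index) and \code{label}, or \code{NULL}.
#' @return An object of class \code{eeg_recording}.
#' @export
recording <- function(data, channels, fs, annotations = NULL) {
  data <- as.matrix(data)
  channels <- as.character(channels)
  if (length(channels) != nrow(data))
    stop("channel label count (", length(channels),
         ") does not match data row count (", nrow(data), ")")
  if (anyDuplicated(channels))
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0), label = character(0),
                              stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations)
    if (!all(c("sample", "label") %in% names(annotations)))
      stop("annotations need 'sample' and 'label' columns")
    if (nrow(annotations) &&
        (min(annotations$sample) < 0 || max(annotations$sample) >= ncol(data)))
      stop("annotation sample indices outside the recording")
  }
  rownames(data) <- channels
  structure(list(channels = channels, fs = fs, data = data,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an \code{eeg_recording}.
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read an EEG recording from disk
#'
#' Supports two formats: 16-bit EDF (European Data Format; digital values are
#' rescaled to physical microvolts with the per-signal calibration fields of
#' the header) and a plain text matrix format with the header lines
#' \code{fs=<Hz>} and \code{channels=<comma list>} followed by
#' whitespace-separated samples, one row per time point.
#'
#' @param path file path.
#' @param format \code{"edf"} or \code{"matrix"}; \code{"auto"} decides by
#'   file extension.
#' @return An \code{eeg_recording}.
#' @export
load_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") read_edf(path) else read_matrix_recording(path)
}

read_matrix_recording <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^fs=", lines[1]) || !grepl("^channels=", lines[2]))
    stop("matrix recording must start with 'fs=' and 'channels=' header lines: ", path)
  fs <- as.numeric(sub("^fs=", "", lines[1]))
  channels <- trimws(strsplit(sub("^channels=", "", lines[2]), ",")[[1]])
  m <- as.matrix(utils::read.table(path, skip = 2L, header = FALSE))
  if (ncol(m) != length(channels))
    stop("matrix has ", ncol(m), " columns but header names ",
         length(channels), " channels")
  recording(t(m), channels, fs)
}

#' Write a recording in the plain matrix format
#'
#' @param rec an \code{eeg_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fs=%.10g", rec$fs),
               paste0("channels=", paste(rec$channels, collapse = ","))), con)
  utils::write.table(format(t(rec$data), digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal 16-bit EDF reader. Header layout per the EDF standard: 256-byte
# static header, then 256 bytes per signal of per-signal fields, then data
# records of interleaved 2-byte little-endian integers. Physical value =
# (digital - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) + phys_min.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                      # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels     <- field(16)
  field(80); field(8)          # transducer, unit
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min  <- as.numeric(field(8))
  dig_max  <- as.numeric(field(8))
  field(80)                    # prefiltering
  spr <- as.integer(field(8))  # samples per record per signal
  field(32)                    # reserved
  stopifnot(seek(con) == header_bytes)
  if (anyDuplicated(labels)) stop("duplicate channel labels in EDF: ", path)
  total <- n_records * sum(spr)
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(raw16) < total) stop("EDF truncated: ", path)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- raw16[(pos + 1L):(pos + spr[s])]
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (seg - dig_min[s]) * gain[s] + phys_min[s]
      pos <- pos + spr[s]
    }
  }
  recording(data, labels, spr[1] / record_dur)
}

#' Read an event table
#'
#' Tab-separated file with two columns: 0-based sample index and class label.
#'
#' @param path file path.
#' @return data frame with columns \code{sample}, \code{label}.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "label"),
                          colClasses = c("integer", "character"))
  ev
}

#' Write an event table
#' @param events data frame with \code{sample} and \code{label}.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("sample", "label")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
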