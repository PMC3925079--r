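# Independent oracles and fixture builders used across the test files.

# Brute-force evaluation of the uniform-subtracted 1-D density: explicit
# double loop over every valid (start, end) cell, no vectorization shared
# with the implementation.
oracle_pdf1d <- function(start_grid, end_grid, mass, f) {
  valid <- 0L
  for (i in seq_along(start_grid))
    for (j in seq_along(end_grid))
      if (start_grid[i] < end_grid[j]) valid <- valid + 1L
  u <- 1 / valid
  total <- 0
  for (i in seq_along(start_grid))
    for (j in seq_along(end_grid))
      if (start_grid[i] < end_grid[j] &&
          start_grid[i] <= f + 1e-9 && end_grid[j] >= f - 1e-9)
        total <- total + (mass[i, j] - u)
  total
}

# Exhaustive greedy Ward agglomeration: recompute every pairwise merge cost
# (the Ward increase in within-cluster SSE) at each step and merge the
# cheapest pair. Returns the list of member index sets merged at each step.
oracle_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      na <- length(clusters[[a]]); nb <- length(clusters[[b]])
      ma <- colMeans(X[clusters[[a]], , drop = FALSE])
      mb <- colMeans(X[clusters[[b]], , drop = FALSE])
      cost <- na * nb / (na + nb) * sum((ma - mb)^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets merged at each step of an hclust tree.
hclust_merge_sets <- function(tree) {
  members <- list()
  merges <- list()
  for (s in seq_len(nrow(tree$merge))) {
    get <- function(idx) if (idx < 0) -idx else members[[idx]]
    m <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
    members[[s]] <- m
    merges[[s]] <- m
  }
  merges
}

# Random two-class trial set with class-dependent source variance through a
# random mixing matrix (for CSP property checks).
random_trial_set <- function(n_per_class = 20, n_ch = 6, n_time = 100,
                             fs = 100) {
  A <- matrix(rnorm(n_ch * n_ch), n_ch)
  labels <- rep(c("L", "R"), each = n_per_class)
  scales <- matrix(1, 2, n_ch)
  scales[1, 1] <- 3; scales[2, 2] <- 3          # class-dependent variance
  trials <- array(0, dim = c(2 * n_per_class, n_ch, n_time))
  for (i in seq_along(labels)) {
    src <- matrix(rnorm(n_ch * n_time), n_ch) *
      scales[1 + (labels[i] == "R"), ]
    trials[i, , ] <- A %*% src
  }
  trial_set(trials, labels, fs)
}

# Standard high-SNR motor-imagery test subject: one rhythm occupying
# 10-14 Hz (center 12, width 1), clear but non-saturating amplitude.
planted_band_subject <- function(seed, amplitude = 2, depth = 0.8) {
  subject_spec(data.frame(center = 12, width = 1.0, amplitude = amplitude),
               noise = c(0.5, 15, 1.2), depth = depth, seed = seed)
}

# Minimal 16-bit EDF writer (test fixture only): one data record per second.
write_edf_fixture <- function(path, data_digital, labels, fs,
                              phys_min, phys_max, dig_min = -32768,
                              dig_max = 32767) {
  ns <- nrow(data_digital)
  n <- ncol(data_digital)
  stopifnot(n %% fs == 0)
  n_records <- n / fs
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeChar(substr(s, 1, w), con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test rec", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (1 + ns), 8); pad("", 44); pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in 1:ns) pad("", 80)            # transducer
  for (i in 1:ns) pad("uV", 8)
  for (v in phys_min) pad(format(v, nsmall = 1), 8)
  for (v in phys_max) pad(format(v, nsmall = 1), 8)
  for (v in rep(dig_min, ns)) pad(v, 8)
  for (v in rep(dig_max, ns)) pad(v, 8)
  for (i in 1:ns) pad("", 80)            # prefiltering
  for (i in 1:ns) pad(fs, 8)             # samples per record
  for (i in 1:ns) pad("", 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- data_digital[s, ((r - 1) * fs + 1):(r * fs)]
      writeBin(as.integer(seg), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# Analytic 1/f-plus-peak spectrum on a grid.
floor_psd <- function(f, k1, k2, lambda) k1 + k2 / f^lambda

# Run code under a temporary seed without clobbering the session RNG.
with_seed_local <- function(seed, code) bssfor:::with_seed(seed, code)
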