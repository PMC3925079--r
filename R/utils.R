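# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Snap values to a step grid anchored at `origin`.
snap_to_grid <- function(x, step = 0.5, origin = 0) {
  origin + round((x - origin) / step) * step
}

# Reflect values into [lo, hi].
reflect <- function(x, lo, hi) {
  span <- 2 * (hi - lo)
  y <- (x - lo) %% span
  y <- ifelse(y > (hi - lo), span - y, y)
  y + lo
}
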