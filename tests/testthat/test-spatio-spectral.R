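test_that("band-pass preserves in-band tones and rejects out-of-band tones", {
  fs <- 100; n <- 400
  t <- (0:(n - 1)) / fs
  mk <- function(f0) {
    x <- array(0, dim = c(1, 1, n)); x[1, 1, ] <- sin(2 * pi * f0 * t)
    trial_set(x, "L", fs)
  }
  rms <- function(ts) sqrt(mean(ts$trials^2))
  keep <- bandpass(mk(10), band(8, 12))
  expect_equal(rms(keep), 1 / sqrt(2), tolerance = 0.05)
  stop <- bandpass(mk(25), band(8, 12))
  expect_lt(rms(stop), 0.05 * (1 / sqrt(2)))
  expect_error(bandpass(mk(10), band(8, 60)), "Nyquist")
})

test_that("band-pass is idempotent up to roll-off", {
  set.seed(21)
  x <- array(rnorm(2 * 3 * 1000), dim = c(2, 3, 1000))
  ts <- trial_set(x, c("L", "R"), 100)
  once <- bandpass(ts, band(8, 12))
  twice <- bandpass(once, band(8, 12))
  # pass-band content: power inside [8.5, 11.5] where |H|^2 ~ 1
  inband_power <- function(tset) {
    p <- welch_psd(as.numeric(tset$trials[1, 1, ]), 100, nperseg = 200,
                   grid = seq(8.5, 11.5, 0.5))
    sum(p$psd)
  }
  p1 <- inband_power(once); p2 <- inband_power(twice)
  expect_lt(abs(sqrt(p2) - sqrt(p1)) / sqrt(p1), 0.02)
})

test_that("CSP solves the two-channel problem in closed form", {
  # class covariances diag(4,1) and diag(1,4): eigenvalues 0.8 and 0.2
  set.seed(33)
  n <- 4000
  trials <- array(0, dim = c(40, 2, n / 10))
  labels <- rep(c("A", "B"), each = 20)
  for (i in 1:40) {
    sd <- if (labels[i] == "A") c(2, 1) else c(1, 2)
    trials[i, , ] <- rbind(rnorm(n / 10, 0, sd[1]), rnorm(n / 10, 0, sd[2]))
  }
  flt <- csp_fit(trial_set(trials, labels, 100), m = 1L)
  expect_equal(flt$eigenvalues, c(0.8, 0.2), tolerance = 0.03)
  # axis-aligned filters: each column dominated by one channel
  dominant <- apply(abs(flt$W), 2, which.max)
  expect_setequal(dominant, c(1, 2))
})

test_that("CSP whitens the composite covariance and label swap flips eigenvalues", {
  set.seed(44)
  for (rep in 1:5) {
    ts <- random_trial_set()
    flt <- csp_fit(ts, m = 2L)
    covs <- bssfor:::trial_covariances(ts)
    S <- bssfor:::class_covariances(covs, ts$labels)
    I_hat <- t(flt$W) %*% (S[[1]] + S[[2]]) %*% flt$W
    expect_lt(max(abs(I_hat - diag(ncol(flt$W)))), 1e-8)
    swapped <- trial_set(ts$trials, chartr("LR", "RL", ts$labels), ts$fs)
    flt2 <- csp_fit(swapped, m = 2L)
    expect_equal(sort(flt2$eigenvalues), sort(1 - flt$eigenvalues),
                 tolerance = 1e-8)
  }
})

test_that("log-variance features follow the closed forms and scaling law", {
  set.seed(55)
  n_time <- 5000
  x <- array(rnorm(2 * 2 * n_time), dim = c(2, 2, n_time))
  ts <- trial_set(x, c("L", "R"), 100)
  W <- structure(list(W = diag(2), eigenvalues = c(0.5, 0.5), m = 1L),
                 class = "spatial_filter_set")
  f1 <- logvar_features(ts, W)
  expect_equal(f1, matrix(0, 2, 2), tolerance = 0.1, ignore_attr = TRUE)
  ts4 <- trial_set(2 * x, c("L", "R"), 100)
  f4 <- logvar_features(ts4, W)
  expect_equal(f4 - f1, matrix(log(4), 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("LDA separates well-separated clouds and breaks ties to the first label", {
  set.seed(66)
  X <- rbind(matrix(rnorm(100, 10), 50, 2), matrix(rnorm(100, -10), 50, 2))
  y <- rep(c("R", "L"), each = 50)
  model <- lda_fit(X, y)
  expect_equal(mean(lda_predict(model, X) == y), 1.0)
  mid <- (colMeans(X[1:50, ]) + colMeans(X[51:100, ])) / 2
  expect_equal(lda_score(model, rbind(mid)), 0, tolerance = 1e-10)
  expect_equal(lda_predict(model, rbind(mid)), "L")  # first sorted label
})

test_that("hand-rolled LDA matches MASS::lda on balanced data", {
  skip_if_not_installed("MASS")
  set.seed(77)
  X <- rbind(matrix(rnorm(200, 0.8), 100, 2), matrix(rnorm(200, 0), 100, 2))
  y <- rep(c("A", "B"), each = 100)
  ours <- lda_predict(lda_fit(X, y), X)
  ref <- as.character(predict(MASS::lda(X, y))$class)
  expect_gt(mean(ours == ref), 0.99)
})

test_that("label-permuted data cross-validates at chance", {
  set.seed(88)
  X <- matrix(rnorm(400 * 4), 400, 4)
  y <- sample(rep(c("L", "R"), 200))
  splits <- chrono_cv_split(400, 8)
  errs <- vapply(splits, function(sp) {
    m <- lda_fit(X[sp$train, ], y[sp$train])
    mean(lda_predict(m, X[sp$test, ]) != y[sp$test])
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.08)
})

test_that("chronological folds are contiguous with remainder to the earliest blocks", {
  sp <- chrono_cv_split(150, 8)
  sizes <- vapply(sp, function(s) length(s$test), integer(1))
  expect_equal(sizes, c(19L, 19L, 19L, 19L, 19L, 19L, 18L, 18L))
  expect_equal(sort(unlist(lapply(sp, `[[`, "test"))), 1:150)
  for (s in sp) {
    expect_equal(s$test, min(s$test):max(s$test))    # contiguous
    expect_setequal(c(s$train, s$test), 1:150)
  }
  expect_error(chrono_cv_split(150, 1), "k >= 2")
  expect_error(chrono_cv_split(5, 6), "exceeds")
})

test_that("fixed-band pipeline nails the planted rhythm and is at chance off-band", {
  sp <- planted_band_subject(seed = 101, amplitude = 3)
  ts <- gen_motor_imagery(sp, n_per_class = 40)
  expect_lt(fixed_band_pipeline(ts, band(10, 14)), 0.05)
  # no class information at all: ERD depth 0
  sp0 <- planted_band_subject(seed = 102, depth = 0)
  ts0 <- gen_motor_imagery(sp0, n_per_class = 40)
  err0 <- fixed_band_pipeline(ts0, band(16, 22))
  expect_lt(abs(err0 - 0.5), 0.12)
})

test_that("heuristic band expansion stops at 5% of the peak score", {
  grid <- seq(5, 35, 0.5)
  # triangular profile peaking at 12 Hz, exactly 5% of max at 8 and 16 Hz
  score <- pmax(0, 1 - 0.95 * abs(grid - 12) / 4)
  score[grid < 8 | grid > 16] <- 0
  score[grid %in% c(8, 16)] <- 0.05    # exact boundary value
  bd <- bssfor:::expand_band_from_scores(grid, score)
  expect_equal(c(bd$b_s, bd$b_e), c(8.5, 15.5))
  # single nonzero score: single grid cell around it
  s2 <- numeric(length(grid)); s2[grid == 11] <- 1
  bd2 <- bssfor:::expand_band_from_scores(grid, s2)
  expect_equal(c(bd2$b_s, bd2$b_e), c(10.75, 11.25))
  expect_warning(bd3 <- bssfor:::expand_band_from_scores(grid, numeric(length(grid))),
                 "zero")
  expect_equal(c(bd3$b_s, bd3$b_e), c(8, 12))
})

test_that("heuristic band finds the planted rhythm's frequency", {
  sp <- planted_band_subject(seed = 103, amplitude = 3)
  ts <- gen_motor_imagery(sp, n_per_class = 40)
  bd <- heuristic_band(ts)
  expect_lte(bd$b_s, 10)
  expect_gte(bd$b_e, 14)
})
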