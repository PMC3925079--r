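test_that("prior particles cover the valid band grid uniformly", {
  ps1 <- sample_prior(1, seed = 1)
  expect_equal(ps1$weights, 1)
  expect_s3_class(ps1, "particle_set")

  ps <- sample_prior(1e4, f_min = 4, f_max = 40, min_bandwidth = 2, seed = 2)
  expect_equal(sum(ps$weights), 1, tolerance = 1e-9)
  expect_true(all(ps$particles[, 2] - ps$particles[, 1] >= 2))
  expect_true(all(ps$particles >= 4 & ps$particles <= 40))
  # fraction with b_s in [4, 22) matches exact enumeration of valid cells
  cells <- bssfor:::valid_band_grid(4, 40, 0.5, 2)
  expected <- mean(cells[, 1] < 22)
  observed <- mean(ps$particles[, 1] < 22)
  expect_lt(abs(observed - expected), 0.02)
})

test_that("particle accumulation into the 2-D density keeps the mass budget", {
  ps <- particle_set(rbind(c(8, 12)), weights = 1)
  p2 <- pdf2d_from_particles(ps)
  si <- which(p2$start_grid == 8); ei <- which(p2$end_grid == 12)
  expect_equal(p2$mass[si, ei], 1)
  expect_equal(sum(p2$mass), 1)

  ps2 <- particle_set(rbind(c(8, 12), c(20, 30)), weights = c(0.5, 0.5))
  p22 <- pdf2d_from_particles(ps2)
  expect_equal(sort(p22$mass[p22$mass > 0]), c(0.5, 0.5))
})

test_that("large uniform particle clouds approach the uniform cell density", {
  ps <- sample_prior(1e5, seed = 3)
  p2 <- pdf2d_from_particles(ps)
  cells <- bssfor:::valid_band_grid(4, 40, 0.5, 2)
  n_cells <- nrow(cells)
  expected <- 1 / n_cells
  se <- sqrt(expected * (1 - expected) / 1e5)
  # restrict to cells the prior can reach (bandwidth >= 2)
  reach <- outer(p2$start_grid, p2$end_grid, function(s, e) e - s >= 2)
  frac_ok <- mean(abs(p2$mass[reach] - expected) <= 3 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("uniform-subtracted 1-D density matches the brute-force double loop", {
  set.seed(10)
  start_grid <- seq(4, 39.5, 0.5); end_grid <- seq(4.5, 40, 0.5)
  valid <- outer(start_grid, end_grid, `<`)
  for (rep in 1:5) {
    mass <- matrix(0, length(start_grid), length(end_grid))
    idx <- which(valid)
    pick <- sample(idx, 12)
    mass[pick] <- rexp(12); mass <- mass / sum(mass)
    p1 <- pdf_1d(pdf2d(start_grid, end_grid, mass))
    probe <- sample(p1$grid, 10)
    for (f in probe)
      expect_lt(abs(p1$values[p1$grid == f] -
                    oracle_pdf1d(start_grid, end_grid, mass, f)), 1e-12)
  }
  # uniform 2-D density collapses to the all-zero vector
  u <- valid * 1
  p1u <- pdf_1d(pdf2d(start_grid, end_grid, u))
  expect_true(all(abs(p1u$values) < 1e-12))
})

test_that("frequencies outside every massed band get non-positive density", {
  start_grid <- seq(4, 39.5, 0.5); end_grid <- seq(4.5, 40, 0.5)
  mass <- matrix(0, length(start_grid), length(end_grid))
  mass[which(start_grid == 8), which(end_grid == 12)] <- 1
  p1 <- pdf_1d(pdf2d(start_grid, end_grid, mass))
  expect_lte(max(p1$values[p1$grid > 12.5]), 0)
  expect_lte(max(p1$values[p1$grid < 7.5]), 0)
  expect_gt(p1$values[p1$grid == 10], 0)
})

test_that("the Gaussian frequency weight follows its closed form", {
  mix1 <- data.frame(alpha = 1, mu = 10, sigma = 2)
  expect_equal(frequency_weight(10, mix1), 1 / (2 * sqrt(2 * pi)))
  peak <- frequency_weight(10, mix1)
  expect_equal(frequency_weight(c(8, 12), mix1),
               rep(exp(-0.5) * peak, 2))
  expect_equal(frequency_weight(c(3, 7, 30), NULL), rep(1, 3))
  expect_equal(default_mixture()$mu, c(10, 19))
})

test_that("AUC integrates the positive part and survives grid refinement", {
  expect_equal(auc_of_pdf(pdf1d(seq(4, 40, 0.5), rep(0, 73))), 0)
  grid <- seq(4, 40, 0.5)
  # half-open indicator of a 4 Hz band: trapezoid area exactly 4
  vals <- as.numeric(grid >= 8 & grid < 12)
  expect_equal(auc_of_pdf(pdf1d(grid, vals)), 4.0)
  # piecewise-linear density: refinement must not change the area
  coarse <- pdf1d(seq(0, 10, 1), pmax(0, 5 - abs(seq(0, 10, 1) - 5)) - 1)
  fine_grid <- seq(0, 10, 0.1)
  fine <- pdf1d(fine_grid, approx(coarse$grid, coarse$values, fine_grid)$y)
  expect_equal(auc_of_pdf(coarse), auc_of_pdf(fine), tolerance = 1e-6)
})

test_that("band likelihood is high inside the planted rhythm and at chance outside", {
  sp <- planted_band_subject(seed = 200, amplitude = 3)
  ts <- gen_motor_imagery(sp, n_per_class = 75)
  expect_gte(particle_likelihood(band(10, 14), ts), 0.9)
  null_lik <- particle_likelihood(band(25, 35), ts)
  expect_lt(abs(null_lik - 0.5), 0.12)
  ts_const <- trial_set(ts$trials, rep("L", 150), ts$fs)
  expect_error(particle_likelihood(band(10, 14), ts_const), "two classes")
})

test_that("spectral-cache covariances equal explicit band-pass covariances", {
  sp <- planted_band_subject(seed = 201)
  ts <- gen_motor_imagery(sp, n_per_class = 10)
  cache <- bssfor:::spectral_cache(ts)
  for (b in list(band(8, 12), band(16, 22), band(5, 30))) {
    c_fast <- bssfor:::cache_band_covariances(cache, b)
    c_slow <- bssfor:::trial_covariances(bandpass(ts, b))
    dev <- max(vapply(seq_along(c_fast), function(i)
      max(abs(c_fast[[i]] - c_slow[[i]])), numeric(1)))
    expect_lt(dev / max(abs(c_slow[[1]])), 1e-10)
  }
})

test_that("a single-particle fit returns that particle with weight one", {
  sp <- planted_band_subject(seed = 202)
  ts <- gen_motor_imagery(sp, n_per_class = 10)
  m <- suppressWarnings(
    bssfo_fit(ts, bssfo_config(n_particles = 1L, max_iter = 2L, seed = 9)))
  expect_equal(nrow(m$posterior$particles), 1L)
  expect_equal(m$posterior$weights, 1)
})

test_that("constant likelihood leaves the prior untouched in distribution", {
  # with every band equally likely, resampling and perturbation must not
  # concentrate the particle cloud: the posterior stays the uniform prior
  testthat::local_mocked_bindings(
    particle_likelihood = function(...) 0.5, .package = "bssfor")
  sp <- planted_band_subject(seed = 204)
  ts <- gen_motor_imagery(sp, n_per_class = 5)
  m <- suppressWarnings(
    bssfo_fit(ts, bssfo_config(n_particles = 1e4L, max_iter = 3L, seed = 31)))
  expect_true(m$chance_flag)
  expect_equal(m$posterior$weights, rep(1e-4, 1e4))
  cells <- bssfor:::valid_band_grid(4, 40, 0.5, 2)
  ref <- rowMeans(cells[with_seed_local(99,
    sample.int(nrow(cells), 1e4, replace = TRUE)), ])
  centers <- rowMeans(m$posterior$particles)
  ks <- suppressWarnings(stats::ks.test(centers, ref)$statistic)
  expect_lt(as.numeric(ks), 0.05)
})

test_that("ensemble prediction follows the weighted majority of particle votes", {
  sp <- planted_band_subject(seed = 203, amplitude = 3)
  ts <- gen_motor_imagery(sp, n_per_class = 20)
  m <- bssfo_fit(ts, bssfo_config(n_particles = 10L, max_iter = 2L, seed = 17))
  # unanimity: force both classifiers to the same prediction by construction
  pred <- bssfo_predict(m, ts)
  expect_true(all(pred %in% c("L", "R")))
  # hand-built two-particle model with weights 0.7 / 0.3 that disagree
  clf <- m$classifiers[[1]]
  mk <- function(w, flip) {
    c2 <- clf
    c2$weight <- w
    if (flip) c2$lda$classes <- rev(c2$lda$classes)
    c2
  }
  m2 <- m
  m2$classifiers <- list(mk(0.7, FALSE), mk(0.3, TRUE))
  p_major <- bssfo_predict(m2, ts)
  p_one <- bssfo_predict(`[[<-`(m2, "classifiers", list(mk(1, FALSE))), ts)
  expect_equal(p_major, p_one)
})
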