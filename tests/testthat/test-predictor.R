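# Small synthetic cohorts for predictor tests: built from analytic spectra so
# they are fast and fully controlled.
make_spectrum <- function(peak_f, peak_h, seed, grid = rest_grid(),
                          k1 = 0.5, k2 = 12, lambda = 1.1) {
  base <- floor_psd(grid, k1, k2, lambda)
  psd <- base + peak_h * exp(-(grid - peak_f)^2 / (2 * 1.2^2))
  profs <- list(spectral_profile(psd, grid, "C3"))
  L <- band_likelihood(profs)
  p2 <- normalize_pdf2d(L)
  p1 <- pdf1d_rest(p2)
  eta <- subject_weight(profs)
  structure(list(profiles = profs, likelihood = L, pdf2d = p2, pdf1d = p1,
                 eta = eta, xi = weighted_subject_pdf(p1, eta), grid = grid),
            class = "subject_spectrum")
}

test_that("feature building augments, z-scores and reduces dimension", {
  s1 <- make_spectrum(10, 3, 1)
  s2 <- make_spectrum(10, 3, 2)
  feats <- build_features(list(s1, s2, make_spectrum(19, 2, 3)))
  expect_equal(ncol(feats$augmented), length(rest_grid()) + 2L)
  # identical subjects get identical reduced vectors
  expect_equal(feats$reduced[1, ], feats$reduced[2, ], tolerance = 1e-9)
  # the two scalar features occupy the last two slots
  expect_equal(feats$augmented[1, length(rest_grid()) + 1L],
               auc_of_pdf(s1$xi))
  expect_equal(feats$augmented[1, length(rest_grid()) + 2L], s1$eta)
})

test_that("rank-one cohort variation keeps a single principal component", {
  base <- make_spectrum(10, 2, 1)
  cohort <- lapply(c(1, 2, 3, 4), function(h) {
    s <- base
    s$xi$values <- base$xi$values * h
    s$eta <- base$eta * h
    s
  })
  feats <- build_features(cohort)
  expect_equal(feats$k, 1L)
})

test_that("Ward clustering matches the exhaustive greedy oracle on small instances", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n)
    cl <- ward_cluster(X, K = 2)
    expect_equal(hclust_merge_sets(cl$tree), oracle_ward_merges(X))
  }
})

test_that("Ward clustering separates two tight groups and K = n is singletons", {
  set.seed(8)
  X <- rbind(matrix(rnorm(9, 0, 0.01), 3), matrix(rnorm(9, 10, 0.01), 3))
  cl <- ward_cluster(X, K = 2)
  expect_equal(length(unique(cl$labels[1:3])), 1L)
  expect_equal(length(unique(cl$labels[4:6])), 1L)
  expect_false(cl$labels[1] == cl$labels[4])
  # brute-force: best 2-partition by total within-cluster SSE
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^6 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(g) || all(g)) next
    sse <- 0
    for (part in list(X[g, , drop = FALSE], X[!g, , drop = FALSE]))
      sse <- sse + sum(scale(part, scale = FALSE)^2)
    if (sse < best_sse) { best_sse <- sse; best <- g }
  }
  expect_true(all(best[1:3] == best[1]) && all(best[4:6] == best[4]) &&
              best[1] != best[4])

  cln <- ward_cluster(X, K = 6)
  expect_equal(sort(unique(cln$labels)), 1:6)
  expect_equal(cln$centers[cln$labels, ], X, ignore_attr = TRUE)
  expect_error(ward_cluster(X, K = 7), "exceeds")
})

test_that("distance vectors are Euclidean and permutation-equivariant", {
  centers <- rbind(c(0, 0), c(3, 4))
  expect_equal(distance_vector(c(0, 0), centers), c(0, 5))
  expect_equal(distance_vector(c(3, 4), centers), c(5, 0))
  expect_equal(distance_vector(c(0, 0), centers[2:1, ]), c(5, 0))
})

test_that("regression recovers exact and noisy weights", {
  set.seed(9)
  D <- matrix(abs(rnorm(100 * 5)), 100, 5)
  w_star <- c(0.3, -0.2, 0.1, 0.05, -0.15)
  acc <- as.numeric(D %*% w_star) + 0.7
  fit <- fit_regression(D, acc)
  expect_lt(max(abs(fit$w - w_star)), 1e-10)
  expect_equal(fit$eps, 0.7, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  acc_n <- acc + rnorm(100, 0, 0.02)
  fit_n <- fit_regression(D, acc_n)
  expect_lt(sqrt(sum((fit_n$w - w_star)^2)) / sqrt(sum(w_star^2)), 0.15)

  fit_c <- fit_regression(D, rep(0.8, 100))
  expect_lt(max(abs(fit_c$w)), 1e-10)
  expect_equal(fit_c$eps, 0.8, tolerance = 1e-10)
})

test_that("prediction reproduces training subjects in a zero-residual model", {
  cohort <- c(lapply(1:4, function(i) make_spectrum(10, 1 + i, i)),
              lapply(1:4, function(i) make_spectrum(19, 0.5 + i / 2, 4 + i)),
              lapply(1:4, function(i) make_spectrum(14, 0.2, 8 + i)))
  feats <- build_features(cohort)
  model0 <- train_predictor(cohort, acc = rep(0.7, 12), K = 2)
  # constant target: prediction is that constant everywhere
  expect_equal(predict_performance(model0, cohort[[5]]), 0.7,
               tolerance = 1e-8)
  # exactly linear target in the distance design: residuals vanish and each
  # training subject is reproduced
  D <- t(apply(feats$reduced, 1, distance_vector,
               centers = ward_cluster(feats$reduced, 3)$centers))
  acc_lin <- as.numeric(D %*% c(0.1, -0.05, 0.02)) + 0.6
  model <- train_predictor(cohort, acc_lin, K = 3)
  expect_lt(max(abs(model$residuals)), 1e-8)
  for (i in c(1, 6, 11))
    expect_equal(predict_performance(model, cohort[[i]]), acc_lin[i],
                 tolerance = 1e-6)
  # order invariance
  perm <- c(7, 2, 11, 4, 1, 12, 3, 9, 5, 10, 8, 6)
  model_p <- train_predictor(cohort[perm], acc_lin[perm], K = 3)
  expect_equal(predict_performance(model_p, cohort[[1]]),
               predict_performance(model, cohort[[1]]), tolerance = 1e-6)
})

test_that("leave-one-out never sees the held-out subject", {
  cohort <- c(lapply(1:5, function(i) make_spectrum(9 + i / 2, 2 + i / 3, i)),
              lapply(1:5, function(i) make_spectrum(18 + i / 2, 1 + i / 3, 5 + i)))
  acc <- seq(0.5, 0.95, length.out = 10)
  model_wo_1 <- train_predictor(cohort[-1], acc[-1], K = 2)
  # perturbing the held-out subject must leave the trained model untouched
  cohort2 <- cohort
  cohort2[[1]] <- make_spectrum(12, 9, 99)
  model_wo_1b <- train_predictor(cohort2[-1], acc[-1], K = 2)
  expect_identical(model_wo_1$w, model_wo_1b$w)
  expect_identical(model_wo_1$centers, model_wo_1b$centers)
  p <- loo_predict(cohort, acc, K = 2)
  expect_length(p, 10)
  expect_equal(p[1], predict_performance(model_wo_1, cohort[[1]]))
})

test_that("the cluster-count sweep flags undefined correlations", {
  cohort <- lapply(1:8, function(i) make_spectrum(8 + i, 1 + i / 4, i))
  res <- suppressWarnings(
    sweep_cluster_count(cohort, rep(0.7, 8), K_range = 1:3))
  expect_equal(res$r, rep(0, 3))
  expect_error(sweep_cluster_count(cohort, rep(0.7, 8), K_range = 1:8),
               "K_range")
})

test_that("pearson matches closed forms and the null band", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(12)
  expect_lt(abs(pearson(rnorm(1e4), rnorm(1e4))), 0.03)
  expect_warning(r0 <- pearson(x, rep(1, 5)), "zero variance")
  expect_equal(as.numeric(r0), 0)
})
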