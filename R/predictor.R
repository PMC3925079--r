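#' Assemble and reduce cohort feature vectors
#'
#' Each subject contributes the augmented vector [Xi grid values, area under
#' Xi, subject weight eta]. Columns are z-scored across the cohort (so the
#' two scalar summaries are not swamped by the grid values) and reduced by
#' principal component analysis, retaining enough components to explain the
#' requested variance fraction (capped at n - 1).
#'
#' @param cohort list of \code{subject_spectrum}s on identical grids.
#' @param var_explained variance fraction to retain (default 0.95).
#' @return An object of class \code{subject_features}: \code{augmented}
#'   (n x p), \code{reduced} (n x k), scaling and rotation needed to project
#'   new subjects.
#' @export
build_features <- function(cohort, var_explained = 0.95) {
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  grid <- cohort[[1]]$grid
  for (s in cohort)
    if (!isTRUE(all.equal(s$grid, grid))) stop("cohort grids differ")
  aug <- t(vapply(cohort, augment_subject, numeric(length(grid) + 2L)))
  mu <- colMeans(aug)
  sd <- apply(aug, 2L, stats::sd)
  sd[sd == 0] <- 1
  Z <- sweep(sweep(aug, 2L, mu), 2L, sd, `/`)
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- min(which(cum >= var_explained - 1e-12), length(cohort) - 1L)
  structure(list(augmented = aug, reduced = pca$x[, seq_len(k), drop = FALSE],
                 center = mu, scale = sd,
                 rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 k = k, grid = grid),
            class = "subject_features")
}

# Augmented feature vector of one subject: Xi values, AUC of Xi, eta.
augment_subject <- function(spectrum) {
  c(spectrum$xi$values, auc_of_pdf(spectrum$xi), spectrum$eta)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under the Ward criterion (each merge minimizes
#' the increase in total within-cluster squared Euclidean distance), cut at
#' \code{K} clusters.
#'
#' @param vectors numeric matrix, one row per subject.
#' @param K number of clusters (default 5).
#' @return list with \code{labels}, \code{centers} (K x dim, member means),
#'   and the \code{hclust} \code{tree}.
#' @export
ward_cluster <- function(vectors, K = 5L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (K > n) stop("K = ", K, " exceeds number of points ", n)
  tree <- stats::hclust(stats::dist(vectors), method = "ward.D2")
  labels <- stats::cutree(tree, k = K)
  centers <- rowsum(vectors, labels) / as.vector(table(labels))
  list(labels = labels, centers = centers, tree = tree)
}

#' Distances from a point to the cluster centers
#'
#' @param v numeric vector in the reduced feature space.
#' @param centers K x dim matrix of cluster centers.
#' @return numeric length-K vector of Euclidean distances.
#' @export
distance_vector <- function(v, centers) {
  centers <- as.matrix(centers)
  if (length(v) != ncol(centers)) stop("dimension mismatch")
  sqrt(colSums((t(centers) - v)^2))
}

#' Ordinary least squares of performance on cluster distances
#'
#' @param D n x K matrix of cluster-distance vectors.
#' @param acc n performance values.
#' @return list with \code{w} (length K), \code{eps} (intercept),
#'   \code{fitted}, \code{residuals}. Rank-deficient designs fall back to
#'   the minimum-norm solution with a warning.
#' @export
fit_regression <- function(D, acc) {
  D <- as.matrix(D)
  if (nrow(D) != length(acc)) stop("row count of D must match length of acc")
  if (nrow(D) <= ncol(D)) stop("need more subjects than clusters")
  X <- cbind(1, D)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient distance design; minimum-norm solution used")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], acc)) / sv$d[pos])
  } else {
    beta <- qr.coef(qrX, acc)
  }
  beta <- as.numeric(beta)
  fitted <- as.numeric(X %*% beta)
  list(w = beta[-1], eps = beta[1], fitted = fitted,
       residuals = acc - fitted)
}

#' Train the resting-state performance predictor
#'
#' Builds PCA-reduced augmented features for the cohort, Ward-clusters them
#' into \code{K} groups, forms each subject's vector of distances to the
#' cluster centers, and regresses the known BCI performances on those
#' distances.
#'
#' @param cohort list of \code{subject_spectrum}s.
#' @param acc known performance (accuracy in [0, 1]) per subject.
#' @param K number of clusters (default 5).
#' @param var_explained PCA variance fraction (default 0.95).
#' @return A \code{predictor_model}.
#' @export
train_predictor <- function(cohort, acc, K = 5L, var_explained = 0.95) {
  if (length(cohort) != length(acc)) stop("cohort/acc length mismatch")
  feats <- build_features(cohort, var_explained)
  cl <- ward_cluster(feats$reduced, K)
  D <- t(apply(feats$reduced, 1L, distance_vector, centers = cl$centers))
  if (K == 1L) D <- matrix(D, ncol = 1L)
  reg <- fit_regression(D, acc)
  structure(list(features = feats, centers = cl$centers,
                 labels = cl$labels, w = reg$w, eps = reg$eps,
                 residuals = reg$residuals, K = K, grid = feats$grid),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf(
    "<predictor_model> %d subjects, K = %d clusters, %d principal components; training RMSE %.3f\n",
    nrow(x$features$reduced), x$K, x$features$k,
    sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Predict BCI performance for a new subject
#'
#' Augments the subject's resting spectrum, applies the stored z-scoring and
#' PCA projection, computes the distances to the training cluster centers,
#' and evaluates the linear model.
#'
#' @param model a \code{predictor_model}.
#' @param spectrum a \code{subject_spectrum} on the training grid.
#' @return predicted accuracy (scalar).
#' @export
predict_performance <- function(model, spectrum) {
  stopifnot(inherits(model, "predictor_model"),
            inherits(spectrum, "subject_spectrum"))
  if (!isTRUE(all.equal(spectrum$grid, model$grid)))
    stop("spectrum grid differs from the training grid")
  a <- augment_subject(spectrum)
  z <- (a - model$features$center) / model$features$scale
  v <- as.numeric(z %*% model$features$rotation)
  d <- distance_vector(v, model$centers)
  sum(d * model$w) + model$eps
}

#' Leave-one-out predictions of the cluster-distance predictor
#'
#' For each subject the whole pipeline (z-scoring, PCA, clustering,
#' regression) is refit without that subject before predicting it.
#'
#' @param cohort list of \code{subject_spectrum}s.
#' @param acc performance per subject.
#' @param K number of clusters.
#' @param var_explained PCA variance fraction.
#' @return numeric vector of held-out predictions.
#' @export
loo_predict <- function(cohort, acc, K = 5L, var_explained = 0.95) {
  vapply(seq_along(cohort), function(i) {
    model <- train_predictor(cohort[-i], acc[-i], K, var_explained)
    predict_performance(model, cohort[[i]])
  }, numeric(1))
}

#' Correlation of leave-one-out predictions across cluster counts
#'
#' @param cohort list of \code{subject_spectrum}s.
#' @param acc performance per subject.
#' @param K_range cluster counts to evaluate (default 1:20).
#' @param var_explained PCA variance fraction.
#' @return data frame with columns \code{K} and \code{r} (Pearson correlation
#'   of held-out predictions with \code{acc}; 0 with a warning when the
#'   correlation is undefined).
#' @export
sweep_cluster_count <- function(cohort, acc, K_range = 1:20,
                                var_explained = 0.95) {
  n <- length(cohort)
  if (any(K_range < 1L) || any(K_range > n - 1L))
    stop("K_range must lie within [1, n - 1]")
  r <- vapply(K_range, function(K) {
    pred <- loo_predict(cohort, acc, K, var_explained)
    as.numeric(pearson(pred, acc))
  }, numeric(1))
  data.frame(K = K_range, r = r)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return sample correlation; 0 with a warning (and attribute
#'   \code{undefined = TRUE}) when either variance is zero.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined, reported as 0")
    return(structure(0, undefined = TRUE))
  }
  stats::cor(x, y)
}
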