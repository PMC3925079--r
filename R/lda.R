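#' Fit a two-class linear discriminant
#'
#' Fisher discriminant with pooled within-class covariance and equal priors.
#' A singular pooled covariance is shrunk toward the scaled identity. At a
#' decision score of exactly zero the tie is broken to the first label in
#' sorted order.
#'
#' @param features numeric matrix, observations in rows.
#' @param labels class label per row (exactly two distinct values).
#' @return An \code{lda_model} with fields \code{w}, \code{b}, \code{classes}.
#' @export
lda_fit <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("lda_fit needs exactly two classes")
  X1 <- features[labels == cls[1], , drop = FALSE]
  X2 <- features[labels == cls[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  pool <- function(X) if (nrow(X) > 1) stats::cov(X) * (nrow(X) - 1) else
    matrix(0, ncol(X), ncol(X))
  Sp <- (pool(X1) + pool(X2)) / max(n1 + n2 - 2, 1)
  ev <- eigen(Sp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10 || max(ev) == 0) Sp <- shrink_cov(Sp)
  w <- solve(Sp, mu1 - mu2)
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = as.numeric(w), b = b, classes = cls), class = "lda_model")
}

#' Predict class labels with a fitted discriminant
#'
#' @param model an \code{lda_model}.
#' @param features numeric matrix with the training feature dimension.
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$w))
    stop("feature dimension ", ncol(features), " != model dimension ",
         length(model$w))
  score <- as.numeric(features %*% model$w) + model$b
  ifelse(score >= 0, model$classes[1], model$classes[2])
}

#' Decision scores (positive favors the first sorted class)
#' @param model an \code{lda_model}.
#' @param features numeric matrix.
#' @return numeric scores.
#' @export
lda_score <- function(model, features) {
  as.numeric(as.matrix(features) %*% model$w) + model$b
}
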