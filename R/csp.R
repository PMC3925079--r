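# Shrink a covariance toward the scaled identity until well conditioned.
shrink_cov <- function(S, kappa_max = 1e10) {
  d <- nrow(S)
  target <- diag(sum(diag(S)) / d, d)
  gamma <- 0
  repeat {
    Sx <- (1 - gamma) * S + gamma * target
    ev <- eigen(Sx, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < kappa_max) break
    gamma <- if (gamma == 0) 1e-6 else gamma * 10
    if (gamma >= 1) { Sx <- target; break }
  }
  if (gamma > 0)
    message("covariance ill-conditioned; shrinkage intensity ", gamma, " applied")
  Sx
}

# Per-class mean of trace-normalized per-trial covariances. covs: list of
# channel x channel matrices; returns the two class means in sorted label order.
class_covariances <- function(covs, labels) {
  cls <- sort(unique(labels))
  lapply(cls, function(cl) {
    idx <- which(labels == cl)
    Reduce(`+`, lapply(covs[idx], function(C) C / sum(diag(C)))) / length(idx)
  })
}

# Uncentered per-trial covariance matrices (channel x channel) of a trial set.
trial_covariances <- function(ts) {
  d <- dim(ts$trials)
  lapply(seq_len(d[1]), function(i) {
    X <- matrix(ts$trials[i, , ], nrow = d[2])   # ch x time
    tcrossprod(X) / d[3]
  })
}

# CSP from two class covariance matrices: solve S1 w = lambda (S1 + S2) w,
# keep the m largest- and m smallest-lambda filters, normalize so that
# W' (S1 + S2) W = I on the retained columns.
csp_from_cov <- function(S1, S2, m) {
  d <- nrow(S1)
  if (2L * m > d) stop("2m = ", 2 * m, " exceeds channel count ", d)
  Sc <- S1 + S2
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) <= max(ec$values) * 1e-12) {
    Sc <- shrink_cov(Sc)
    ec <- eigen(Sc, symmetric = TRUE)
  }
  P <- ec$vectors %*% diag(1 / sqrt(ec$values), d) %*% t(ec$vectors)
  es <- eigen(P %*% S1 %*% P, symmetric = TRUE)       # values in [0,1], descending
  sel <- c(seq_len(m), seq(d - m + 1L, d))
  W <- P %*% es$vectors[, sel, drop = FALSE]
  lam <- es$values[sel]
  ord <- order(lam, decreasing = TRUE)
  structure(list(W = W[, ord, drop = FALSE], eigenvalues = lam[ord], m = m),
            class = "spatial_filter_set")
}

#' Fit common spatial pattern filters
#'
#' Solves the generalized eigenproblem of the class-1 covariance against the
#' composite covariance; per-trial covariances are trace-normalized before
#' averaging within class so high-amplitude trials do not dominate. The
#' class whose sorted label comes first plays the role of class 1.
#'
#' @param trials a two-class \code{trial_set}.
#' @param m number of filter pairs to retain; \code{NULL} (default) picks 2,
#'   or 1 when the montage has at most 4 channels.
#' @return A \code{spatial_filter_set}: \code{W} (channel x 2m filter matrix),
#'   \code{eigenvalues} (discriminability in [0,1], descending), \code{m}.
#' @export
csp_fit <- function(trials, m = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  assert_two_classes(trials)
  covs <- trial_covariances(trials)
  S <- class_covariances(covs, trials$labels)
  csp_from_cov(S[[1]], S[[2]], default_csp_pairs(m, nrow(S[[1]])))
}

# spec'd default: 2 CSP pairs, dropping to 1 on very small montages
default_csp_pairs <- function(m, n_ch) {
  if (!is.null(m)) return(as.integer(m))
  if (n_ch <= 4L) 1L else 2L
}

#' @export
print.spatial_filter_set <- function(x, ...) {
  cat(sprintf("<spatial_filter_set> %d filters (%d pairs); eigenvalues: %s\n",
              ncol(x$W), x$m, paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' Log-variance features of spatially filtered trials
#'
#' Feature j of trial i is \code{log(var(w_j' x_i))} over time. Zero
#' variances are floored at 1e-12 with a message.
#'
#' @param trials a \code{trial_set}.
#' @param filters a \code{spatial_filter_set} whose channel dimension matches.
#' @return numeric matrix, trials in rows, 2m features in columns.
#' @export
logvar_features <- function(trials, filters) {
  stopifnot(inherits(trials, "trial_set"), inherits(filters, "spatial_filter_set"))
  d <- dim(trials$trials)
  if (nrow(filters$W) != d[2])
    stop("filter channel dimension ", nrow(filters$W),
         " does not match trials (", d[2], ")")
  out <- matrix(0, d[1], ncol(filters$W))
  for (i in seq_len(d[1])) {
    Z <- crossprod(filters$W, matrix(trials$trials[i, , ], nrow = d[2]))
    v <- apply(Z, 1L, stats::var)
    if (any(v <= 0)) {
      message("zero-variance projection floored")
      v <- pmax(v, 1e-12)
    }
    out[i, ] <- log(v)
  }
  out
}

# Same features from precomputed per-trial covariances (uncentered): the
# variance of w'x equals w' C w when the filtered signal is mean-free, which
# holds for any band excluding DC.
logvar_from_cov <- function(covs, W) {
  t(vapply(covs, function(C) log(pmax(diag(crossprod(W, C %*% W)), 1e-12)),
           numeric(ncol(W))))
}
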