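#' Export a 1-D density as tab-separated text
#'
#' @param p1 a \code{pdf1d}.
#' @param path output path; two columns, frequency and value.
#' @export
write_pdf_tsv <- function(p1, path) {
  stopifnot(inherits(p1, "pdf1d"))
  utils::write.table(data.frame(frequency = p1$grid, value = p1$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 1-D density from tab-separated text
#' @param path file written by \code{\link{write_pdf_tsv}}.
#' @return A \code{pdf1d}.
#' @export
read_pdf_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  pdf1d(d[[1]], d[[2]])
}

#' Serialize a fitted model to JSON
#'
#' Supports \code{bssfo_model} (particles, weights, per-band spatial filters
#' and discriminant coefficients, configuration snapshot) and
#' \code{predictor_model} (scaling, rotation, cluster centers, regression
#' weights).
#'
#' @param model a \code{bssfo_model} or \code{predictor_model}.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "bssfo_model")) {
    list(type = "bssfo_model",
         particles = model$posterior$particles,
         weights = model$posterior$weights,
         range = c(model$posterior$f_min, model$posterior$f_max),
         step = model$posterior$step,
         min_bandwidth = model$posterior$min_bandwidth,
         iterations = model$iterations,
         converged = model$converged,
         chance_flag = model$chance_flag,
         classes = model$classes,
         config = unclass(model$config),
         classifiers = lapply(model$classifiers, function(clf) {
           list(band = c(clf$band$b_s, clf$band$b_e),
                W = clf$filters$W, eigenvalues = clf$filters$eigenvalues,
                m = clf$filters$m, lda_w = clf$lda$w, lda_b = clf$lda$b,
                lda_classes = clf$lda$classes, weight = clf$weight)
         }))
  } else if (inherits(model, "predictor_model")) {
    list(type = "predictor_model",
         center = model$features$center, scale = model$features$scale,
         rotation = model$features$rotation, k = model$features$k,
         grid = model$grid, centers = model$centers, labels = model$labels,
         w = model$w, eps = model$eps, K = model$K)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved with \code{\link{save_model}}
#'
#' @param path JSON file path.
#' @return The reconstructed \code{bssfo_model} or \code{predictor_model}.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))   # rowmajor nested lists
  if (identical(obj$type, "bssfo_model")) {
    cfg_raw <- obj$config[!vapply(obj$config, function(x)
      is.null(x) || (is.list(x) && !length(x)), logical(1))]
    cfg <- do.call(bssfo_config, cfg_raw)
    ps <- particle_set(mat(obj$particles), num(obj$weights),
                       num(obj$range)[1], num(obj$range)[2], num(obj$step),
                       num(obj$min_bandwidth), as.integer(obj$iterations))
    classifiers <- lapply(obj$classifiers, function(c0) {
      list(band = band(num(c0$band)[1], num(c0$band)[2]),
           filters = structure(list(W = mat(c0$W),
                                    eigenvalues = num(c0$eigenvalues),
                                    m = as.integer(c0$m)),
                               class = "spatial_filter_set"),
           lda = structure(list(w = num(c0$lda_w), b = num(c0$lda_b),
                                classes = unlist(c0$lda_classes)),
                           class = "lda_model"),
           weight = num(c0$weight))
    })
    structure(list(posterior = ps, classifiers = classifiers, config = cfg,
                   converged = isTRUE(obj$converged),
                   iterations = as.integer(obj$iterations),
                   chance_flag = isTRUE(obj$chance_flag),
                   classes = unlist(obj$classes)),
              class = "bssfo_model")
  } else if (identical(obj$type, "predictor_model")) {
    structure(list(features = list(center = num(obj$center),
                                   scale = num(obj$scale),
                                   rotation = mat(obj$rotation),
                                   k = as.integer(obj$k)),
                   centers = mat(obj$centers),
                   labels = as.integer(unlist(obj$labels)),
                   w = num(obj$w), eps = num(obj$eps), residuals = NULL,
                   K = as.integer(obj$K), grid = num(obj$grid)),
              class = "predictor_model")
  } else stop("unrecognized model file: ", path)
}
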