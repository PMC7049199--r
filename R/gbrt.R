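#' Fit gradient-boosted regression trees on integer features
#'
#' A compiled, deterministic boosted-regression-trees learner for the
#' squared-error objective: each round fits a depth-limited regression tree to
#' the current residuals by exact greedy search over histogrammed integer
#' feature values, with an L2 leaf penalty and shrinkage. When a validation
#' set is supplied, training stops once validation RMSE has not improved for
#' `patience` rounds and the model is truncated at its best round.
#'
#' Feature importance is split gain summed per feature over the retained
#' trees ("gain" importance).
#'
#' @param X integer-valued numeric matrix, samples x features
#' @param y numeric response (the adjusted integer phenotype)
#' @param nrounds maximum boosting rounds
#' @param eta learning rate
#' @param max_depth maximum tree depth
#' @param min_child minimum samples per leaf
#' @param lambda L2 penalty on leaf weights
#' @param X_valid,y_valid optional validation split for early stopping
#' @param patience early-stopping patience in rounds
#' @return object of class `exomehub_gbrt`
#' @export
gbrt <- function(X, y, nrounds = 300L, eta = 0.1, max_depth = 6L,
                 min_child = 5L, lambda = 1, X_valid = NULL, y_valid = NULL,
                 patience = 20L) {
  if (anyNA(X) || anyNA(y)) stop("NaN/NA in features or labels")
  Xi <- as_int_matrix(X)
  if (is.null(X_valid)) {
    Xv <- matrix(integer(0), 0L, ncol(Xi))
    yv <- numeric(0)
  } else {
    Xv <- as_int_matrix(X_valid)
    yv <- as.numeric(y_valid)
  }
  fit <- gbrt_fit_cpp(Xi, as.numeric(y), Xv, yv, as.integer(nrounds), eta,
                      as.integer(max_depth), as.integer(min_child), lambda,
                      as.integer(patience))
  names(fit$importance) <- colnames(X)
  structure(list(trees = fit$trees,
                 best_iter = fit$best_iter,
                 base = fit$base,
                 eta = eta,
                 importance = fit$importance,
                 valid_rmse = fit$valid_rmse,
                 params = list(nrounds = nrounds, eta = eta,
                               max_depth = max_depth, min_child = min_child,
                               lambda = lambda, patience = patience),
                 feature_names = colnames(X)),
            class = "exomehub_gbrt")
}

as_int_matrix <- function(X) {
  Xi <- matrix(as.integer(round(X)), nrow(X), ncol(X))
  if (any(abs(X - Xi) > 1e-6))
    stop("features must be integer-valued (adjusted matrices are)")
  Xi
}

#' @export
predict.exomehub_gbrt <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == length(object$feature_names) ||
              is.null(object$feature_names))
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  drop(gbrt_predict_cpp(object$trees, object$base, object$eta,
                        as_int_matrix(newdata)))
}

#' @export
print.exomehub_gbrt <- function(x, ...) {
  cat(sprintf("gbrt model: %d trees (depth <= %d, eta %.2f), %d/%d features used\n",
              x$best_iter, x$params$max_depth, x$eta,
              sum(x$importance > 0), length(x$importance)))
  invisible(x)
}
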