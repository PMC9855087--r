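#' Fit a multi-output regression random forest
#'
#' Each tree is grown on a bootstrap sample, choosing at every split the
#' feature/threshold pair that maximizes the variance reduction summed over
#' all outputs (so the ensemble predicts every output jointly).
#'
#' @param X Numeric matrix, samples x features.
#' @param Y Numeric matrix, samples x outputs (row-aligned with `X`).
#' @param n_trees Number of trees (default 500).
#' @param mtry_fraction Fraction of features tried per split (default 1/3).
#' @param max_depth Maximum tree depth; `NULL` (default) = unlimited.
#' @param min_split Minimum node size eligible for splitting (default 5).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return A `kdt_forest` object.
#' @export
rf_fit <- function(X, Y, n_trees = 500, mtry_fraction = 1 / 3,
                   max_depth = NULL, min_split = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in X or Y", call. = FALSE)
  mtry <- max(1L, as.integer(floor(mtry_fraction * ncol(X))))
  trees <- .rf_fit_cpp(X, Y, as.integer(n_trees), mtry,
                       if (is.null(max_depth)) -1L else as.integer(max_depth),
                       as.integer(min_split), as.double(seed))
  structure(list(trees = trees, feature_ids = colnames(X),
                 output_ids = colnames(Y), n_outputs = ncol(Y),
                 seed = seed, n_trees = n_trees, mtry = mtry),
            class = "kdt_forest")
}

#' Predict from a fitted forest
#' @param object A `kdt_forest`.
#' @param newdata Samples x features matrix (same feature order as training).
#' @param ... Unused.
#' @return Samples x outputs matrix of ensemble-mean predictions.
#' @export
predict.kdt_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- .rf_predict_cpp(object$trees, newdata, object$n_outputs)
  dimnames(out) <- list(rownames(newdata), object$output_ids)
  out
}

#' @export
print.kdt_forest <- function(x, ...) {
  cat(sprintf("<multi-output random forest: %d trees, %d features, %d outputs>\n",
              x$n_trees, length(x$feature_ids), x$n_outputs))
  invisible(x)
}
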