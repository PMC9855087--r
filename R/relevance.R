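#' Configuration for the relevance model
#'
#' @param kdt_genes Character vector of known-drug-target gene symbols; these
#'   are the model's features.
#' @param n_trees Trees in the forest (default 500).
#' @param max_depth Maximum tree depth or `NULL` (default, unlimited).
#' @param mtry_fraction Fraction of features tried per split (default 1/3).
#' @param cv_folds Folds for the out-of-fold R-squared (default 5).
#' @param seed Integer seed governing bootstrap, fold assignment and the
#'   SHAP background draw.
#' @param background_size Background points for interventional SHAP
#'   (default `min(100, n_samples)` at fit time).
#' @return A `kdt_relevance_config` list.
#' @export
relevance_config <- function(kdt_genes, n_trees = 500, max_depth = NULL,
                             mtry_fraction = 1 / 3, cv_folds = 5, seed = 1,
                             background_size = NULL) {
  stopifnot(length(kdt_genes) >= 1, cv_folds >= 2, n_trees >= 1,
            mtry_fraction > 0, mtry_fraction <= 1)
  structure(list(kdt_genes = as.character(kdt_genes), n_trees = n_trees,
                 max_depth = max_depth, mtry_fraction = mtry_fraction,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 background_size = background_size),
            class = "kdt_relevance_config")
}

#' Fit the KDT-to-circuit relevance model
#'
#' Restricts the expression matrix to the KDT columns (the feature matrix X),
#' fits the multi-output random forest against the circuit activities Y, and
#' scores each circuit's predictability with an out-of-fold R-squared from a
#' seeded K-fold cross-validation. R-squared of a constant response is 0 by
#' convention.
#'
#' @param expr Normalized expression matrix (samples x genes).
#' @param Y Circuit-activity matrix (samples x circuits), row-aligned.
#' @param config A [relevance_config()].
#' @param compute_r2 Set `FALSE` to skip the cross-validation (the `r2` field
#'   is then `NA`); useful when only the SHAP ranking is needed.
#' @return A `kdt_relevance_model`: fields `forest`, `r2` (named per-circuit
#'   vector), `X` (training features), `config`.
#' @export
fit_relevance_model <- function(expr, Y, config, compute_r2 = TRUE) {
  Y <- as.matrix(Y)
  missing <- setdiff(config$kdt_genes, colnames(expr))
  if (length(missing))
    stop("KDT gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(expr[, config$kdt_genes, drop = FALSE])
  n <- nrow(X)
  if (n < config$cv_folds)
    stop("fewer samples than cv_folds", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in X or Y", call. = FALSE)

  if (compute_r2) {
    # out-of-fold predictions, folds seeded
    old <- .Random.seed_guard(config$seed)
    on.exit(old(), add = TRUE)
    folds <- sample(rep_len(seq_len(config$cv_folds), n))
    pred <- matrix(NA_real_, n, ncol(Y))
    for (k in seq_len(config$cv_folds)) {
      tr <- folds != k
      fit_k <- rf_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      n_trees = config$n_trees,
                      mtry_fraction = config$mtry_fraction,
                      max_depth = config$max_depth,
                      seed = derive_seed(config$seed, 100 + k))
      pred[!tr, ] <- predict(fit_k, X[!tr, , drop = FALSE])
    }
    ss_res <- colSums((Y - pred)^2)
    ss_tot <- colSums(sweep(Y, 2L, colMeans(Y))^2)
    r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  } else {
    r2 <- rep(NA_real_, ncol(Y))
  }
  names(r2) <- colnames(Y)

  forest <- rf_fit(X, Y, n_trees = config$n_trees,
                   mtry_fraction = config$mtry_fraction,
                   max_depth = config$max_depth,
                   seed = derive_seed(config$seed, 1))
  structure(list(forest = forest, r2 = r2, X = X, config = config),
            class = "kdt_relevance_model")
}

#' @export
print.kdt_relevance_model <- function(x, ...) {
  cat(sprintf("<relevance model: %d KDTs -> %d circuits; median CV R^2 = %.3f>\n",
              ncol(x$X), length(x$r2), stats::median(x$r2)))
  invisible(x)
}

#' Exact interventional Shapley values of the relevance model
#'
#' For every sample, feature and circuit, the Shapley contribution of the
#' feature to that circuit's prediction, with the value function
#' `v(S) = E_z[f(x_S, z_!S)]` over a seeded background drawn from the
#' training features. Local accuracy `sum_f phi + base = prediction` holds to
#' machine precision.
#'
#' @param model A `kdt_relevance_model` (or a bare `kdt_forest`, with `X` and
#'   `seed` supplied).
#' @param X Foreground samples x features matrix; defaults to the training X.
#' @param background Optional explicit background matrix; by default
#'   `background_size` rows are sampled (seeded) from the training X.
#' @return List with `phi` (array samples x features x circuits) and `base`
#'   (per-circuit scalar).
#' @export
shap_values <- function(model, X = NULL, background = NULL) {
  stopifnot(inherits(model, "kdt_relevance_model"))
  if (is.null(X)) X <- model$X
  X <- as.matrix(X)
  if (is.null(background)) {
    n <- nrow(model$X)
    bs <- model$config$background_size
    if (is.null(bs)) bs <- min(100L, n)
    old <- .Random.seed_guard(derive_seed(model$config$seed, 2))
    on.exit(old(), add = TRUE)
    background <- model$X[sample.int(n, min(bs, n)), , drop = FALSE]
  }
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background set is empty", call. = FALSE)
  res <- .rf_shap_cpp(model$forest$trees, X, background,
                      model$forest$n_outputs)
  dimnames(res$phi) <- list(rownames(X), model$forest$feature_ids,
                            model$forest$output_ids)
  names(res$base) <- model$forest$output_ids
  res
}

#' Per-(KDT, circuit) relevance: mean absolute Shapley value
#'
#' Each sample's prediction is decomposed into per-feature contributions for
#' every circuit; the relevance of gene g to circuit c is the mean over
#' samples of `|phi[, g, c]|`.
#'
#' @inheritParams shap_values
#' @return KDT x circuit numeric matrix (non-negative).
#' @export
shap_relevance <- function(model, X = NULL, background = NULL) {
  sv <- shap_values(model, X, background)
  rel <- apply(abs(sv$phi), c(2L, 3L), mean)
  rel
}

#' Global per-KDT relevance and rank
#'
#' The global relevance of a KDT is its mean relevance across circuits; ranks
#' are by descending relevance (1 = most relevant), ties broken by gene
#' symbol ascending.
#'
#' @param relevance KDT x circuit relevance matrix (see [shap_relevance()]).
#' @return data.frame with columns `gene`, `relevance`, `rank`, sorted by
#'   rank.
#' @export
global_relevance <- function(relevance) {
  if (is.null(dim(relevance)) || ncol(relevance) == 0L)
    stop("empty circuit set", call. = FALSE)
  g <- rowMeans(relevance)
  ord <- order(-g, rownames(relevance))
  out <- data.frame(gene = rownames(relevance)[ord], relevance = g[ord],
                    rank = seq_along(g), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
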