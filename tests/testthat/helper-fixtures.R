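# fixtures and independent oracles shared across tests

# 3-node activation chain R -> M -> E
chain_circuit <- function(id = "chain", genes = c(R = "gR", M = "gM", E = "gE"),
                          signs = c("activation", "activation")) {
  circuit(id, nodes = as.list(genes),
          edges = data.frame(from = c("R", "M"), to = c("M", "E"),
                             sign = signs, stringsAsFactors = FALSE),
          receptors = "R", effector = "E")
}

one_chain_collection <- function() {
  pathway_collection(list(list(id = "P1", name = "p1",
                               circuits = list(chain_circuit()))))
}

# structural equality of collections, order-insensitive within circuits
expect_equal_collection <- function(a, b) {
  ca <- collection_circuits(a)
  cb <- collection_circuits(b)
  expect_setequal(names(ca), names(cb))
  for (id in names(ca)) {
    x <- ca[[id]]; y <- cb[[id]]
    expect_setequal(names(x$nodes), names(y$nodes))
    for (nid in names(x$nodes))
      expect_setequal(x$nodes[[nid]], y$nodes[[nid]])
    ex <- x$edges[order(x$edges$from, x$edges$to), ]
    ey <- y$edges[order(y$edges$from, y$edges$to), ]
    rownames(ex) <- rownames(ey) <- NULL
    expect_equal(ex, ey)
    expect_setequal(x$receptors, y$receptors)
    expect_identical(x$effector, y$effector)
  }
}

# exact Shapley values by exhaustive coalition enumeration; the value of a
# coalition S is the background-mean model prediction at the hybrid point
# (features in S from x, the rest from the background row). Independent of
# the C++ SHAP path: uses only predict().
brute_force_shap <- function(forest, x, background, d) {
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  v <- function(S) {
    H <- background
    if (any(S)) H[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    colMeans(predict(forest, H))
  }
  phi <- matrix(0, d, forest$n_outputs)
  for (i in seq_len(d)) {
    for (r in seq_len(nrow(subsets))) {
      S <- subsets[r, ]
      if (S[i]) next
      s <- sum(S)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      Si <- S; Si[i] <- TRUE
      phi[i, ] <- phi[i, ] + w * (v(Si) - v(S))
    }
  }
  phi
}

# small fitted model on smooth 2-signal data for SHAP tests
tiny_model <- function(n = 80, d = 3, n_trees = 40, seed = 7) {
  withr::with_seed(99, {
    X <- matrix(runif(n * d), n, d, dimnames = list(NULL, paste0("g", seq_len(d))))
    Y <- cbind(c1 = 2 * X[, 1] + X[, 2] + rnorm(n, 0, 0.05),
               c2 = 1 - X[, min(d, 3)] + rnorm(n, 0, 0.05))
  })
  cfg <- relevance_config(paste0("g", seq_len(d)), n_trees = n_trees,
                          cv_folds = 3, seed = seed, background_size = 8)
  fit_relevance_model(X, Y, cfg)
}

# scaled-down simulated world for pipeline-level tests
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_pathways = 2, circuits_per_pathway = 2, n_samples = 80,
         n_kdts = 10, n_drivers = 2, n_background_genes = 60, seed = seed),
    list(...))
  do.call(simulation_config, args)
}
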