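#' Normalize an expression matrix to [0, 1]
#'
#' Per gene, values are truncated at that gene's `upper_quantile` quantile
#' (blunting outliers) and then min-max scaled to `[0, 1]`. A gene constant
#' across samples maps to all zeros: the deterministic convention that a flat
#' gene carries no signal.
#'
#' @param raw Numeric matrix, samples x genes, non-negative, with sample ids
#'   as rownames and gene ids as colnames.
#' @param upper_quantile Truncation quantile in (0, 1], default 0.99.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @examples
#' normalize_expression(cbind(g = c(0, 5, 10)))
#' @export
normalize_expression <- function(raw, upper_quantile = 0.99) {
  raw <- as.matrix(raw)
  if (anyNA(raw)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(raw < 0)) stop("expression values must be non-negative", call. = FALSE)
  stopifnot(upper_quantile > 0, upper_quantile <= 1)
  out <- raw
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j]
    hi <- as.numeric(quantile(v, upper_quantile, names = FALSE))
    v <- pmin(v, hi)
    lo <- min(v)
    out[, j] <- if (hi > lo) (v - lo) / (hi - lo) else 0
  }
  out
}

#' Per-sample node values for a circuit
#'
#' A circuit node can bundle several genes; its value is an aggregate of the
#' member genes' normalized expression.
#'
#' @param expr Normalized expression matrix (samples x genes, values in
#'   `[0, 1]`).
#' @param circ A [circuit()].
#' @param aggregator `"mean"` (default) or `"min"`.
#' @param missing_gene `"error"` (default) or `"impute"`: impute fills 0.5
#'   for genes absent from `expr`, with a warning.
#' @return Matrix samples x nodes with values in `[0, 1]`.
#' @export
node_values <- function(expr, circ, aggregator = c("mean", "min"),
                        missing_gene = c("error", "impute")) {
  aggregator <- match.arg(aggregator)
  missing_gene <- match.arg(missing_gene)
  agg <- if (aggregator == "mean") rowMeans else function(m) apply(m, 1L, min)
  out <- matrix(NA_real_, nrow(expr), length(circ$nodes),
                dimnames = list(rownames(expr), names(circ$nodes)))
  for (nid in names(circ$nodes)) {
    genes <- circ$nodes[[nid]]
    absent <- setdiff(genes, colnames(expr))
    if (length(absent)) {
      if (missing_gene == "error")
        stop(sprintf("circuit '%s': gene(s) %s absent from expression matrix",
                     circ$id, paste(absent, collapse = ", ")), call. = FALSE)
      warning(sprintf("circuit '%s': imputing 0.5 for absent gene(s) %s",
                      circ$id, paste(absent, collapse = ", ")), call. = FALSE)
    }
    vals <- matrix(0.5, nrow(expr), length(genes))
    present <- genes %in% colnames(expr)
    vals[, present] <- expr[, genes[present], drop = FALSE]
    out[, nid] <- agg(vals)
  }
  out
}

#' Propagate signal through a circuit
#'
#' Nodes are processed in topological order. A receptor node passes its own
#' value through (`S = v`, full incoming stimulus). Any other node with
#' activating parents `A` and inhibiting parents `I` receives
#' `S = v * (1 - prod(1 - S_a)) * prod(1 - S_i)`: a probabilistic OR over
#' activators and AND-NOT over inhibitors. A node with only inhibiting
#' parents takes activation factor 1. The circuit activity is the effector's
#' signal.
#'
#' @param circ A validated [circuit()] (must be a DAG).
#' @param node_vals Matrix samples x nodes in `[0, 1]` (see [node_values()]).
#' @return Numeric vector of per-sample activities in `[0, 1]`.
#' @export
propagate_circuit <- function(circ, node_vals) {
  if (any(node_vals < 0 | node_vals > 1))
    stop("node values outside [0,1]; normalize expression first", call. = FALSE)
  node_ids <- names(circ$nodes)
  g <- igraph::graph_from_data_frame(circ$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = node_ids))
  topo <- igraph::topo_sort(g, mode = "out")$name
  S <- matrix(NA_real_, nrow(node_vals), length(node_ids),
              dimnames = list(rownames(node_vals), node_ids))
  act_parents <- split(circ$edges$from[circ$edges$sign == "activation"],
                       circ$edges$to[circ$edges$sign == "activation"])
  inh_parents <- split(circ$edges$from[circ$edges$sign == "inhibition"],
                       circ$edges$to[circ$edges$sign == "inhibition"])
  for (nid in topo) {
    v <- node_vals[, nid]
    if (nid %in% circ$receptors) {
      S[, nid] <- v
      next
    }
    A <- act_parents[[nid]]
    I <- inh_parents[[nid]]
    act <- if (length(A) == 1L) {
      S[, A] # single parent: algebraically 1-(1-S), written to stay bit-exact
    } else if (length(A)) {
      1 - apply(1 - S[, A, drop = FALSE], 1L, prod)
    } else 1
    inh <- if (length(I)) apply(1 - S[, I, drop = FALSE], 1L, prod) else 1
    S[, nid] <- v * act * inh
  }
  S[, circ$effector]
}

#' Compute the circuit-activity matrix for a collection
#'
#' One activity column per circuit; rows aligned to the samples of `expr`.
#'
#' @param collection A `kdt_pathway_collection`.
#' @param expr Normalized expression matrix (samples x genes in `[0, 1]`).
#' @param aggregator,missing_gene Passed to [node_values()].
#' @return Matrix samples x circuits with values in `[0, 1]`.
#' @export
compute_activities <- function(collection, expr, aggregator = "mean",
                               missing_gene = "error") {
  circs <- collection_circuits(collection)
  Y <- matrix(NA_real_, nrow(expr), length(circs),
              dimnames = list(rownames(expr), names(circs)))
  for (cid in names(circs)) {
    nv <- node_values(expr, circs[[cid]], aggregator, missing_gene)
    Y[, cid] <- propagate_circuit(circs[[cid]], nv)
  }
  Y
}

#' Read an expression TSV (first column gene id, one column per sample)
#' @param path TSV path.
#' @return Samples x genes numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("input missing: ", path, call. = FALSE)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- d[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path, call. = FALSE)
  m <- t(as.matrix(d[, -1L, drop = FALSE]))
  colnames(m) <- genes
  m
}

#' Write an expression matrix as TSV (genes x samples layout on disk)
#' @param expr Samples x genes matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene = colnames(expr), t(expr), check.names = FALSE)
  write.table(format(d, digits = 6, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
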