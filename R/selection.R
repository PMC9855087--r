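#' Select relevant KDTs for one circuit (convex R-squared-gated quantile)
#'
#' The selection quantile is the convex combination
#' `q = clip(r2) * 0.95 + (1 - clip(r2)) * 1`, i.e. a selected fraction of
#' `0.05 * clip(r2, 0, 1)^gamma`: a perfectly predicted circuit (r2 = 1)
#' keeps its top 5% of KDTs by mean |SHAP|; as predictability drops the
#' fraction shrinks, reaching zero at r2 <= 0. The count is floored, so
#' poorly predicted circuits may select nothing.
#'
#' @param ranking Named numeric vector: per-KDT score (mean |SHAP|) for this
#'   circuit, covering all KDTs. Order need not be sorted.
#' @param r2 The circuit's coefficient of determination.
#' @param gamma Exponent on the clipped r2 (default 1, the plain convex rule).
#' @param circuit_id Optional id recorded in the result.
#' @return A `kdt_circuit_selection`: list with `circuit_id`, `r2`,
#'   `selected_fraction`, `selected_kdts` (ordered, score descending, ties by
#'   gene symbol ascending).
#' @examples
#' select_kdts(setNames(runif(100), paste0("g", 1:100)), r2 = 1)
#' @export
select_kdts <- function(ranking, r2, gamma = 1, circuit_id = NA_character_) {
  n_kdts <- length(ranking)
  if (n_kdts == 0L) stop("empty KDT ranking", call. = FALSE)
  if (!is.finite(r2)) stop("non-finite r2", call. = FALSE)
  if (any(ranking < 0)) stop("scores must be non-negative", call. = FALSE)
  frac <- 0.05 * clip01(r2)^gamma
  count <- floor(frac * n_kdts)
  ord <- order(-ranking, names(ranking))
  structure(list(circuit_id = circuit_id, r2 = r2, selected_fraction = frac,
                 selected_kdts = names(ranking)[ord][seq_len(count)]),
            class = "kdt_circuit_selection")
}

#' Selection over all circuits of a relevance result
#'
#' @param relevance KDT x circuit mean-|SHAP| matrix.
#' @param r2 Named per-circuit R-squared vector.
#' @param gamma Passed to [select_kdts()].
#' @return Named list of `kdt_circuit_selection`, one per circuit.
#' @export
select_all_circuits <- function(relevance, r2, gamma = 1) {
  circuits <- colnames(relevance)
  sel <- lapply(circuits, function(cid)
    select_kdts(relevance[, cid], r2[[cid]], gamma = gamma, circuit_id = cid))
  names(sel) <- circuits
  sel
}

#' Per-KDT summary of circuit selections
#'
#' For each KDT: the circuits in which it was selected, how many pathways
#' those circuits belong to, and the pairwise circuit overlap between KDTs.
#'
#' @param selections List of `kdt_circuit_selection` (see
#'   [select_all_circuits()]).
#' @param kdt_genes Character vector of all KDTs (so never-selected KDTs get
#'   count 0).
#' @param pathway_map Optional named vector mapping circuit id to pathway id
#'   (see [circuit_pathway_map()]); enables the pathway count.
#' @return List with `per_kdt` (data.frame: gene, n_circuits, n_pathways,
#'   circuits), and `shared` (matrix of pairwise shared-circuit counts).
#' @export
circuits_per_target <- function(selections, kdt_genes, pathway_map = NULL) {
  sets <- lapply(kdt_genes, function(g)
    vapply(selections, function(s) g %in% s$selected_kdts, TRUE))
  names(sets) <- kdt_genes
  circ_ids <- vapply(selections, `[[`, "", "circuit_id")
  per_kdt <- data.frame(
    gene = kdt_genes,
    n_circuits = vapply(sets, sum, 0L),
    n_pathways = vapply(sets, function(m) {
      if (is.null(pathway_map)) return(NA_integer_)
      length(unique(pathway_map[circ_ids[m]]))
    }, 0L),
    circuits = vapply(sets, function(m) paste(circ_ids[m], collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  shared <- outer(kdt_genes, kdt_genes,
                  Vectorize(function(a, b) sum(sets[[a]] & sets[[b]])))
  dimnames(shared) <- list(kdt_genes, kdt_genes)
  list(per_kdt = per_kdt, shared = shared)
}
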