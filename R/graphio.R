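#' Construct a signaling circuit
#'
#' A circuit is a directed acyclic receptor-to-effector subgraph of a
#' signaling pathway. Nodes carry one or more gene symbols (KEGG-style nodes
#' may bundle paralogues); edges are signed (activation / inhibition).
#'
#' @param id Circuit identifier, unique within a pathway collection.
#' @param nodes Named list mapping node id to a non-empty character vector of
#'   gene symbols.
#' @param edges A data.frame (or matrix) with columns `from`, `to`, `sign`;
#'   `sign` must be `"activation"` or `"inhibition"`.
#' @param receptors Character vector of receptor node ids (in-degree 0).
#' @param effector Single effector node id (out-degree 0).
#' @param validate Check circuit invariants (default `TRUE`).
#' @return An object of class `kdt_circuit`.
#' @examples
#' circuit("c1", nodes = list(R = "GENE1", M = "GENE2", E = "GENE3"),
#'         edges = data.frame(from = c("R", "M"), to = c("M", "E"),
#'                            sign = "activation"),
#'         receptors = "R", effector = "E")
#' @export
circuit <- function(id, nodes, edges, receptors, effector, validate = TRUE) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    edges <- data.frame(from = as.character(edges[[1L]]),
                        to = as.character(edges[[2L]]),
                        sign = as.character(edges[[3L]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  obj <- structure(list(id = id,
                        nodes = lapply(nodes, as.character),
                        edges = edges,
                        receptors = as.character(receptors),
                        effector = as.character(effector)),
                   class = "kdt_circuit")
  if (validate) validate_circuit(obj)
  obj
}

#' Validate circuit invariants
#'
#' Checks that the circuit is a DAG, node ids are unique, gene lists are
#' non-empty, receptors have in-degree 0 and the effector out-degree 0,
#' every node is reachable from some receptor, and the effector is reachable
#' from every receptor.
#'
#' @param x A `kdt_circuit`.
#' @return `x`, invisibly; errors (naming the circuit) otherwise.
#' @export
validate_circuit <- function(x) {
  cid <- x$id
  fail <- function(msg) stop(sprintf("circuit '%s': %s", cid, msg), call. = FALSE)
  node_ids <- names(x$nodes)
  if (is.null(node_ids) || anyDuplicated(node_ids))
    fail("node ids missing or duplicated")
  if (any(!vapply(x$nodes, length, 1L) | vapply(x$nodes, function(g) any(!nzchar(g)), TRUE)))
    fail("every node needs a non-empty gene list")
  if (!all(x$edges$sign %in% c("activation", "inhibition")))
    fail("edge signs must be 'activation' or 'inhibition'")
  if (!all(c(x$edges$from, x$edges$to) %in% node_ids))
    fail("edge endpoints must be declared nodes")
  if (length(x$receptors) == 0L) fail("receptor list is empty")
  if (!all(x$receptors %in% node_ids) || !(x$effector %in% node_ids))
    fail("receptors/effector must be declared nodes")
  g <- igraph::graph_from_data_frame(
    x$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = node_ids))
  if (!igraph::is_dag(g)) fail("graph contains a cycle")
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  if (any(indeg[x$receptors] != 0L)) fail("receptors must have in-degree 0")
  if (outdeg[x$effector] != 0L) fail("effector must have out-degree 0")
  reach <- igraph::subcomponent(g, x$receptors[1L], mode = "out")$name
  for (r in x$receptors) {
    down <- igraph::subcomponent(g, r, mode = "out")$name
    if (!(x$effector %in% down)) fail(sprintf("effector unreachable from receptor '%s'", r))
    reach <- union(reach, down)
  }
  if (!setequal(reach, node_ids)) fail("nodes unreachable from any receptor")
  invisible(x)
}

#' Construct a pathway collection
#'
#' @param pathways List of pathways, each a list with fields `id`, `name`,
#'   and `circuits` (a list of [circuit()] objects).
#' @return A `kdt_pathway_collection`.
#' @export
pathway_collection <- function(pathways) {
  pids <- vapply(pathways, `[[`, "", "id")
  if (anyDuplicated(pids)) stop("duplicate pathway ids", call. = FALSE)
  cids <- unlist(lapply(pathways, function(p)
    vapply(p$circuits, `[[`, "", "id")), use.names = FALSE)
  if (anyDuplicated(cids)) stop("duplicate circuit ids in collection", call. = FALSE)
  structure(list(pathways = pathways), class = "kdt_pathway_collection")
}

#' @export
print.kdt_pathway_collection <- function(x, ...) {
  cs <- collection_circuits(x)
  cat(sprintf("<pathway collection: %d pathways, %d circuits, %d genes>\n",
              length(x$pathways), length(cs),
              length(collection_genes(x))))
  invisible(x)
}

#' @export
print.kdt_circuit <- function(x, ...) {
  cat(sprintf("<circuit '%s': %d nodes, %d edges, %d receptor(s) -> '%s'>\n",
              x$id, length(x$nodes), nrow(x$edges), length(x$receptors),
              x$effector))
  invisible(x)
}

#' Flatten a collection into a named list of circuits
#' @param collection A `kdt_pathway_collection`.
#' @return Named list of `kdt_circuit`, names = circuit ids.
#' @export
collection_circuits <- function(collection) {
  cs <- unlist(lapply(collection$pathways, `[[`, "circuits"), recursive = FALSE)
  names(cs) <- vapply(cs, `[[`, "", "id")
  cs
}

#' All gene symbols appearing in a collection
#' @param collection A `kdt_pathway_collection`.
#' @return Sorted character vector.
#' @export
collection_genes <- function(collection) {
  sort(unique(unlist(lapply(collection_circuits(collection),
                            function(cc) unlist(cc$nodes, use.names = FALSE)))))
}

#' Map circuit id to the id of the pathway containing it
#' @param collection A `kdt_pathway_collection`.
#' @return Named character vector (names = circuit ids).
#' @export
circuit_pathway_map <- function(collection) {
  out <- unlist(lapply(collection$pathways, function(p)
    setNames(rep(p$id, length(p$circuits)),
             vapply(p$circuits, `[[`, "", "id"))))
  out
}

#' Read a pathway collection
#'
#' Two formats are supported. `"json"` is the native schema:
#' `{"pathways":[{"id","name","circuits":[{"id","nodes":[{"id","genes":[..]}],`
#' `"edges":[["src","dst","activation"|"inhibition"],..],"receptors":[..],`
#' `"effector":".."}]}]}`. `"sif"` is one edge per line
#' (`src <TAB> relation <TAB> dst`) and needs a sidecar TSV declaring, per
#' circuit, its receptors, effector and node gene content (see
#' [write_pathways()] for the layout); a SIF file holds a single pathway.
#'
#' @param path File path.
#' @param format `"json"` or `"sif"`.
#' @param sidecar For `format = "sif"`, path to the sidecar TSV with columns
#'   `node`, `genes` (semicolon-joined), `role` (`receptor`/`effector`/`""`).
#' @return A validated `kdt_pathway_collection`.
#' @export
read_pathways <- function(path, format = c("json", "sif"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input missing: ", path, call. = FALSE)
  if (format == "json") read_pathways_json(path) else read_pathways_sif(path, sidecar)
}

read_pathways_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error in '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(doc$pathways)) stop("parse error: no 'pathways' field", call. = FALSE)
  pws <- lapply(doc$pathways, function(p) {
    if (is.null(p$id)) stop("parse error: pathway without id", call. = FALSE)
    circs <- lapply(p$circuits, function(cc) {
      if (is.null(cc$id) || is.null(cc$nodes) || is.null(cc$effector))
        stop(sprintf("parse error: malformed circuit record in pathway '%s'", p$id),
             call. = FALSE)
      nodes <- setNames(lapply(cc$nodes, function(n) unlist(n$genes)),
                        vapply(cc$nodes, function(n) n$id, ""))
      edges <- if (length(cc$edges))
        do.call(rbind, lapply(cc$edges, function(e)
          data.frame(from = e[[1L]], to = e[[2L]], sign = e[[3L]],
                     stringsAsFactors = FALSE)))
      else data.frame(from = character(), to = character(), sign = character())
      circuit(cc$id, nodes, edges, unlist(cc$receptors), cc$effector)
    })
    list(id = p$id, name = if (is.null(p$name)) p$id else p$name, circuits = circs)
  })
  pathway_collection(pws)
}

read_pathways_sif <- function(path, sidecar) {
  if (is.null(sidecar) || !file.exists(sidecar))
    stop("SIF import needs an existing sidecar TSV", call. = FALSE)
  ed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ed) != 3L)
    stop("parse error in '", path, "': SIF lines must be src<TAB>relation<TAB>dst",
         call. = FALSE)
  side <- read.delim(sidecar, stringsAsFactors = FALSE)
  need <- c("circuit", "node", "genes", "role")
  if (!all(need %in% names(side)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  circs <- lapply(split(side, side$circuit), function(s) {
    nodes <- setNames(lapply(strsplit(s$genes, ";", fixed = TRUE), trimws), s$node)
    keep <- ed[[1L]] %in% s$node & ed[[3L]] %in% s$node
    circuit(s$circuit[1L], nodes,
            data.frame(from = ed[keep, 1L], to = ed[keep, 3L],
                       sign = ed[keep, 2L], stringsAsFactors = FALSE),
            receptors = s$node[s$role == "receptor"],
            effector = s$node[s$role == "effector"])
  })
  pid <- sub("\\.sif$", "", basename(path))
  pathway_collection(list(list(id = pid, name = pid, circuits = unname(circs))))
}

#' Write a pathway collection
#'
#' `format = "json"` writes the native schema so that
#' `read_pathways(write_pathways(x))` is the identity. `format = "sif"`
#' writes one SIF per pathway plus one sidecar TSV (paths derived from
#' `path`); only single-pathway collections are supported for SIF.
#'
#' @param collection A `kdt_pathway_collection`.
#' @param path Output file path.
#' @param format `"json"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(collection, path, format = c("json", "sif")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(pathways = lapply(collection$pathways, function(p) {
      list(id = p$id, name = p$name, circuits = lapply(p$circuits, function(cc) {
        list(id = cc$id,
             nodes = lapply(names(cc$nodes), function(nid)
               list(id = nid, genes = as.list(cc$nodes[[nid]]))),
             edges = lapply(seq_len(nrow(cc$edges)), function(i)
               list(cc$edges$from[i], cc$edges$to[i], cc$edges$sign[i])),
             receptors = as.list(cc$receptors),
             effector = cc$effector)
      }))
    }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    if (length(collection$pathways) != 1L)
      stop("SIF export supports single-pathway collections", call. = FALSE)
    circs <- collection_circuits(collection)
    ed <- do.call(rbind, lapply(circs, function(cc)
      data.frame(from = cc$edges$from, rel = cc$edges$sign, to = cc$edges$to)))
    write.table(unique(ed), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    side <- do.call(rbind, lapply(circs, function(cc)
      data.frame(circuit = cc$id, node = names(cc$nodes),
                 genes = vapply(cc$nodes, paste, "", collapse = ";"),
                 role = ifelse(names(cc$nodes) %in% cc$receptors, "receptor",
                               ifelse(names(cc$nodes) == cc$effector,
                                      "effector", "")))))
    write.table(side, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
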