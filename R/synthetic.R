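#' Simulation configuration
#'
#' The generator emulates the shape of a tissue-expression + disease-map
#' input: a collection of receptor-to-effector circuits, an expression matrix
#' whose circuit activities are driven by a known subset of KDT genes (the
#' planted drivers) through the propagation rule, decoy KDTs carrying no
#' signal, and background genes.
#'
#' `driver_effect` maps to a signal-amplitude multiplier: `"strong"` = 3.0,
#' `"moderate"` = 1.5, `"weak"` = 0.5; a numeric value overrides the mapping
#' (0 yields a signal-free world: with `noise_sd = 0` every activity is
#' constant).
#'
#' @param n_pathways,circuits_per_pathway Collection size (defaults 5 x 4).
#' @param chain_length_range Min/max nodes on a circuit's main chain
#'   (default c(3, 6)).
#' @param n_samples Samples to simulate (default 300).
#' @param n_kdts Known drug targets = model features (default 40).
#' @param n_drivers Planted driver KDTs (default 5; must be <= n_kdts).
#' @param n_background_genes Structural/background gene pool (default 200).
#' @param driver_effect `"strong"`, `"moderate"`, `"weak"`, or a number.
#' @param noise_sd Additive measurement-noise SD on every gene (default 0.25,
#'   in the same arbitrary expression units as the baseline).
#' @param seed Integer seed; generation is fully reproducible from
#'   (config, seed).
#' @return A `kdt_sim_config` list.
#' @export
simulation_config <- function(n_pathways = 5, circuits_per_pathway = 4,
                              chain_length_range = c(3, 6), n_samples = 300,
                              n_kdts = 40, n_drivers = 5,
                              n_background_genes = 200,
                              driver_effect = "strong", noise_sd = 0.25,
                              seed = 1) {
  mult <- if (is.numeric(driver_effect)) driver_effect
          else switch(match.arg(driver_effect, c("strong", "moderate", "weak")),
                      strong = 3.0, moderate = 1.5, weak = 0.5)
  stopifnot(n_drivers <= n_kdts, n_drivers >= 0, n_kdts >= 1,
            n_pathways >= 1, circuits_per_pathway >= 1, n_samples >= 2,
            noise_sd >= 0, length(chain_length_range) == 2,
            chain_length_range[1] >= 2)
  structure(list(n_pathways = n_pathways,
                 circuits_per_pathway = circuits_per_pathway,
                 chain_length_range = chain_length_range,
                 n_samples = n_samples, n_kdts = n_kdts,
                 n_drivers = n_drivers,
                 n_background_genes = n_background_genes,
                 driver_effect = driver_effect, effect_multiplier = mult,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kdt_sim_config")
}

#' Generate a synthetic pathway collection with planted drivers
#'
#' Circuits are chains (branched with probability 0.4: a second receptor arm
#' merging into the main chain, occasionally by inhibition). Each driver KDT
#' is placed, solo, into a randomly chosen node of up to two circuits; about
#' a third of the decoy KDTs are bundled into multi-gene structural nodes
#' (where the mean aggregator dilutes them), the rest appear in no circuit.
#' Structural nodes draw genes from the background pool without reuse across
#' circuits.
#'
#' @param config A [simulation_config()].
#' @return List with `collection` (a validated `kdt_pathway_collection`) and
#'   `truth` (driver genes, decoy genes, driver-to-circuit map, structural
#'   gene-to-circuit map, config echo).
#' @export
generate_pathways <- function(config) {
  old <- .Random.seed_guard(derive_seed(config$seed, 11))
  on.exit(old(), add = TRUE)

  kdts <- sprintf("KDT%02d", seq_len(config$n_kdts))
  bg <- sprintf("BG%03d", seq_len(config$n_background_genes))
  drivers <- if (config$n_drivers > 0) sample(kdts, config$n_drivers) else character()
  decoys <- setdiff(kdts, drivers)

  bg_next <- 0L
  take_bg <- function(k) {
    if (bg_next + k > length(bg))
      stop("infeasible config: background gene pool exhausted; ",
           "increase n_background_genes", call. = FALSE)
    out <- bg[bg_next + seq_len(k)]
    bg_next <<- bg_next + k
    out
  }

  pathways <- vector("list", config$n_pathways)
  circuit_nodes <- list() # circuit id -> circuit object (pre driver placement)
  for (p in seq_len(config$n_pathways)) {
    circs <- vector("list", config$circuits_per_pathway)
    for (ci in seq_len(config$circuits_per_pathway)) {
      cid <- sprintf("P%d_c%d", p, ci)
      L <- sample(seq(config$chain_length_range[1],
                      config$chain_length_range[2]), 1L)
      ids <- sprintf("n%d", seq_len(L))
      edges <- data.frame(from = ids[-L], to = ids[-1L], sign = "activation",
                          stringsAsFactors = FALSE)
      receptors <- ids[1L]
      if (L >= 3 && runif(1) < 0.4) { # second receptor arm into node 2
        ids <- c(ids, "b1")
        edges <- rbind(edges, data.frame(
          from = "b1", to = "n2",
          sign = if (runif(1) < 0.3) "inhibition" else "activation"))
        receptors <- c(receptors, "b1")
      }
      nodes <- setNames(vector("list", length(ids)), ids)
      for (nid in ids) {
        k <- if (runif(1) < 0.25) 2L else 1L
        nodes[[nid]] <- take_bg(k)
      }
      circuit_nodes[[cid]] <- list(id = cid, nodes = nodes, edges = edges,
                                   receptors = receptors, effector = sprintf("n%d", L))
    }
    pathways[[p]] <- list(id = sprintf("P%d", p), name = sprintf("pathway %d", p),
                          circuits = circs) # filled below
  }

  cids <- names(circuit_nodes)
  # place each driver solo into a random free node of up to two circuits
  free_nodes <- lapply(circuit_nodes, function(cc) names(cc$nodes))
  driver_circuit_map <- setNames(vector("list", length(drivers)), drivers)
  for (g in drivers) {
    eligible <- cids[vapply(free_nodes, length, 1L) > 0]
    n_place <- min(2L, length(eligible))
    if (n_place == 0L)
      stop("infeasible config: more drivers than free node slots", call. = FALSE)
    chosen <- sample(eligible, n_place)
    for (cid in chosen) {
      nid <- if (length(free_nodes[[cid]]) == 1L) free_nodes[[cid]]
             else sample(free_nodes[[cid]], 1L)
      circuit_nodes[[cid]]$nodes[[nid]] <- g # replace: driver sits solo
      free_nodes[[cid]] <- setdiff(free_nodes[[cid]], nid)
    }
    driver_circuit_map[[g]] <- chosen
  }
  # bundle ~1/3 of decoys into structural nodes (diluted by mean aggregation)
  n_bundle <- floor(length(decoys) / 3)
  bundled <- if (n_bundle > 0) sample(decoys, n_bundle) else character()
  for (g in bundled) {
    eligible <- cids[vapply(free_nodes, length, 1L) > 0]
    if (!length(eligible)) break
    cid <- sample(eligible, 1L)
    nid <- if (length(free_nodes[[cid]]) == 1L) free_nodes[[cid]]
           else sample(free_nodes[[cid]], 1L)
    circuit_nodes[[cid]]$nodes[[nid]] <-
      c(circuit_nodes[[cid]]$nodes[[nid]], g)
  }

  struct_gene_circuit <- unlist(lapply(circuit_nodes, function(cc) {
    gs <- setdiff(unlist(cc$nodes, use.names = FALSE), kdts)
    setNames(rep(cc$id, length(gs)), gs)
  }), use.names = TRUE)
  names(struct_gene_circuit) <- sub("^P\\d+_c\\d+\\.", "", names(struct_gene_circuit))

  for (p in seq_len(config$n_pathways)) {
    this <- grep(sprintf("^P%d_", p), cids, value = TRUE)
    pathways[[p]]$circuits <- lapply(this, function(cid) {
      cc <- circuit_nodes[[cid]]
      circuit(cc$id, cc$nodes, cc$edges, cc$receptors, cc$effector)
    })
  }
  collection <- pathway_collection(pathways)
  truth <- structure(list(driver_genes = sort(drivers),
                          decoy_genes = sort(decoys),
                          bundled_decoys = sort(bundled),
                          kdt_genes = kdts,
                          driver_circuit_map = driver_circuit_map,
                          struct_gene_circuit = struct_gene_circuit,
                          config = config), class = "kdt_synthetic_truth")
  list(collection = collection, truth = truth)
}

#' Generate a synthetic expression matrix over a collection
#'
#' Each driver KDT follows its own latent factor scaled by the effect
#' multiplier; structural genes of a circuit load (with gene-specific weights
#' drawn from U(0.5, 1)) on the mean latent of the circuit's drivers, or on a
#' circuit-private latent when the circuit hosts no driver — emulating the
#' within-pathway co-expression that makes KDT-restricted features predictive
#' of circuit activity in real tissue data. Decoy KDTs and unplaced
#' background genes carry measurement noise only. All values are baseline +
#' signal + `noise_sd` Gaussian noise, truncated at 0.
#'
#' @param collection Collection from [generate_pathways()].
#' @param truth Matching `kdt_synthetic_truth`.
#' @param config The same [simulation_config()].
#' @return Samples x genes non-negative matrix (columns: all KDTs, then the
#'   background pool).
#' @export
generate_expression <- function(collection, truth, config) {
  old <- .Random.seed_guard(derive_seed(config$seed, 12))
  on.exit(old(), add = TRUE)
  n <- config$n_samples
  genes <- c(truth$kdt_genes, sprintf("BG%03d", seq_len(config$n_background_genes)))
  mult <- config$effect_multiplier

  cids <- names(collection_circuits(collection))
  z_driver <- matrix(rnorm(n * max(1L, length(truth$driver_genes))), nrow = n)
  colnames(z_driver) <- if (length(truth$driver_genes)) truth$driver_genes else "none"
  z_circuit <- matrix(rnorm(n * length(cids)), nrow = n,
                      dimnames = list(NULL, cids))
  circuit_signal <- sapply(cids, function(cid) {
    hosts <- names(Filter(function(v) cid %in% v, truth$driver_circuit_map))
    if (length(hosts)) rowMeans(z_driver[, hosts, drop = FALSE])
    else z_circuit[, cid]
  })

  mu <- setNames(runif(length(genes), 3, 7), genes)
  expr <- matrix(0, n, length(genes),
                 dimnames = list(sprintf("S%03d", seq_len(n)), genes))
  for (g in genes) {
    signal <- if (g %in% truth$driver_genes) {
      mult * z_driver[, g]
    } else if (g %in% names(truth$struct_gene_circuit)) {
      runif(1, 0.5, 1) * mult * circuit_signal[, truth$struct_gene_circuit[[g]]]
    } else 0
    expr[, g] <- pmax(0, mu[[g]] + signal + config$noise_sd * rnorm(n))
  }
  expr
}

#' One-call synthetic dataset
#'
#' @param config A [simulation_config()].
#' @return List with `collection`, `truth`, `expr` (raw expression).
#' @export
simulate_dataset <- function(config) {
  gp <- generate_pathways(config)
  expr <- generate_expression(gp$collection, gp$truth, config)
  list(collection = gp$collection, truth = gp$truth, expr = expr)
}
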