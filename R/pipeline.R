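#' Run the full relevance pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> circuit activities ->
#' relevance model -> per-circuit selection -> stability -> report, writing
#' every artifact plus a run manifest that suffices to re-execute the run
#' bit-identically.
#'
#' The configuration is a JSON file (or an equivalent R list) with blocks:
#' \describe{
#'   \item{seed}{single integer fanned out to per-stage seeds.}
#'   \item{simulate}{arguments for [simulation_config()]; mutually exclusive
#'     with `inputs`.}
#'   \item{inputs}{paths `expression` (TSV), `pathways` (JSON),
#'     `kdt_genes` (plain text, one symbol per line).}
#'   \item{normalize}{`upper_quantile` (default 0.99).}
#'   \item{model}{`n_trees`, `max_depth`, `mtry_fraction`, `cv_folds`,
#'     `background_size`.}
#'   \item{selection}{`gamma` (default 1).}
#'   \item{stability}{`enabled` (default TRUE), `M`, `subsample_fraction`,
#'     `mode`.}
#' }
#'
#' @param config Path to a JSON config, or a list.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) stop("input missing: ", config, call. = FALSE)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say <- function(...) if (!quiet) message("[kdtrank] ", sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t <- system.time(res <- force(expr))["elapsed"]
    timings[[stage]] <<- unname(t)
    say("%-12s %.2fs", stage, t)
    res
  }

  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       modifyList(config$simulate,
                                  list(seed = derive_seed(seed, 1))))
    ds <- clock("simulate", simulate_dataset(sim_cfg))
    collection <- ds$collection; raw <- ds$expr; truth <- ds$truth
    kdt_genes <- truth$kdt_genes
    write_expression(raw, file.path(out_dir, "expression.tsv"))
    write_pathways(collection, file.path(out_dir, "pathways.json"))
    writeLines(kdt_genes, file.path(out_dir, "kdt_genes.txt"))
    jsonlite::write_json(
      list(driver_genes = truth$driver_genes,
           decoy_genes = truth$decoy_genes,
           driver_circuit_map = truth$driver_circuit_map),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in unlist(inp[c("expression", "pathways", "kdt_genes")]))
      if (!file.exists(f)) stop("input missing: ", f, call. = FALSE)
    raw <- clock("load", read_expression(inp$expression))
    collection <- read_pathways(inp$pathways, "json")
    kdt_genes <- readLines(inp$kdt_genes)
    kdt_genes <- kdt_genes[nzchar(kdt_genes)]
  } else stop("config needs a 'simulate' or 'inputs' block", call. = FALSE)

  # --- activities -----------------------------------------------------------
  uq <- if (is.null(config$normalize$upper_quantile)) 0.99
        else config$normalize$upper_quantile
  expr <- clock("normalize", normalize_expression(raw, upper_quantile = uq))
  Y <- clock("activities", compute_activities(collection, expr))
  write_tsv6(as.data.frame(Y), file.path(out_dir, "activities.tsv"),
             row_label = "sample")

  # --- relevance ------------------------------------------------------------
  mc <- if (is.null(config$model)) list() else config$model
  rc <- relevance_config(
    kdt_genes = kdt_genes,
    n_trees = if (is.null(mc$n_trees)) 500 else mc$n_trees,
    max_depth = mc$max_depth,
    mtry_fraction = if (is.null(mc$mtry_fraction)) 1 / 3 else mc$mtry_fraction,
    cv_folds = if (is.null(mc$cv_folds)) 5 else mc$cv_folds,
    background_size = mc$background_size,
    seed = derive_seed(seed, 2))
  model <- clock("relevance", fit_relevance_model(expr, Y, rc))
  rel <- clock("shap", shap_relevance(model))
  glob <- global_relevance(rel)
  write_tsv6(as.data.frame(rel), file.path(out_dir, "relevance.tsv"),
             row_label = "gene")
  write_tsv6(data.frame(circuit = names(model$r2), r2 = unname(model$r2)),
             file.path(out_dir, "r2.tsv"))
  write_tsv6(glob, file.path(out_dir, "global_relevance.tsv"))

  # --- selection ------------------------------------------------------------
  gamma <- if (is.null(config$selection$gamma)) 1 else config$selection$gamma
  sel <- clock("select", select_all_circuits(rel, model$r2, gamma = gamma))
  sel_tab <- data.frame(
    circuit_id = vapply(sel, `[[`, "", "circuit_id"),
    r2 = vapply(sel, `[[`, 0.0, "r2"),
    fraction = vapply(sel, `[[`, 0.0, "selected_fraction"),
    selected = vapply(sel, function(s) paste(s$selected_kdts, collapse = ";"), ""),
    row.names = NULL)
  write_tsv6(sel_tab, file.path(out_dir, "selection.tsv"))
  summ <- circuits_per_target(sel, kdt_genes, circuit_pathway_map(collection))
  write_tsv6(summ$per_kdt, file.path(out_dir, "kdt_summary.tsv"))

  # --- stability ------------------------------------------------------------
  stab <- NULL
  sc <- if (is.null(config$stability)) list() else config$stability
  if (is.null(sc$enabled) || isTRUE(sc$enabled)) {
    stab <- clock("stability", run_stability_harness(
      expr, Y, rc,
      M = if (is.null(sc$M)) 30 else sc$M,
      subsample_fraction = if (is.null(sc$subsample_fraction)) 0.8
                           else sc$subsample_fraction,
      gamma = gamma,
      mode = if (is.null(sc$mode)) "union" else sc$mode,
      seed = derive_seed(seed, 3)))
    write.table(stab$Z, file.path(out_dir, "stability_Z.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(stab$report),
                         file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  # --- manifest -------------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "kdtrank",
    version = as.character(utils::packageVersion("kdtrank")),
    config = config,
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1),
                       relevance = derive_seed(seed, 2),
                       stability = derive_seed(seed, 3)),
    timings_s = as.list(timings),
    output_md5 = as.list(tools::md5sum(outputs)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done in %.1fs -> %s", manifest$elapsed_s, out_dir)
  invisible(list(collection = collection, truth = truth, expr = expr, Y = Y,
                 model = model, relevance = rel, global = glob,
                 selections = sel, summary = summ, stability = stab,
                 manifest = manifest))
}
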