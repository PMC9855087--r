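#' Nogueira stability estimate of a selection matrix
#'
#' With `Z` an M x d binary matrix of selections (rows = resamples), let
#' `p_f` be the selection frequency of feature f, `s2_f = M/(M-1) p_f (1-p_f)`
#' its unbiased variance, and `kbar` the mean number of features selected per
#' resample. The stability estimate is
#' `phi = 1 - mean(s2_f) / ((kbar/d) (1 - kbar/d))`: 1 means every resample
#' selected the identical set; values near 0 are indistinguishable from
#' random selection of kbar features; negative values mean systematically
#' anti-correlated selections.
#'
#' @param Z Binary matrix, M resamples x d features (M >= 2).
#' @return `phi` (numeric), or `NA` with attribute `reason` when
#'   `kbar` is 0 or d (stability undefined for empty/full selections).
#' @examples
#' Z <- matrix(rep(c(1, 1, 0, 0), 5), nrow = 5, byrow = TRUE)
#' nogueira_stability(Z) # identical rows -> 1
#' @export
nogueira_stability <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("need at least 2 resamples", call. = FALSE)
  if (!all(Z %in% c(0, 1))) stop("Z must be binary", call. = FALSE)
  M <- nrow(Z); d <- ncol(Z)
  kbar <- mean(rowSums(Z))
  if (kbar == 0 || kbar == d) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "stability undefined: mean selection size is %s of %d features",
      format(kbar), d)
    return(out)
  }
  p <- colMeans(Z)
  s2 <- (M / (M - 1)) * p * (1 - p)
  1 - mean(s2) / ((kbar / d) * (1 - kbar / d))
}

#' Percentile-bootstrap confidence interval for the stability estimate
#'
#' Resamples the M rows of `Z` with replacement `B` times; replicates with a
#' degenerate mean selection size (0 or d) are skipped and counted.
#'
#' @param Z Binary selection matrix (M x d).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `ci_low`, `ci_high`, `n_degenerate`.
#' @export
stability_ci <- function(Z, B = 1000, seed = 1, level = 0.95) {
  Z <- as.matrix(Z)
  M <- nrow(Z)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  reps <- vapply(seq_len(B), function(b)
    nogueira_stability(Z[sample.int(M, M, replace = TRUE), , drop = FALSE]),
    0.0)
  ok <- !is.na(reps)
  if (!any(ok)) stop("all bootstrap replicates degenerate", call. = FALSE)
  qs <- quantile(reps[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], n_degenerate = sum(!ok))
}

# mean stability of uniformly random selections matched to Z's row sizes
matched_null_phi <- function(Z, draws = 500, seed = 1) {
  Z <- as.matrix(Z)
  M <- nrow(Z); d <- ncol(Z)
  k <- rowSums(Z)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  vals <- vapply(seq_len(draws), function(b) {
    Zr <- matrix(0, M, d)
    for (m in seq_len(M)) if (k[m] > 0) Zr[m, sample.int(d, k[m])] <- 1
    nogueira_stability(Zr)
  }, 0.0)
  mean(vals, na.rm = TRUE)
}

#' Stability harness: refit the selection pipeline on subsamples
#'
#' Draws `M` seeded subsamples of the data (without replacement), refits the
#' relevance model and the per-circuit selection on each, and records, per
#' resample, the union over circuits of the selected KDTs as a binary vector
#' (a per-circuit mode keeps circuits separate, concatenating one block of
#' columns per circuit). Assembles the Nogueira estimate, a bootstrap 95% CI,
#' and an effect size against a matched random-selection null (same per-row
#' selection counts, `null_draws` draws).
#'
#' @param expr Normalized expression matrix (samples x genes).
#' @param Y Circuit-activity matrix (samples x circuits).
#' @param config A [relevance_config()].
#' @param M Number of resamples (default 30).
#' @param subsample_fraction Fraction of samples per resample (default 0.8).
#' @param gamma Selection exponent, see [select_kdts()].
#' @param mode `"union"` (default) or `"per_circuit"`.
#' @param seed Integer seed.
#' @param ci_reps,null_draws Bootstrap and null-model draw counts.
#' @return List with `Z` (selection matrix) and `report` (a
#'   `kdt_stability_report`: phi_hat, ci_low, ci_high, null_phi, effect_size,
#'   M, d, mean_k, seed).
#' @export
run_stability_harness <- function(expr, Y, config, M = 30,
                                  subsample_fraction = 0.8, gamma = 1,
                                  mode = c("union", "per_circuit"), seed = 1,
                                  ci_reps = 1000, null_draws = 500) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  n <- nrow(expr)
  n_sub <- max(config$cv_folds, floor(subsample_fraction * n))
  kdts <- config$kdt_genes
  circuits <- colnames(Y)
  feat_ids <- if (mode == "union") kdts
              else as.vector(outer(kdts, circuits, paste, sep = "@"))
  Z <- matrix(0L, M, length(feat_ids), dimnames = list(NULL, feat_ids))
  for (m in seq_len(M)) {
    sub_seed <- derive_seed(seed, 1000 + m)
    old <- .Random.seed_guard(sub_seed)
    idx <- sample.int(n, n_sub)
    old()
    cfg_m <- config
    cfg_m$seed <- sub_seed
    model <- fit_relevance_model(expr[idx, , drop = FALSE],
                                 Y[idx, , drop = FALSE], cfg_m)
    rel <- shap_relevance(model)
    sel <- select_all_circuits(rel, model$r2, gamma = gamma)
    if (mode == "union") {
      picked <- unique(unlist(lapply(sel, `[[`, "selected_kdts")))
      Z[m, picked] <- 1L
    } else {
      for (cid in circuits)
        if (length(sel[[cid]]$selected_kdts))
          Z[m, paste(sel[[cid]]$selected_kdts, cid, sep = "@")] <- 1L
    }
  }
  phi <- nogueira_stability(Z)
  ci <- if (is.na(phi)) list(ci_low = NA_real_, ci_high = NA_real_,
                             n_degenerate = NA_integer_)
        else stability_ci(Z, B = ci_reps, seed = derive_seed(seed, 2))
  null_phi <- matched_null_phi(Z, draws = null_draws,
                               seed = derive_seed(seed, 3))
  report <- structure(list(
    phi_hat = as.numeric(phi),
    undefined_reason = attr(phi, "reason"),
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    null_phi = null_phi,
    effect_size = as.numeric(phi) - null_phi,
    M = M, d = ncol(Z), mean_k = mean(rowSums(Z)),
    mode = mode, subsample_fraction = subsample_fraction,
    seed = seed), class = "kdt_stability_report")
  list(Z = Z, report = report)
}

#' @export
print.kdt_stability_report <- function(x, ...) {
  cat(sprintf("<stability: phi = %.3f [%.3f, %.3f], null = %.3f, effect = %.3f (M=%d, d=%d)>\n",
              x$phi_hat, x$ci_low, x$ci_high, x$null_phi, x$effect_size,
              x$M, x$d))
  invisible(x)
}
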