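# shared helpers: seed fan-out, RNG scoping, rounding, TSV output

#' Derive a per-stage seed from a global seed
#'
#' Counter-based fan-out so a single user-facing seed drives every stochastic
#' stage deterministically; results stay below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647)
}

# set.seed locally; returns a restore function for on.exit
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Round half away from zero
#'
#' Unlike base `round()` (banker's rounding), halves round away from zero,
#' matching how printed tables are conventionally rounded.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip01 <- function(x) pmin(1, pmax(0, x))

# TSV with '.' decimals, tab delimiter, no quoting, 6 significant digits
write_tsv6 <- function(d, path, row_label = NULL) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 6, format = "g"))
  if (!is.null(row_label)) d <- cbind(setNames(data.frame(rownames(d)), row_label), d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
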