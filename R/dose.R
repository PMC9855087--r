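# Per-fatty-acid dose arithmetic for a gavage supplement: dose rate (mg of
# supplement per g body weight) times each analyte's content (g per 100 g of
# oil). Class totals (omega-3/6/9, SFA, MUFA, PUFA) follow the grouping
# declared in the composition table itself; the bundled EFA table reproduces
# the source batch sheet, whose printed totals place Adrenic outside omega-6
# and Eicosatetraenoic outside the PUFA sum.

#' Read a fatty-acid composition table
#'
#' TSV with columns `analyte`, `shorthand` (e.g. "C22:6 n3"), `classes`
#' (semicolon-joined subset of w3/w6/w9/SFA/MUFA/PUFA; may be empty) and
#' `content` (g per 100 g oil).
#'
#' @param path TSV path; defaults to the bundled EFA marine-oil supplement
#'   batch composition.
#' @return A `kdt_composition` data.frame.
#' @export
read_composition <- function(path = system.file("extdata",
                                                "efa_composition.tsv",
                                                package = "kdtrank")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("analyte", "shorthand", "classes", "content")
  if (!all(need %in% names(d)))
    stop("composition table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$content < 0)) stop("negative content", call. = FALSE)
  if (anyDuplicated(d[c("analyte", "shorthand")]))
    stop("duplicate (analyte, shorthand) pair", call. = FALSE)
  class(d) <- c("kdt_composition", "data.frame")
  d
}

#' Per-analyte administered dose from composition and dose rate
#'
#' `dose_i = dose_rate * content_i / 100`, displayed rounded half-away-from-
#' zero to 3 decimals. Class totals are computed from the unrounded member
#' doses and then rounded, so no per-row rounding error accumulates.
#'
#' @param comp A composition table (see [read_composition()]).
#' @param dose_rate Supplement dose in mg per g body weight (default 2.82,
#'   the gavage rate of the bundled supplement).
#' @return data.frame with columns `analyte`, `shorthand`, `dose` (exact) and
#'   `dose_rounded` (3 decimals); class-total rows appended with analyte
#'   `"Total <class>"`.
#' @examples
#' compute_doses(read_composition())
#' @export
compute_doses <- function(comp, dose_rate = 2.82) {
  if (dose_rate <= 0) stop("dose_rate must be positive", call. = FALSE)
  if (any(comp$content < 0)) stop("negative content", call. = FALSE)
  dose <- dose_rate * comp$content / 100
  rows <- data.frame(analyte = comp$analyte, shorthand = comp$shorthand,
                     dose = dose, dose_rounded = round_half_away(dose, 3),
                     stringsAsFactors = FALSE)
  tags <- strsplit(ifelse(is.na(comp$classes), "", comp$classes), ";",
                   fixed = TRUE)
  classes <- c("w3", "w6", "w9", "SFA", "MUFA", "PUFA")
  present <- classes[classes %in% unlist(tags)]
  totals <- do.call(rbind, lapply(present, function(cl) {
    tot <- sum(dose[vapply(tags, function(t) cl %in% t, TRUE)])
    data.frame(analyte = paste("Total", cl), shorthand = "", dose = tot,
               dose_rounded = round_half_away(tot, 3),
               stringsAsFactors = FALSE)
  }))
  rbind(rows, totals)
}

#' Daily supplement intake range over a body-weight range
#'
#' @param dose_rate mg per g body weight.
#' @param bw_range Length-2 numeric, body weight range in grams (low, high).
#' @return Numeric length-2 vector, mg/day, rounded to 1 decimal.
#' @examples
#' daily_intake_range(2.82, c(5, 9)) # 14.1 to 25.4 mg
#' @export
daily_intake_range <- function(dose_rate, bw_range) {
  if (length(bw_range) != 2 || bw_range[1] <= 0 || bw_range[1] > bw_range[2])
    stop("bw_range must be (low, high) with 0 < low <= high", call. = FALSE)
  round_half_away(dose_rate * bw_range, 1)
}
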