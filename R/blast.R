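#' PSI-BLAST annotation-transfer baseline
#'
#' Transfers GO terms from every annotated hit with an E-value strictly
#' better than `e_cutoff` (a hit at exactly the cutoff is excluded).
#' Each transferred term is scored `-log10(max(E, e_floor)) + b`; a term
#' carried by several qualifying hits keeps its best (maximum) score —
#' per-hit provenance, in contrast with PFP's additive sum.
#'
#' @param result A `search_result` with annotated hits.
#' @param e_cutoff Strict E-value threshold (default 0.01).
#' @param b Score offset (default 2).
#' @param e_floor Clamp for zero E-values (default 1e-180).
#' @param matrix_tag Optional scoring-matrix label recorded in the
#'   prediction metadata for reporting (the matrix only affects the
#'   upstream search, not this scoring).
#' @param max_hits Optional cap on the number of best qualifying hits
#'   used (`Inf` uses all).
#' @return A `prediction_set` (method `"blast"`); empty when no hit
#'   qualifies.
#' @export
blast_transfer <- function(result, e_cutoff = 0.01, b = 2, e_floor = 1e-180,
                           matrix_tag = "blosum62", max_hits = Inf) {
  scores <- numeric(0)
  used <- 0L
  for (h in result$hits) {
    if (h$e_value >= e_cutoff || length(h$annotations) == 0L) next
    used <- used + 1L
    if (used > max_hits) break
    s <- neglog_weight(h$e_value, b, e_floor)
    for (f in h$annotations) {
      scores[[f]] <- max(scores[f], s, na.rm = TRUE)
    }
  }
  prediction_set(result$query_id, scores, "blast",
                 metadata = list(matrix_tag = matrix_tag,
                                 e_cutoff = e_cutoff))
}

#' Evenly spaced score-cutoff grid
#'
#' The grid the baseline's recall curves are traced over: by default 100
#' cutoffs from 4 (E-value 0.01) to 45 (E-value 1e-43), inclusive.
#'
#' @param lo,hi Grid endpoints (`lo < hi`; defaults 4 and 45).
#' @param n Number of cutoffs (default 100).
#' @return Numeric vector of length `n` from `lo` to `hi`.
#' @export
blast_cutoff_grid <- function(lo = 4, hi = 45, n = 100) {
  if (!(lo < hi) || n < 2) stop("invalid cutoff grid: need lo < hi and n >= 2")
  seq(lo, hi, length.out = n)
}
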