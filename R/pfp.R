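#' PFP scoring configuration
#'
#' The PFP score for a candidate term fa sums, over every sequence hit i
#' with E-value at most `e_max` and every GO annotation fj of that hit,
#' the product of the hit weight `-log10(E_i) + b` and the co-occurrence
#' probability P(fa | fj) from the annotation corpus.  The offset `b` is
#' tied to `e_max` (`b = log10(e_max)`) so the weakest admissible hit
#' weighs exactly 0 and all scores are non-negative; the defaults
#' `e_max = 100`, `b = 2` reproduce that calibration.
#'
#' @param e_max Hits with E-value above this are excluded (default 100).
#' @param b Weight offset; defaults to `log10(e_max)`.
#' @param e_floor Clamp for zero E-values (default 1e-180).
#' @param cond_prob_fallback Score contribution used when P(fa|fj) is
#'   undefined because fj annotates no corpus protein: the hit annotation
#'   fj then contributes `fallback` to itself only (default 0 — no
#'   corpus evidence, no score).
#' @param propagate_parents Whether [pfp_score()] applies the upward
#'   parental propagation (default `TRUE`).
#' @param cond_prob_view Annotation view for co-occurrence statistics
#'   (`"direct"` by default; see [cond_prob()]).
#' @return A list of class `pfp_config`.
#' @export
pfp_config <- function(e_max = 100, b = log10(e_max), e_floor = 1e-180,
                       cond_prob_fallback = 0, propagate_parents = TRUE,
                       cond_prob_view = "direct") {
  stopifnot(e_max > 0, e_floor > 0,
            cond_prob_fallback >= 0, cond_prob_fallback <= 1)
  if (abs(b - log10(e_max)) > 1e-9) {
    warning("b != log10(e_max): hits at e_max will not weigh exactly 0")
  }
  structure(list(e_max = e_max, b = b, e_floor = e_floor,
                 cond_prob_fallback = cond_prob_fallback,
                 propagate_parents = propagate_parents,
                 cond_prob_view = cond_prob_view),
            class = "pfp_config")
}

#' Direct PFP score
#'
#' Applies the co-occurrence sum to one query's hit list: every term
#' co-annotated in the corpus with any hit annotation becomes a
#' candidate, and candidates accumulate `weight(hit) * P(candidate | fj)`
#' over all (hit, annotation fj) pairs.  Terms scoring 0 are omitted.
#'
#' @param result A `search_result` with annotated hits.
#' @param db An `annotation_db`.
#' @param cfg A [pfp_config()].
#' @return A `prediction_set` (method `"pfp"`) of direct scores.
#' @export
pfp_direct_score <- function(result, db, cfg = pfp_config()) {
  acc <- new.env(parent = emptyenv())
  for (h in result$hits) {
    if (h$e_value > cfg$e_max) next
    w <- neglog_weight(h$e_value, cfg$b, cfg$e_floor)
    if (w == 0) next
    for (fj in h$annotations) {
      row <- cond_prob_row(db, fj, cfg$cond_prob_view)
      if (is.null(row)) {
        if (cfg$cond_prob_fallback > 0) {
          prev <- get0(fj, envir = acc, inherits = FALSE) %||% 0
          assign(fj, prev + w * cfg$cond_prob_fallback, envir = acc)
        }
        next
      }
      for (fa in names(row)) {
        prev <- get0(fa, envir = acc, inherits = FALSE) %||% 0
        assign(fa, prev + w * row[[fa]], envir = acc)
      }
    }
  }
  terms <- ls(acc)
  scores <- vapply(terms, function(t) get(t, envir = acc), 0)
  scores <- scores[scores > 0]
  prediction_set(result$query_id, scores, "pfp")
}

#' Upward parental propagation of PFP scores
#'
#' Transfers each directly scored term's score to all of its ancestors,
#' scaled by the proportion of proteins annotated (after propagation) to
#' the descendant relative to the ancestor:
#' `raw(p) = direct(p) + sum_fa direct(fa) * n(fa) / n(p)` over the set
#' of scored descendants fa of p.  Each descendant contributes once
#' regardless of how many paths link it to p, and only direct scores are
#' propagated (no cascading through intermediate ancestors), so nothing
#' is double-counted up a chain.  The result is the raw score.
#'
#' @param direct A `prediction_set` of direct scores.
#' @param dag A `go_dag`.
#' @param db An `annotation_db` supplying propagated term counts.
#' @return A `prediction_set` of raw scores (method `"pfp"`).
#' @export
pfp_propagate_parents <- function(direct, dag, db) {
  raw <- as.list(direct$scores)
  skipped <- 0L
  for (fa in names(direct$scores)) {
    n_fa <- term_count(db, fa, propagated = TRUE)
    if (n_fa == 0L) next
    s_fa <- direct$scores[[fa]]
    for (p in go_ancestors(dag, fa)) {
      n_p <- term_count(db, p, propagated = TRUE)
      if (n_p == 0L) {
        skipped <- skipped + 1L
        next
      }
      raw[[p]] <- (raw[[p]] %||% 0) + s_fa * n_fa / n_p
    }
  }
  if (skipped > 0L) {
    warning("pfp_propagate_parents: skipped ", skipped,
            " ancestor contribution(s) with zero propagated count")
  }
  prediction_set(direct$query_id, unlist(raw), "pfp")
}

#' PFP raw score for one query
#'
#' Convenience wrapper: [pfp_direct_score()] followed by
#' [pfp_propagate_parents()] (unless disabled in the config).
#'
#' @inheritParams pfp_direct_score
#' @param dag A `go_dag`.
#' @return A `prediction_set` of raw PFP scores.
#' @export
pfp_score <- function(result, db, dag, cfg = pfp_config()) {
  direct <- pfp_direct_score(result, db, cfg)
  if (!cfg$propagate_parents) return(direct)
  pfp_propagate_parents(direct, dag, db)
}

#' Ranked terms of a prediction set
#'
#' @param pred A `prediction_set`.
#' @param n_top Truncate to at most this many terms (default 1000).
#' @return Character vector of accessions, descending by score with ties
#'   broken by ascending accession.
#' @export
pfp_ranked_terms <- function(pred, n_top = 1000) {
  utils::head(names(pred$scores), n_top)
}

#' Nested rank-prefix cutoff sets
#'
#' Sorts predictions by raw score, truncates to the top `n_top`, and
#' returns the nested prefixes at ranks `interval, 2*interval, ...,
#' n_top` — the ranked-list cutoff grid used for PFP precision/recall
#' curves (by default 100 prefixes of sizes 10, 20, ..., 1000).
#'
#' @param pred A `prediction_set`.
#' @param n_top Maximum list length (default 1000).
#' @param interval Rank step (default 10).
#' @return Named list of character vectors; names are the nominal ranks.
#'   Prefixes are capped at the number of scored terms.  Empty
#'   predictions yield an empty list.
#' @export
pfp_rank_cutoffs <- function(pred, n_top = 1000, interval = 10) {
  stopifnot(n_top >= interval, interval >= 1)
  ranked <- pfp_ranked_terms(pred, n_top)
  if (length(ranked) == 0L) return(list())
  ranks <- seq(interval, n_top, by = interval)
  stats::setNames(
    lapply(ranks, function(k) ranked[seq_len(min(k, length(ranked)))]),
    ranks
  )
}

#' Terms retained at a fractional list cutoff
#'
#' A fractional cutoff c in (0, 1\] on the top-`n_top` ranked list keeps
#' the first `round(c * n_top)` terms — e.g. the PFP cutoff 0.5 keeps at
#' most 500 of 1000 predictions.
#'
#' @param pred A `prediction_set`.
#' @param fraction Cutoff in (0, 1\].
#' @param n_top Maximum list length (default 1000).
#' @return Character vector of retained accessions.
#' @export
pfp_fraction_terms <- function(pred, fraction, n_top = 1000) {
  stopifnot(fraction > 0, fraction <= 1)
  ranked <- pfp_ranked_terms(pred, n_top)
  ranked[seq_len(min(round(fraction * n_top), length(ranked)))]
}
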