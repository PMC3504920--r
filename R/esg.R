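#' ESG configuration
#'
#' The Extended Similarity Group score explores two levels of the
#' sequence-similarity space: an initial search from the target and, for
#' each of the top first-level hits, a second search seeded at that hit.
#' Within each search the hits receive weights proportional to
#' `-log10(E)`, normalized to sum to 1; a GO term's score combines the
#' weight mass of the hits it annotates across the two levels as a
#' convex mixture, which keeps every term score in \[0, 1\].
#'
#' @param level_weights Two non-negative reals summing to 1: the mixture
#'   weights of the first and second search level (default `c(0.5, 0.5)`).
#' @param n_first_level How many first-level hits seed second-level
#'   searches (default 10).
#' @param e_floor Clamp for zero E-values (default 1e-180).
#' @param e_max Hits with E-value above this never enter the
#'   normalization (default 100).
#' @return A list of class `esg_config`.
#' @export
esg_config <- function(level_weights = c(0.5, 0.5), n_first_level = 10,
                       e_floor = 1e-180, e_max = 100) {
  stopifnot(length(level_weights) == 2L, all(level_weights >= 0),
            abs(sum(level_weights) - 1) < 1e-9,
            n_first_level >= 1, e_floor > 0)
  structure(list(level_weights = level_weights,
                 n_first_level = as.integer(n_first_level),
                 e_floor = e_floor, e_max = e_max),
            class = "esg_config")
}

#' Normalize one search level's hit weights
#'
#' Each hit with E-value at most `e_max` gets the weight
#' `max(0, -log10(max(E, e_floor)))` — hits with E above 1 would have a
#' negative log and are clamped to 0, since a negative share of a level
#' is meaningless — and weights are normalized to sum to 1 over the
#' level.
#'
#' @param result A `search_result`.
#' @param cfg An [esg_config()].
#' @return Named numeric vector (subject id -> weight in \[0, 1\],
#'   summing to 1).  Errors with condition class
#'   `moonscore_esg_degenerate_level` when no hit carries positive
#'   weight.
#' @export
esg_normalize_level <- function(result, cfg = esg_config()) {
  ev <- hit_evalues(result)
  keep <- ev <= cfg$e_max
  ev <- ev[keep]
  subj <- hit_subjects(result)[keep]
  w <- pmax(0, -log10(pmax(ev, cfg$e_floor)))
  if (length(w) == 0L || sum(w) == 0) {
    stop(structure(
      class = c("moonscore_esg_degenerate_level", "error", "condition"),
      list(message = paste0("degenerate search level for query ",
                            result$query_id, ": no hit with E < 1"),
           call = sys.call())
    ))
  }
  out <- stats::setNames(w / sum(w), subj)
  attr(out, "hit_index") <- which(keep)
  out
}

#' ESG score for one query
#'
#' Runs the first-level search through `provider`, expands the top
#' `n_first_level` hits into second-level searches (the original target
#' and the seed itself are removed from second-level hit lists so the
#' query never serves as its own evidence), and scores every GO term f:
#'
#' `score(f) = a1 * sum_i w_i 1(f in ann_i)
#'           + a2 * sum_i w_i sum_j v_ij 1(f in ann_ij)`
#'
#' where `w` are the normalized first-level weights, `v_i.` the
#' normalized weights of the search seeded at hit i, and `(a1, a2)` the
#' level mixture.  A first-level hit contributes its own annotations
#' whether or not its expansion succeeds; a degenerate or failing
#' second-level search is skipped with a warning and only forfeits its
#' seed's second-level mass.
#'
#' @param query_id Query accession.
#' @param provider A search provider (see [table_search_provider()]).
#' @param db An `annotation_db` (annotates second-level hits that the
#'   provider returns bare).
#' @param cfg An [esg_config()].
#' @return A `prediction_set` (method `"esg"`) with scores in \[0, 1\].
#' @export
esg_score <- function(query_id, provider, db, cfg = esg_config()) {
  first <- provider_search(provider, query_id)
  first <- drop_subjects(first, query_id)
  first <- annotate_hits(first, db)
  w <- tryCatch(esg_normalize_level(first, cfg), error = function(e) NULL)
  if (is.null(w)) {
    warning("esg_score: no usable first-level hits for ", query_id)
    return(prediction_set(query_id, numeric(0), "esg"))
  }
  acc <- new.env(parent = emptyenv())
  add <- function(f, x) {
    assign(f, (get0(f, envir = acc, inherits = FALSE) %||% 0) + x, envir = acc)
  }
  a <- cfg$level_weights
  idx1 <- attr(w, "hit_index")
  for (i in seq_along(w)) {
    hit <- first$hits[[idx1[[i]]]]
    for (f in hit$annotations) add(f, a[[1L]] * w[[i]])
    if (i > cfg$n_first_level || a[[2L]] == 0) next
    second <- tryCatch(provider_search(provider, hit$subject_id),
                       error = function(e) NULL)
    if (is.null(second)) {
      warning("esg_score: second-level search failed for seed ", hit$subject_id)
      next
    }
    second <- drop_subjects(second, c(query_id, hit$subject_id))
    second <- annotate_hits(second, db)
    v <- tryCatch(esg_normalize_level(second, cfg), error = function(e) NULL)
    if (is.null(v)) next
    idx2 <- attr(v, "hit_index")
    for (j in seq_along(v)) {
      hit2 <- second$hits[[idx2[[j]]]]
      for (f in hit2$annotations) add(f, a[[2L]] * w[[i]] * v[[j]])
    }
  }
  terms <- ls(acc)
  scores <- vapply(terms, function(t) get(t, envir = acc), 0)
  scores <- scores[scores > 0]
  prediction_set(query_id, scores, "esg")
}

drop_subjects <- function(result, subjects) {
  keep <- !(hit_subjects(result) %in% subjects)
  result$hits <- result$hits[keep]
  result
}

annotate_hits <- function(result, db) {
  result$hits <- lapply(result$hits, function(h) {
    if (length(h$annotations) == 0L) {
      h$annotations <- db$direct[[h$subject_id]] %||% character(0)
    }
    h
  })
  result
}
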