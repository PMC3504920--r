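#' E-value weight transform
#'
#' The score weight used throughout: `-log10(max(e_value, e_floor)) + b`.
#' With the default offset `b = 2 = log10(100)` a hit at E-value 100
#' weighs exactly 0, a hit at 0.01 weighs 4, and a hit at 1e-43 weighs
#' 45.  E-values reported as 0 are clamped to `e_floor` so the weight is
#' never infinite.
#'
#' @param e_value Non-negative E-value(s).
#' @param b Additive offset (default 2).
#' @param e_floor Positive clamp applied below (default 1e-180).
#' @return Numeric weight(s), non-increasing in `e_value`.
#' @export
neglog_weight <- function(e_value, b = 2, e_floor = 1e-180) {
  stopifnot(e_floor > 0, all(e_value >= 0))
  -log10(pmax(e_value, e_floor)) + b
}

#' Construct a search result
#'
#' @param query_id Query accession.
#' @param subject_id Character vector of hit subject accessions.
#' @param e_value Numeric vector of E-values, same length.
#' @param annotations List of character vectors of GO accessions per hit.
#' @return A `search_result`: list with `query_id` and `hits`, where
#'   `hits` is a list of `list(subject_id, e_value, annotations)` sorted
#'   ascending by E-value (ties keep input order).
#' @export
search_result <- function(query_id, subject_id = character(0),
                          e_value = numeric(0), annotations = NULL) {
  stopifnot(length(subject_id) == length(e_value), all(e_value >= 0))
  if (is.null(annotations)) annotations <- rep(list(character(0)), length(subject_id))
  ord <- order(e_value)  # stable: ties keep input order
  hits <- lapply(ord, function(i) {
    list(subject_id = subject_id[[i]], e_value = e_value[[i]],
         annotations = annotations[[i]])
  })
  structure(list(query_id = query_id, hits = hits), class = "search_result")
}

#' Parse a BLAST tabular hit file
#'
#' Reads an outfmt-6 style file (columns 1 = query, 2 = subject,
#' 11 = E-value; other columns ignored), annotates each hit with the
#' subject's direct GO annotations from `db`, drops self-hits
#' (subject == query), and sorts each query's hits ascending by E-value.
#' Gzipped files are read transparently.
#'
#' @param path Path to a BLAST tabular file.
#' @param db An `annotation_db` supplying subject annotations (subjects
#'   absent from the corpus get an empty annotation set).
#' @return Named list: query id -> `search_result`.
#' @export
read_blast_tab <- function(path, db) {
  if (!file.exists(path)) stop("cannot read hit table: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 11L
  ev <- suppressWarnings(vapply(fields, function(f) {
    if (length(f) >= 11L) as.numeric(f[[11L]]) else NA_real_
  }, 0))
  bad <- !ok | is.na(ev) | ev < 0
  if (any(bad)) warning("read_blast_tab: skipped ", sum(bad), " unparsable row(s)")
  fields <- fields[!bad]
  ev <- ev[!bad]
  q <- vapply(fields, `[[`, "", 1L)
  s <- vapply(fields, `[[`, "", 2L)
  queries <- unique(q)   # keep queries whose only hits are self-hits
  self <- q == s
  q <- q[!self]; s <- s[!self]; ev <- ev[!self]
  out <- list()
  for (qid in queries) {
    sel <- q == qid
    out[[qid]] <- search_result(
      qid, s[sel], ev[sel],
      lapply(s[sel], function(sub) db$direct[[sub]] %||% character(0))
    )
  }
  out
}

#' Write search results as BLAST tabular
#'
#' Emits a 12-column outfmt-6 dialect (dummy alignment columns) so fixture
#' hit tables round-trip through [read_blast_tab()].
#'
#' @param results Named list of `search_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(results, path) {
  rows <- character(0)
  for (res in results) {
    for (h in res$hits) {
      rows <- c(rows, paste(res$query_id, h$subject_id,
                            "50.00", "100", "10", "1", "1", "100", "1", "100",
                            sprintf("%.3e", h$e_value), "100.0", sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Table-backed search provider
#'
#' Wraps a parsed hit map into the search-provider contract consumed by
#' the ESG scorer: `provider_search(provider, query_id)` returns the
#' stored `search_result` (an empty result for unknown queries), so
#' repeated calls are deterministic.  Scorers never invoke an external
#' search binary directly; any such adapter would implement the same
#' contract.
#'
#' @param results Named list of `search_result` (e.g. from
#'   [read_blast_tab()]).
#' @return An object of class `table_search_provider`.
#' @export
table_search_provider <- function(results) {
  structure(list(results = results), class = "table_search_provider")
}

#' Run a search through a provider
#'
#' @param provider A search provider.
#' @param query_id Query accession.
#' @return A `search_result` for `query_id`.
#' @export
provider_search <- function(provider, query_id) {
  UseMethod("provider_search")
}

#' @export
provider_search.table_search_provider <- function(provider, query_id) {
  provider$results[[query_id]] %||% search_result(query_id)
}

hit_evalues <- function(result) {
  vapply(result$hits, `[[`, 0, "e_value")
}

hit_subjects <- function(result) {
  vapply(result$hits, `[[`, "", "subject_id")
}
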