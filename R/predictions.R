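#' Construct a prediction set
#'
#' A scored set of GO terms for one query protein.  Scores are stored
#' sorted by descending score with ties broken by ascending accession, so
#' rank-based cutoffs are deterministic.
#'
#' @param query_id Query accession.
#' @param scores Named numeric vector (names are GO accessions).
#' @param method One of `"pfp"`, `"esg"`, `"blast"`.
#' @param metadata Optional named list (e.g. scoring-matrix tag).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(query_id, scores = numeric(0),
                           method = c("pfp", "esg", "blast"),
                           metadata = list()) {
  method <- match.arg(method)
  if (is.null(scores)) scores <- numeric(0)
  if (length(scores)) {
    stopifnot(!is.null(names(scores)), all(nzchar(names(scores))))
    scores <- scores[order(-scores, names(scores))]
  }
  structure(list(query_id = query_id, scores = scores, method = method,
                 metadata = metadata),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set [", x$method, "] query", x$query_id, ":",
      length(x$scores), "terms")
  if (length(x$scores)) cat(", top:", names(x$scores)[1L],
                            format(x$scores[[1L]], digits = 4))
  cat("\n")
  invisible(x)
}

#' Write prediction sets to TSV
#'
#' Three columns (`query_id`, `go_id`, `score`); the method tag and any
#' metadata are recorded in `#`-prefixed header comment lines.
#'
#' @param preds A `prediction_set` or a list of them (one method).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  if (inherits(preds, "prediction_set")) preds <- list(preds)
  stopifnot(length(preds) > 0L)
  method <- preds[[1L]]$method
  header <- paste0("# method=", method)
  meta <- preds[[1L]]$metadata
  for (k in names(meta)) header <- c(header, paste0("# ", k, "=", meta[[k]]))
  rows <- unlist(lapply(preds, function(p) {
    if (length(p$scores) == 0L) return(character(0))
    paste(p$query_id, names(p$scores), sprintf("%.10g", p$scores), sep = "\t")
  }), use.names = FALSE)
  writeLines(c(header, "query_id\tgo_id\tscore", rows), path)
  invisible(path)
}

#' Read prediction sets from TSV
#'
#' @param path A file written by [write_predictions()].
#' @return Named list of `prediction_set` objects keyed by query id; the
#'   method tag is recovered from the header.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  method <- sub("^# method=", "", hdr[startsWith(hdr, "# method=")][1L])
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L]  # column header
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(list())
  f <- strsplit(body, "\t", fixed = TRUE)
  q <- vapply(f, `[[`, "", 1L)
  g <- vapply(f, `[[`, "", 2L)
  s <- as.numeric(vapply(f, `[[`, "", 3L))
  out <- list()
  for (qid in unique(q)) {
    sel <- q == qid
    out[[qid]] <- prediction_set(qid, stats::setNames(s[sel], g[sel]), method)
  }
  out
}
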