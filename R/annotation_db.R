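#' Load a protein-to-GO annotation corpus
#'
#' Reads either a GAF 2.x file (tab-separated, comment lines starting
#' with `!`; columns 2 = protein id, 4 = qualifier, 5 = GO id,
#' 7 = evidence) or the minimal 2-column fixture dialect
#' (`protein_id<TAB>go_id`).  Rows with a `NOT` qualifier are skipped,
#' as are rows whose GO accession cannot be resolved in `dag` or points
#' at an obsolete term (a warning reports the skipped count).  For every
#' protein both the directly asserted term set and its ancestor closure
#' (via [go_propagate()]) are stored, together with term-to-protein
#' inverted indexes for fast counting.
#'
#' @param path Path to a GAF or 2-column TSV file.
#' @param dag A `go_dag` used to resolve and propagate accessions.
#' @param evidence_allow Optional character vector of evidence codes to
#'   keep; `NULL` (default) keeps all rows.
#' @return An object of class `annotation_db`: list with `direct` and
#'   `propagated` (named lists protein -> sorted GO accessions),
#'   `by_term_direct` / `by_term_prop` (named lists GO accession ->
#'   protein ids), `n_proteins`, and the companion `dag`.
#' @export
read_gaf <- function(path, dag, evidence_allow = NULL) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  skipped <- 0L
  prot <- character(0)
  go <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (nf[[i]] >= 7L) {              # GAF row
      if (grepl("\\bNOT\\b", f[[4L]])) next
      if (!is.null(evidence_allow) && !(f[[7L]] %in% evidence_allow)) next
      p <- f[[2L]]; g <- f[[5L]]
    } else if (nf[[i]] == 2L) {       # minimal fixture dialect
      p <- f[[1L]]; g <- f[[2L]]
    } else {
      skipped <- skipped + 1L
      next
    }
    if (!nzchar(p) || !grepl("^GO:[0-9]{7}$", g)) {
      skipped <- skipped + 1L
      next
    }
    prot <- c(prot, p)
    go <- c(go, g)
  }
  # resolve alt_ids; drop unresolvable or obsolete annotations
  known <- go %in% dag$ids | go %in% names(dag$alt_ids)
  if (any(!known)) {
    skipped <- skipped + sum(!known)
    prot <- prot[known]; go <- go[known]
  }
  if (length(go)) {
    go <- resolve_go_ids(dag, go)
    live <- !dag$obsolete[go]
    if (any(!live)) {
      skipped <- skipped + sum(!live)
      prot <- prot[live]; go <- go[live]
    }
  }
  if (skipped > 0L) {
    warning("read_gaf: skipped ", skipped, " unusable row(s)")
  }
  if (length(go) == 0L) stop("no usable annotation rows in ", path)
  direct <- lapply(split(go, prot), function(x) sort(unique(x)))
  propagated <- lapply(direct, function(x) go_propagate(dag, x))
  new_annotation_db(direct, propagated, dag)
}

new_annotation_db <- function(direct, propagated, dag) {
  invert <- function(sets) {
    prots <- rep(names(sets), lengths(sets))
    lapply(split(prots, unlist(sets, use.names = FALSE)), unique)
  }
  structure(
    list(
      direct = direct,
      propagated = propagated,
      by_term_direct = invert(direct),
      by_term_prop = invert(propagated),
      n_proteins = length(direct),
      dag = dag,
      cache = new.env(parent = emptyenv())
    ),
    class = "annotation_db"
  )
}

#' Number of proteins annotated with a term
#'
#' @param db An `annotation_db`.
#' @param f A GO accession (alternate ids resolved; unseen terms count 0).
#' @param propagated If `TRUE`, count proteins whose ancestor-closed
#'   annotation set contains `f` (i.e. proteins annotated to `f` or any
#'   of its descendants); if `FALSE` (default), count direct annotations
#'   only.
#' @return Integer count.
#' @export
term_count <- function(db, f, propagated = FALSE) {
  f <- tryCatch(resolve_go_ids(db$dag, f), error = function(e) f)
  idx <- if (propagated) db$by_term_prop else db$by_term_direct
  length(idx[[f]])
}

#' Conditional co-occurrence probability P(fa | fj)
#'
#' The fraction of proteins annotated with `fj` that are also annotated
#' with `fa`, computed on the directly asserted annotations by default.
#' This is the co-occurrence statistic the PFP score weights hit
#' annotations with.  The propagated view is available but degenerate for
#' ancestor/descendant pairs (an ancestor co-occurs with everything below
#' it), so PFP's defaults use the direct view.
#'
#' @param db An `annotation_db`.
#' @param fa,fj GO accessions.
#' @param view `"direct"` (default) or `"propagated"`.
#' @return Probability in \[0, 1\].  Errors with condition class
#'   `moonscore_undefined_cond_prob` when `fj` annotates no protein in
#'   the chosen view.
#' @export
cond_prob <- function(db, fa, fj, view = c("direct", "propagated")) {
  view <- match.arg(view)
  row <- cond_prob_row(db, fj, view)
  if (is.null(row)) {
    stop(structure(
      class = c("moonscore_undefined_cond_prob", "error", "condition"),
      list(message = paste0("P(. | ", fj, ") undefined: term annotates no protein"),
           call = sys.call())
    ))
  }
  fa <- tryCatch(resolve_go_ids(db$dag, fa), error = function(e) fa)
  p <- row[fa]
  if (is.na(p)) 0 else unname(p)
}

# Full conditional-probability row P(. | fj): named numeric over every term
# co-annotated with fj.  Lazily computed and cached per (fj, view); a dense
# table over all GO pairs is never built.
cond_prob_row <- function(db, fj, view = "direct") {
  fj <- tryCatch(resolve_go_ids(db$dag, fj), error = function(e) fj)
  key <- paste0(view, "|", fj)
  hit <- get0(key, envir = db$cache, inherits = FALSE)
  if (!is.null(hit)) return(if (identical(hit, NA)) NULL else hit)
  idx <- if (view == "propagated") db$by_term_prop else db$by_term_direct
  ann <- if (view == "propagated") db$propagated else db$direct
  prots <- idx[[fj]]
  if (length(prots) == 0L) {
    assign(key, NA, envir = db$cache)
    return(NULL)
  }
  counts <- table(unlist(ann[prots], use.names = FALSE))
  row <- as.numeric(counts) / length(prots)
  names(row) <- names(counts)
  assign(key, row, envir = db$cache)
  row
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", x$n_proteins, "proteins,",
      length(x$by_term_direct), "directly used terms,",
      length(x$by_term_prop), "terms after propagation\n")
  invisible(x)
}
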