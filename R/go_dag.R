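#' Parse a Gene Ontology OBO file into a DAG
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 file and builds a directed
#' acyclic graph over GO accessions.  Only `is_a` edges define the
#' hierarchy; `part_of`, `regulates` and other relationship types are
#' ignored, which is the minimal reading of "parental terms" and matches
#' how most annotation-propagation pipelines treat the ontology by
#' default.  `alt_id` accessions are recorded and silently resolved to
#' their primary accession by every lookup in this package.  Obsolete
#' terms are kept (so files round-trip) but carry no parents and are
#' never returned by traversal operations.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: a list with elements `ids`
#'   (character vector of primary accessions), `name`, `namespace`,
#'   `obsolete` (named vectors over `ids`), `parents` (named list of
#'   character vectors of `is_a` parents), `roots` (accessions of the
#'   namespace roots: non-obsolete terms with no parents), and `alt_ids`
#'   (named character vector mapping alternate to primary accessions).
#' @seealso [go_ancestors()], [go_propagate()], [write_obo()]
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    stop("no [Term] stanzas found in ", path)
  }
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  names(stanza_ends) <- stanza_starts
  ids <- character(0)
  nm <- character(0)
  ns <- character(0)
  obs <- logical(0)
  parents <- list()
  alt_ids <- character(0)
  for (s in term_starts) {
    block <- lines[(s + 1L):stanza_ends[[as.character(s)]]]
    block <- block[nzchar(block)]
    tag_split <- regmatches(block, regexpr(": ", block), invert = TRUE)
    tags <- vapply(tag_split, `[`, "", 1L)
    vals <- vapply(tag_split, function(x) if (length(x) > 1L) x[[2L]] else "", "")
    id <- vals[tags == "id"][1L]
    if (is.na(id) || !grepl("^GO:[0-9]{7}$", id)) {
      stop("OBO term stanza without a valid GO id near line ", s)
    }
    is_obs <- any(tags == "is_obsolete" & grepl("^true", vals))
    isa <- vals[tags == "is_a"]
    # strip trailing "! name" comments
    isa <- sub("\\s*!.*$", "", isa)
    isa <- trimws(isa)
    ids <- c(ids, id)
    nm <- c(nm, vals[tags == "name"][1L] %||% "")
    ns <- c(ns, vals[tags == "namespace"][1L] %||% "")
    obs <- c(obs, is_obs)
    parents[[id]] <- if (is_obs) character(0) else unique(isa)
    alt <- vals[tags == "alt_id"]
    if (length(alt)) {
      new_alt <- stats::setNames(rep(id, length(alt)), alt)
      alt_ids <- c(alt_ids, new_alt)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicated term id in OBO file: ", ids[duplicated(ids)][1L])
  }
  names(nm) <- ids
  names(ns) <- ids
  names(obs) <- ids
  missing_parents <- setdiff(unique(unlist(parents)), ids)
  if (length(missing_parents)) {
    stop("is_a parent not defined in file: ", missing_parents[1L])
  }
  dag <- structure(
    list(
      ids = ids, name = nm, namespace = ns, obsolete = obs,
      parents = parents,
      roots = ids[!obs & vapply(parents[ids], length, 0L) == 0L],
      alt_ids = alt_ids,
      cache = new.env(parent = emptyenv())
    ),
    class = "go_dag"
  )
  assert_acyclic(dag)
  dag
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

# Kahn topological sort over non-obsolete terms; errors naming one cycle member.
assert_acyclic <- function(dag) {
  live <- dag$ids[!dag$obsolete]
  indeg <- vapply(dag$parents[live], length, 0L)  # edges child -> parent
  children <- split(
    rep(live, lengths(dag$parents[live])),
    unlist(dag$parents[live], use.names = FALSE)
  )
  # process terms whose parents are all processed: reverse Kahn on parent edges
  queue <- live[indeg == 0L]
  done <- 0L
  remaining <- indeg
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    done <- done + 1L
    for (ch in children[[t]] %||% character(0)) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(live)) {
    member <- names(remaining)[remaining > 0L][1L]
    stop("is_a graph contains a cycle involving ", member)
  }
  invisible(TRUE)
}

#' Resolve GO accessions to primary ids
#'
#' Maps alternate accessions to their primary id and errors on accessions
#' unknown to the DAG.
#'
#' @param dag A `go_dag`.
#' @param ids Character vector of GO accessions.
#' @return Character vector of primary accessions, same length as `ids`.
#' @export
resolve_go_ids <- function(dag, ids) {
  out <- ids
  unknown <- !(out %in% dag$ids)
  if (any(unknown)) {
    mapped <- dag$alt_ids[out[unknown]]
    if (anyNA(mapped)) {
      bad <- out[unknown][is.na(mapped)][1L]
      stop("unknown GO accession: ", bad)
    }
    out[unknown] <- mapped
  }
  unname(out)
}

#' Ancestors of a GO term
#'
#' All terms reachable from `term` by following `is_a` parent edges,
#' excluding `term` itself and including the namespace root.  Results are
#' memoised on the DAG.
#'
#' @param dag A `go_dag`.
#' @param term A single GO accession (alternate ids are resolved).
#' @return Sorted character vector of ancestor accessions (empty for a root).
#' @export
go_ancestors <- function(dag, term) {
  id <- resolve_go_ids(dag, term[1L])
  anc_memo(dag, id)
}

anc_memo <- function(dag, id) {
  hit <- get0(id, envir = dag$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- character(0)
  for (p in dag$parents[[id]]) {
    out <- c(out, p, anc_memo(dag, p))
  }
  out <- sort(unique(out))
  assign(id, out, envir = dag$cache)
  out
}

#' Propagate a GO term set to the root
#'
#' Closes a set of terms under the ancestor relation: the result is the
#' input terms plus every `is_a` ancestor up to (and including) the
#' namespace roots.  Idempotent and monotone in the input set.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of GO accessions.
#' @return Sorted character vector: `terms` union all their ancestors.
#' @export
go_propagate <- function(dag, terms) {
  if (length(terms) == 0L) return(character(0))
  ids <- resolve_go_ids(dag, terms)
  anc <- lapply(ids, function(id) anc_memo(dag, id))
  sort(unique(c(ids, unlist(anc, use.names = FALSE))))
}

#' Serialize a GO DAG back to OBO
#'
#' Writes `[Term]` stanzas (sorted by accession, tags in a fixed order) so
#' that fixture DAGs round-trip through [read_obo()].
#'
#' @param dag A `go_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  alt_by_primary <- split(names(dag$alt_ids), unname(dag$alt_ids))
  for (id in sort(dag$ids)) {
    stanza <- c("[Term]", paste0("id: ", id),
                paste0("name: ", dag$name[[id]]),
                paste0("namespace: ", dag$namespace[[id]]))
    for (a in sort(alt_by_primary[[id]] %||% character(0))) {
      stanza <- c(stanza, paste0("alt_id: ", a))
    }
    for (p in sort(dag$parents[[id]])) {
      stanza <- c(stanza, paste0("is_a: ", p, " ! ", dag$name[[p]]))
    }
    if (dag$obsolete[[id]]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$ids), "terms (", sum(x$obsolete), "obsolete ),",
      length(x$roots), "roots,", length(x$alt_ids), "alt_ids\n")
  invisible(x)
}
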