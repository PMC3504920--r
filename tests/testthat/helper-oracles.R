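# Shared toy builders and independent brute-force oracles.

gid <- function(i) sprintf("GO:%07d", i)

# Write an OBO file for a named list id -> character vector of parents.
toy_obo_file <- function(parents, namespace = "molecular_function",
                         obsolete = character(0), alt = character(0)) {
  path <- tempfile(fileext = ".obo")
  out <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    stanza <- c("[Term]", paste0("id: ", id), paste0("name: term ", id),
                paste0("namespace: ", namespace))
    for (a in names(alt)[alt == id]) stanza <- c(stanza, paste0("alt_id: ", a))
    for (p in parents[[id]]) stanza <- c(stanza, paste0("is_a: ", p))
    if (id %in% obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  path
}

toy_dag <- function(parents, ...) read_obo(toy_obo_file(parents, ...))

# root gid(1) with n_children leaves under it
flat_parents <- function(n_children) {
  p <- c(list(character(0)), rep(list(gid(1)), n_children))
  names(p) <- gid(seq_len(n_children + 1L))
  p
}

# Build an annotation_db from a named list protein -> terms via the
# 2-column TSV dialect (exercises the real loader).
toy_db <- function(dag, direct) {
  path <- tempfile(fileext = ".tsv")
  writeLines(unlist(lapply(names(direct), function(p) {
    paste(p, direct[[p]], sep = "\t")
  })), path)
  read_gaf(path, dag)
}

# naive recursive ancestor closure, reading raw parent edges only
oracle_ancestors <- function(parents, id) {
  out <- character(0)
  for (p in parents[[id]]) {
    out <- union(out, union(p, oracle_ancestors(parents, p)))
  }
  sort(out)
}

# quadruple-loop PFP direct score: hits x annotations x candidates, with
# co-occurrence probabilities recomputed by scanning the corpus
oracle_pfp_direct <- function(hits, direct, b = 2, e_max = 100,
                              e_floor = 1e-180) {
  all_terms <- sort(unique(unlist(direct)))
  prots <- names(direct)
  s <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (fa in all_terms) {
    for (h in hits) {
      if (h$e_value > e_max) next
      w <- -log10(max(h$e_value, e_floor)) + b
      for (fj in h$annotations) {
        with_fj <- vapply(prots, function(p) fj %in% direct[[p]], TRUE)
        if (!any(with_fj)) next
        with_both <- vapply(prots, function(p) {
          fj %in% direct[[p]] && fa %in% direct[[p]]
        }, TRUE)
        s[[fa]] <- s[[fa]] + w * sum(with_both) / sum(with_fj)
      }
    }
  }
  s[s > 0]
}

# brute-force two-level ESG enumeration over plain tables:
# searches = named list query -> data.frame(subject, e); ann = named list
# subject -> terms
oracle_esg <- function(query, searches, ann, lw = c(0.5, 0.5),
                       n_first = 10, e_floor = 1e-180, e_max = 100) {
  level <- function(qid, excl) {
    tab <- searches[[qid]]
    if (is.null(tab)) tab <- data.frame(subject = character(0), e = numeric(0))
    tab <- tab[!(tab$subject %in% excl) & tab$e <= e_max, , drop = FALSE]
    tab <- tab[order(tab$e), , drop = FALSE]
    w <- pmax(0, -log10(pmax(tab$e, e_floor)))
    if (nrow(tab) == 0L || sum(w) == 0) return(NULL)
    data.frame(subject = tab$subject, w = w / sum(w))
  }
  s <- new.env(parent = emptyenv())
  add <- function(f, x) assign(f, (get0(f, envir = s) %||% 0) + x, envir = s)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  first <- level(query, query)
  if (is.null(first)) return(numeric(0))
  for (i in seq_len(nrow(first))) {
    sub <- first$subject[[i]]
    for (f in ann[[sub]] %||% character(0)) add(f, lw[[1L]] * first$w[[i]])
    if (i > n_first) next
    second <- level(sub, c(query, sub))
    if (is.null(second)) next
    for (j in seq_len(nrow(second))) {
      for (f in ann[[second$subject[[j]]]] %||% character(0)) {
        add(f, lw[[2L]] * first$w[[i]] * second$w[[j]])
      }
    }
  }
  out <- vapply(ls(s), function(t) get(t, envir = s), 0)
  out[out > 0]
}

# random tiny PFP instance: flat DAG, random corpus, random annotated hits
random_pfp_instance <- function(seed) {
  set.seed(seed)
  n_t <- sample(4:8, 1)
  dag <- toy_dag(flat_parents(n_t))
  terms <- gid(1 + seq_len(n_t))
  prots <- sprintf("P%02d", seq_len(sample(3:8, 1)))
  direct <- lapply(prots, function(p) sort(sample(terms, sample(1:3, 1))))
  names(direct) <- prots
  db <- toy_db(dag, direct)
  n_h <- sample(2:6, 1)
  subj <- sample(c(prots, "UNANN"), n_h, replace = TRUE)
  ev <- 10^stats::runif(n_h, -10, 2.2)
  res <- search_result("QX", subj, ev,
                       lapply(subj, function(s) {
                         if (s == "UNANN") character(0) else direct[[s]]
                       }))
  list(dag = dag, db = db, direct = direct, result = res)
}

# random tiny two-level ESG instance over plain tables + a table provider
random_esg_instance <- function(seed) {
  set.seed(seed)
  terms <- gid(1:6)
  subjects <- sprintf("S%02d", 1:6)
  ann <- lapply(subjects, function(s) sort(sample(terms, sample(0:3, 1))))
  names(ann) <- subjects
  searches <- list()
  mk <- function(n) {
    sub <- sample(subjects, n)
    data.frame(subject = sub, e = 10^stats::runif(n, -8, 1.5))
  }
  searches[["QX"]] <- mk(sample(2:4, 1))
  for (s in subjects) searches[[s]] <- mk(sample(1:3, 1))
  results <- lapply(names(searches), function(q) {
    tab <- searches[[q]]
    search_result(q, tab$subject, tab$e,
                  lapply(tab$subject, function(s) ann[[s]]))
  })
  names(results) <- names(searches)
  list(searches = searches, ann = ann,
       provider = table_search_provider(results),
       fake_db = structure(list(direct = ann), class = "annotation_db"))
}
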