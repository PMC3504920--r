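#' Fixture generation parameters
#'
#' Describes a synthetic benchmark: a random GO DAG (three namespaces), a
#' background annotation corpus, moonlighting query proteins with two
#' planted functions, and a hit table in which each query receives two
#' hit clusters — a strong-similarity cluster carrying the first
#' function's terms and a weak-similarity cluster carrying the second
#' function's terms.  E-values are drawn log-uniformly; the function-2
#' cluster uses the weak half of `e_value_log10_range`, so recovering
#' the second function requires admitting weakly similar sequences (the
#' effect switching to a more permissive substitution matrix has on a
#' real search).  Identical specs produce byte-identical files.
#'
#' @param seed Integer RNG seed (single stream; drives everything).
#' @param n_terms Terms per namespace, including the root (default 40).
#' @param max_parents Maximum is_a parents per non-root term (default 3).
#' @param n_proteins Background corpus proteins (default 100).
#' @param annotations_per_protein Length-2 range of direct annotations
#'   per background protein (default `c(2, 5)`).
#' @param n_queries Number of query proteins (default 19).
#' @param hits_per_cluster Length-2 range of hits per function cluster
#'   (default `c(5, 7)`).
#' @param e_value_log10_range Length-2 log10(E) interval (default
#'   `c(-8, 1)`); cluster 1 samples the strong half, cluster 2 the weak
#'   half.
#' @param moonlighting_fraction Fraction of queries given a second
#'   function (default 1).
#' @param function_overlap Terms labelled `both` per moonlighting query
#'   (default 1).
#' @param preset `"paper-scale"` (the defaults; a 19-protein cohort) or
#'   `"tiny"` (a smaller variant for fast smoke runs); explicit
#'   arguments override the preset.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_terms = 40, max_parents = 3,
                         n_proteins = 100,
                         annotations_per_protein = c(2, 5),
                         n_queries = 19, hits_per_cluster = c(5, 7),
                         e_value_log10_range = c(-8, 1),
                         moonlighting_fraction = 1, function_overlap = 1,
                         preset = c("paper-scale", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    if (missing(n_terms)) n_terms <- 15
    if (missing(n_proteins)) n_proteins <- 30
    if (missing(n_queries)) n_queries <- 4
    if (missing(hits_per_cluster)) hits_per_cluster <- c(3, 4)
  }
  if (n_terms < 3 || n_proteins < 1 || n_queries < 1 ||
      diff(annotations_per_protein) < 0 || diff(hits_per_cluster) < 0 ||
      diff(e_value_log10_range) <= 0 ||
      moonlighting_fraction < 0 || moonlighting_fraction > 1) {
    stop("degenerate fixture spec")
  }
  structure(list(seed = as.integer(seed), n_terms = n_terms,
                 max_parents = max_parents, n_proteins = n_proteins,
                 annotations_per_protein = annotations_per_protein,
                 n_queries = n_queries, hits_per_cluster = hits_per_cluster,
                 e_value_log10_range = e_value_log10_range,
                 moonlighting_fraction = moonlighting_fraction,
                 function_overlap = function_overlap, preset = preset),
            class = "fixture_spec")
}

#' Generate a synthetic benchmark
#'
#' Emits `fixture.obo` (random DAG, terms added in topological order so
#' acyclicity holds by construction), `fixture.gaf` (background corpus
#' plus the hit proteins), `hits.tsv` (BLAST tabular; first- and
#' second-level rows), `truth.tsv` (per-query labels) and
#' `manifest.json` (checksums, planted truth, per-term counts) into
#' `out_dir`.
#'
#' Each moonlighting query gets 3 function-1 terms, 3 function-2 terms,
#' `function_overlap` both-terms and 2 neither-terms.  The first
#' function-1 term annotates every strong-cluster hit (a consensus
#' signal that all three scorers pick up); function-2 terms are assigned
#' round-robin, one per weak-cluster hit, so some of them ride only on
#' high-E hits and are invisible to a strict E-value cutoff.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (a list mirroring `manifest.json`).
#' @export
generate_fixtures <- function(spec = fixture_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  namespaces <- c("molecular_function", "biological_process",
                  "cellular_component")
  go_id <- function(k) sprintf("GO:%07d", k)
  counter <- 0L
  ids <- character(0); ns <- character(0); obs <- logical(0)
  parents <- list(); roots <- character(0)
  for (nsp in namespaces) {
    ns_ids <- go_id(counter + seq_len(spec$n_terms))
    counter <- counter + spec$n_terms
    roots <- c(roots, ns_ids[[1L]])
    parents[[ns_ids[[1L]]]] <- character(0)
    for (k in 2:spec$n_terms) {
      np <- rint(c(1L, min(spec$max_parents, k - 1L)))
      parents[[ns_ids[[k]]]] <- sort(sample(ns_ids[seq_len(k - 1L)], np))
    }
    ids <- c(ids, ns_ids)
    ns <- c(ns, rep(nsp, spec$n_terms))
    obs <- c(obs, rep(FALSE, spec$n_terms))
    # one obsolete term per namespace, to exercise parser handling
    ob <- go_id(counter + 1L)
    counter <- counter + 1L
    ids <- c(ids, ob); ns <- c(ns, nsp); obs <- c(obs, TRUE)
    parents[[ob]] <- character(0)
  }
  names(ns) <- ids; names(obs) <- ids
  live <- ids[!obs]
  nonroot <- setdiff(live, roots)
  # a couple of alt_ids pointing at real terms
  alt_ids <- stats::setNames(sample(nonroot, 2L),
                             go_id(counter + 1:2))
  dag <- structure(
    list(ids = ids,
         name = stats::setNames(paste("synthetic term", seq_along(ids)), ids),
         namespace = ns, obsolete = obs, parents = parents,
         roots = roots, alt_ids = alt_ids,
         cache = new.env(parent = emptyenv())),
    class = "go_dag")
  write_obo(dag, file.path(out_dir, "fixture.obo"))

  # background corpus
  gaf_prot <- character(0); gaf_go <- character(0)
  for (i in seq_len(spec$n_proteins)) {
    p <- sprintf("B%04d", i)
    n_ann <- rint(spec$annotations_per_protein)
    terms <- sample(nonroot, min(n_ann, length(nonroot)))
    gaf_prot <- c(gaf_prot, rep(p, length(terms)))
    gaf_go <- c(gaf_go, terms)
  }

  # moonlighting queries, planted term classes, hit clusters
  lo <- spec$e_value_log10_range[[1L]]
  hi <- spec$e_value_log10_range[[2L]]
  mid <- (lo + hi) / 2
  n_moon <- round(spec$moonlighting_fraction * spec$n_queries)
  truth_rows <- character(0)
  hit_rows <- character(0)
  planted <- list()
  runif_log_e <- function(n, a, b) 10^stats::runif(n, a, b)
  for (q in seq_len(spec$n_queries)) {
    qid <- sprintf("Q%02d", q)
    is_moon <- q <= n_moon
    n_pick <- 3L + (if (is_moon) 3L else 0L) + spec$function_overlap + 2L
    picked <- sample(nonroot, n_pick)
    f1 <- picked[1:3]
    f2 <- if (is_moon) picked[4:6] else character(0)
    off <- 3L + length(f2)
    fb <- if (spec$function_overlap > 0)
      picked[off + seq_len(spec$function_overlap)] else character(0)
    fn_ <- picked[(off + spec$function_overlap + 1L):n_pick]
    truth_rows <- c(
      truth_rows,
      paste(qid, f1, "function1", sep = "\t"),
      if (is_moon) paste(qid, f2, "function2", sep = "\t"),
      if (length(fb)) paste(qid, fb, "both", sep = "\t"),
      paste(qid, fn_, "neither", sep = "\t")
    )
    k1 <- rint(spec$hits_per_cluster)
    k2 <- rint(spec$hits_per_cluster)
    c1 <- sprintf("%sA%02d", qid, seq_len(k1))
    e1 <- sort(runif_log_e(k1, lo, mid))
    for (i in seq_len(k1)) {
      ann <- unique(c(f1[[1L]], sample(f1[-1L], 1L), fb))
      gaf_prot <- c(gaf_prot, rep(c1[[i]], length(ann)))
      gaf_go <- c(gaf_go, ann)
      hit_rows <- c(hit_rows, blast_row(qid, c1[[i]], e1[[i]]))
    }
    # second-level rows: strong-cluster members hit each other
    if (k1 > 1L) {
      for (i in seq_len(k1)) {
        mates <- c1[-i]
        e2l <- runif_log_e(length(mates), lo, mid)
        for (j in seq_along(mates)) {
          hit_rows <- c(hit_rows, blast_row(c1[[i]], mates[[j]], e2l[[j]]))
        }
      }
    }
    cluster2 <- character(0)
    if (is_moon) {
      c2 <- sprintf("%sC%02d", qid, seq_len(k2))
      e2 <- sort(runif_log_e(k2, mid, hi))
      for (i in seq_len(k2)) {
        ann <- f2[[((i - 1L) %% 3L) + 1L]]
        gaf_prot <- c(gaf_prot, c2[[i]])
        gaf_go <- c(gaf_go, ann)
        hit_rows <- c(hit_rows, blast_row(qid, c2[[i]], e2[[i]]))
      }
      cluster2 <- c2
    }
    planted[[qid]] <- list(moonlighting = is_moon, function1 = f1,
                           function2 = f2, both = fb, neither = fn_,
                           cluster1 = c1, cluster2 = cluster2)
  }

  # GAF 2.2: 17 columns, the parser reads 2 (id), 4 (qualifier), 5 (GO), 7 (evidence)
  gaf_lines <- c(
    "!gaf-version: 2.2",
    sprintf("FIX\t%s\t%s\tenables\t%s\tFIX:0001\tIEA\t\t%s\t\t\tprotein\ttaxon:0\t20120101\tFIX\t\t",
            gaf_prot, gaf_prot, gaf_go,
            substr(ns[gaf_go], 1L, 1L))
  )
  writeLines(gaf_lines, file.path(out_dir, "fixture.gaf"))
  writeLines(hit_rows, file.path(out_dir, "hits.tsv"))
  writeLines(c("protein_id\tgo_id\tlabel", truth_rows),
             file.path(out_dir, "truth.tsv"))

  direct_counts <- lapply(split(gaf_prot, gaf_go), function(p) length(unique(p)))
  files <- c("fixture.obo", "fixture.gaf", "hits.tsv", "truth.tsv")
  manifest <- list(
    seed = spec$seed,
    preset = spec$preset,
    spec = unclass(spec),
    n_proteins = length(unique(gaf_prot)),
    n_moonlighting = n_moon,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))),
    term_direct_counts = direct_counts,
    planted = planted
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# sample one integer from an inclusive range (safe for degenerate ranges)
rint <- function(r) {
  if (r[[1L]] >= r[[2L]]) return(as.integer(r[[1L]]))
  sample(r[[1L]]:r[[2L]], 1L)
}

blast_row <- function(q, s, e) {
  paste(q, s, "50.00", "100", "10", "1", "1", "100", "1", "100",
        sprintf("%.3e", e), "100.0", sep = "\t")
}
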