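#' Moonlighting truth labels
#'
#' Reads a 3-column TSV (`protein_id`, `go_id`, `label`) classifying
#' each protein's GO terms into the four moonlighting classes:
#' `function1` (the major function), `function2` (the second function),
#' `both`, and `neither`.  Accessions are resolved against `dag`.
#'
#' @param path Path to the truth TSV (a header row is detected and
#'   skipped; `#` comment lines ignored).
#' @param dag A `go_dag`.
#' @return Named list of class `moonlighting_truth`: protein id -> named
#'   character vector mapping GO accession to label.
#' @export
read_truth <- function(path, dag) {
  if (!file.exists(path)) stop("cannot read truth file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f) && identical(f[[1L]][1:2], c("protein_id", "go_id"))) {
    f <- f[-1L]
  }
  if (length(f) == 0L) stop("no truth rows in ", path)
  bad <- lengths(f) < 3L
  if (any(bad)) stop("malformed truth row: ", lines[bad][1L])
  prot <- vapply(f, `[[`, "", 1L)
  go <- resolve_go_ids(dag, vapply(f, `[[`, "", 2L))
  lab <- vapply(f, `[[`, "", 3L)
  valid <- c("function1", "function2", "both", "neither")
  if (!all(lab %in% valid)) {
    stop("invalid truth label: ", setdiff(lab, valid)[1L])
  }
  out <- lapply(split(seq_along(prot), prot), function(i) {
    stats::setNames(lab[i], go[i])
  })
  structure(out, class = "moonlighting_truth")
}

#' Truth label filters
#'
#' `truth_filter_all` keeps every labelled term; `truth_filter_moonlighting`
#' restricts evaluation to the two moonlighting functions, keeping terms
#' labelled `both` since such a term belongs to each function.
#'
#' @export
truth_filter_all <- c("function1", "function2", "both", "neither")

#' @rdname truth_filter_all
#' @export
truth_filter_moonlighting <- c("function1", "function2", "both")

#' Truth term set under a label filter
#'
#' @param labels Named character vector (GO accession -> label) as stored
#'   in a `moonlighting_truth`.
#' @param filter Character vector of labels to keep.
#' @return Character vector of GO accessions.
#' @export
truth_terms <- function(labels, filter = truth_filter_all) {
  names(labels)[labels %in% filter]
}

#' Predicted term set at a cutoff
#'
#' @param pred A `prediction_set`.
#' @param cutoff Score threshold (terms with score >= cutoff are kept)
#'   or, for `cutoff_type = "fraction"`, a ranked-list fraction passed to
#'   [pfp_fraction_terms()].
#' @param cutoff_type `"score"` (default) or `"fraction"`.
#' @param n_top Ranked-list length for fractional cutoffs (default 1000).
#' @return Character vector of GO accessions.
#' @export
predicted_terms <- function(pred, cutoff, cutoff_type = c("score", "fraction"),
                            n_top = 1000) {
  cutoff_type <- match.arg(cutoff_type)
  if (cutoff_type == "fraction") {
    pfp_fraction_terms(pred, cutoff, n_top)
  } else {
    names(pred$scores)[pred$scores >= cutoff]
  }
}

#' Confusion counts at one cutoff
#'
#' Both the predicted term set at the cutoff and the truth set are
#' propagated to the root of the ontology before counting:
#' `tp = |P & T|`, `fp = |P \ T|`, `fn = |T \ P|`, with
#' precision `tp/(tp+fp)` (NA when nothing is predicted) and recall
#' `tp/(tp+fn)`.  Namespace roots count by default — the literal reading
#' of propagating "to the root" — and can be excluded for a stricter
#' evaluation.
#'
#' @inheritParams predicted_terms
#' @param truth_terms Non-empty character vector of true GO accessions.
#' @param dag A `go_dag`.
#' @param include_roots Count the namespace roots as terms (default
#'   `TRUE`).
#' @return A list of class `pr_point`: `cutoff`, `tp`, `fp`, `fn`,
#'   `precision` (possibly `NA`), `recall`.
#' @export
confusion_at_cutoff <- function(pred, truth_terms, dag, cutoff,
                                include_roots = TRUE,
                                cutoff_type = "score", n_top = 1000) {
  if (length(truth_terms) == 0L) stop("empty truth set")
  P <- go_propagate(dag, predicted_terms(pred, cutoff, cutoff_type, n_top))
  T_ <- go_propagate(dag, truth_terms)
  if (!include_roots) {
    P <- setdiff(P, dag$roots)
    T_ <- setdiff(T_, dag$roots)
  }
  tp <- length(intersect(P, T_))
  fp <- length(setdiff(P, T_))
  fn <- length(setdiff(T_, P))
  structure(
    list(cutoff = cutoff, tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else 0),
    class = "pr_point"
  )
}

#' Precision/recall curve over a cutoff grid
#'
#' For each cutoff, per-protein precision and recall are computed via
#' [confusion_at_cutoff()] with the truth restricted by `truth_filter`,
#' then averaged.  Macro averaging (the default) averages per-protein
#' values: proteins with no prediction at a cutoff have undefined
#' precision and are dropped from the precision mean, but contribute
#' recall 0.  Micro averaging pools the tp/fp/fn counts across proteins
#' instead.
#'
#' @param preds Named list: protein id -> `prediction_set` (one method).
#' @param truths A `moonlighting_truth` covering at least the proteins
#'   in `preds`.
#' @param dag A `go_dag`.
#' @param cutoffs Numeric vector of cutoffs.
#' @param truth_filter Labels to evaluate against (default all four).
#' @param average `"macro"` (default) or `"micro"`.
#' @param include_roots See [confusion_at_cutoff()].
#' @param cutoff_type,n_top See [predicted_terms()].
#' @return A data.frame of class `pr_curve`: `cutoff`, `precision`,
#'   `recall`, `n_proteins` (with non-empty filtered truth),
#'   `n_precision` (with defined precision; macro mode).
#' @export
pr_curve <- function(preds, truths, dag, cutoffs,
                     truth_filter = truth_filter_all,
                     average = c("macro", "micro"),
                     include_roots = TRUE, cutoff_type = "score",
                     n_top = 1000) {
  average <- match.arg(average)
  if (length(preds) == 0L) stop("no proteins to evaluate")
  missing_truth <- setdiff(names(preds), names(truths))
  if (length(missing_truth)) {
    stop("no truth labels for protein ", missing_truth[1L])
  }
  tsets <- lapply(names(preds), function(p) truth_terms(truths[[p]], truth_filter))
  names(tsets) <- names(preds)
  use <- names(preds)[lengths(tsets) > 0L]
  if (length(use) == 0L) stop("no protein has truth terms under this filter")
  rows <- lapply(cutoffs, function(ct) {
    pts <- lapply(use, function(p) {
      confusion_at_cutoff(preds[[p]], tsets[[p]], dag, ct,
                          include_roots, cutoff_type, n_top)
    })
    prec <- vapply(pts, `[[`, 0, "precision")
    rec <- vapply(pts, `[[`, 0, "recall")
    if (average == "macro") {
      data.frame(cutoff = ct,
                 precision = if (all(is.na(prec))) NA_real_
                             else mean(prec, na.rm = TRUE),
                 recall = mean(rec),
                 n_proteins = length(use),
                 n_precision = sum(!is.na(prec)))
    } else {
      tp <- sum(vapply(pts, `[[`, 0, "tp"))
      fp <- sum(vapply(pts, `[[`, 0, "fp"))
      fn <- sum(vapply(pts, `[[`, 0, "fn"))
      data.frame(cutoff = ct,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else 0,
                 n_proteins = length(use),
                 n_precision = length(use))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Per-protein recall at method-specific fixed cutoffs
#'
#' Evaluates each method at its fixed operating point — by default the
#' PFP ranked-list fraction 0.5 (at most 500 of the top 1000 terms), the
#' ESG score 0.35, and the PSI-BLAST transfer score 4 (E-value 0.01).
#' A (protein, method) pair with no predictions is recorded as recall 0
#' and flagged `empty`.
#'
#' @param preds_by_method Named list: method tag -> (named list protein
#'   -> `prediction_set`).
#' @param truths A `moonlighting_truth`.
#' @param dag A `go_dag`.
#' @param fixed_cutoffs Named numeric vector of per-method cutoffs
#'   (default `c(pfp = 0.5, esg = 0.35, blast = 4)`).
#' @param cutoff_types Named character vector mapping method to
#'   `"score"`/`"fraction"` (default: fraction for pfp, score otherwise).
#' @param truth_filter,include_roots,n_top As in [pr_curve()].
#' @return Long data.frame: `protein`, `method`, `recall`, `empty`.
#' @export
per_protein_recall <- function(preds_by_method, truths, dag,
                               fixed_cutoffs = c(pfp = 0.5, esg = 0.35,
                                                 blast = 4),
                               cutoff_types = c(pfp = "fraction",
                                                esg = "score",
                                                blast = "score"),
                               truth_filter = truth_filter_all,
                               include_roots = TRUE, n_top = 1000) {
  proteins <- sort(unique(unlist(lapply(preds_by_method, names))))
  rows <- list()
  for (m in names(preds_by_method)) {
    ct <- fixed_cutoffs[[m]]
    cty <- cutoff_types[[m]] %||% "score"
    for (p in proteins) {
      tt <- truth_terms(truths[[p]] %||% character(0), truth_filter)
      if (length(tt) == 0L) next
      pred <- preds_by_method[[m]][[p]]
      if (is.null(pred) || length(pred$scores) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p, method = m, recall = 0, empty = TRUE)
        next
      }
      pt <- confusion_at_cutoff(pred, tt, dag, ct, include_roots, cty, n_top)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, method = m, recall = pt$recall,
        empty = length(predicted_terms(pred, ct, cty, n_top)) == 0L)
    }
  }
  do.call(rbind, rows)
}

#' Write a precision/recall curve to TSV
#'
#' @param curve A `pr_curve` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(curve, path) {
  utils::write.table(format(curve, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
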