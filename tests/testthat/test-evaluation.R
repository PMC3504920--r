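# two namespaces: root gid(1) with children gid(2..5); root gid(10) with
# children gid(11..13)
eval_dag <- function() {
  p <- c(list(character(0)), rep(list(gid(1)), 4),
         list(character(0)), rep(list(gid(10)), 3))
  names(p) <- gid(c(1:5, 10:13))
  toy_dag(p)
}

pred_of <- function(scores, method = "blast") prediction_set("q", scores, method)

test_that("confusion counts follow set arithmetic on propagated sets", {
  dag <- eval_dag()
  truth <- gid(c(3, 4, 5))
  # P == T after closure
  perfect <- pred_of(stats::setNames(c(9, 9, 9), gid(c(3, 4, 5))))
  pt <- confusion_at_cutoff(perfect, truth, dag, 4)
  expect_equal(pt$precision, 1)
  expect_equal(pt$recall, 1)

  # flat namespace: P = {2,3,4}+root, T = {3,4,5}+root
  pred <- pred_of(stats::setNames(c(9, 9, 9), gid(c(2, 3, 4))))
  pt2 <- confusion_at_cutoff(pred, truth, dag, 4)
  expect_equal(c(pt2$tp, pt2$fp, pt2$fn), c(3, 1, 1))
  expect_equal(pt2$precision, 3 / 4)
  expect_equal(pt2$recall, 3 / 4)
  # the shared root stops counting when roots are excluded
  pt3 <- confusion_at_cutoff(pred, truth, dag, 4, include_roots = FALSE)
  expect_equal(c(pt3$tp, pt3$fp, pt3$fn), c(2, 1, 1))

  # cutoff above every score: nothing predicted
  pt4 <- confusion_at_cutoff(pred, truth, dag, 99)
  expect_equal(pt4$recall, 0)
  expect_true(is.na(pt4$precision))
  expect_error(confusion_at_cutoff(pred, character(0), dag, 4), "empty truth")
})

test_that("tp + fn equals the propagated truth size at every cutoff", {
  dag <- eval_dag()
  truth <- gid(c(3, 11))
  t_size <- length(go_propagate(dag, truth))
  pred <- pred_of(stats::setNames(c(10, 6, 2), gid(c(2, 3, 12))))
  for (ct in seq(0, 12, by = 0.5)) {
    pt <- confusion_at_cutoff(pred, truth, dag, ct)
    expect_identical(pt$tp + pt$fn, t_size)
  }
})

test_that("a perfect predictor traces a flat (1,1) curve", {
  dag <- eval_dag()
  truths <- structure(list(q = stats::setNames("function1", gid(3))),
                      class = "moonlighting_truth")
  preds <- list(q = pred_of(stats::setNames(99, gid(3))))
  curve <- pr_curve(preds, truths, dag, cutoffs = c(1, 50, 99))
  expect_equal(curve$precision, rep(1, 3))
  expect_equal(curve$recall, rep(1, 3))
})

test_that("macro and micro averages agree with a per-protein loop oracle", {
  d <- withr::local_tempdir()
  generate_fixtures(fixture_spec(seed = 11, preset = "tiny"), d)
  dag <- read_obo(file.path(d, "fixture.obo"))
  db <- read_gaf(file.path(d, "fixture.gaf"), dag)
  hits <- read_blast_tab(file.path(d, "hits.tsv"), db)
  truths <- read_truth(file.path(d, "truth.tsv"), dag)
  qs <- intersect(names(hits), names(truths))
  preds <- lapply(hits[qs], blast_transfer)
  cutoffs <- c(4, 5, 6)
  curve <- pr_curve(preds, truths, dag, cutoffs)
  for (k in seq_along(cutoffs)) {
    pts <- lapply(qs, function(q) {
      confusion_at_cutoff(preds[[q]], truth_terms(truths[[q]]), dag,
                          cutoffs[[k]])
    })
    rec <- vapply(pts, `[[`, 0, "recall")
    prec <- vapply(pts, `[[`, 0, "precision")
    expect_equal(curve$recall[[k]], mean(rec))
    expect_equal(curve$precision[[k]], mean(prec, na.rm = TRUE))
  }
  micro <- pr_curve(preds, truths, dag, cutoffs, average = "micro")
  tp <- sum(vapply(qs, function(q) {
    confusion_at_cutoff(preds[[q]], truth_terms(truths[[q]]), dag, 4)$tp
  }, 0))
  fp <- sum(vapply(qs, function(q) {
    confusion_at_cutoff(preds[[q]], truth_terms(truths[[q]]), dag, 4)$fp
  }, 0))
  expect_equal(micro$precision[[1L]], tp / (tp + fp))
})

test_that("the all-labels filter is identical to an unfiltered run", {
  d <- withr::local_tempdir()
  generate_fixtures(fixture_spec(seed = 12, preset = "tiny"), d)
  dag <- read_obo(file.path(d, "fixture.obo"))
  db <- read_gaf(file.path(d, "fixture.gaf"), dag)
  hits <- read_blast_tab(file.path(d, "hits.tsv"), db)
  truths <- read_truth(file.path(d, "truth.tsv"), dag)
  qs <- intersect(names(hits), names(truths))
  preds <- lapply(hits[qs], blast_transfer)
  c_all <- pr_curve(preds, truths, dag, c(4, 6), truth_filter = truth_filter_all)
  c_unf <- pr_curve(preds, truths, dag, c(4, 6),
                    truth_filter = c("function1", "function2", "both", "neither"))
  expect_identical(c_all, c_unf)
})

test_that("recall decomposes across disjoint function-1/function-2 namespaces", {
  dag <- eval_dag()
  # function 1 lives under gid(1), function 2 under gid(10)
  labels <- stats::setNames(c("function1", "function1", "function2"),
                            gid(c(2, 3, 11)))
  pred <- pred_of(stats::setNames(c(9, 9), gid(c(2, 11))))
  tp_of <- function(filter) {
    confusion_at_cutoff(pred, truth_terms(labels, filter), dag, 4,
                        include_roots = FALSE)$tp
  }
  expect_identical(tp_of(c("function1", "function2", "both")),
                   tp_of("function1") + tp_of("function2"))
})

test_that("per-protein recall matches recomputation and flags empty methods", {
  d <- withr::local_tempdir()
  generate_fixtures(fixture_spec(seed = 13, preset = "tiny"), d)
  dag <- read_obo(file.path(d, "fixture.obo"))
  db <- read_gaf(file.path(d, "fixture.gaf"), dag)
  hits <- read_blast_tab(file.path(d, "hits.tsv"), db)
  truths <- read_truth(file.path(d, "truth.tsv"), dag)
  qs <- intersect(names(hits), names(truths))
  preds <- list(
    pfp = lapply(hits[qs], function(h) pfp_score(h, db, dag)),
    blast = lapply(hits[qs], blast_transfer),
    esg = stats::setNames(
      lapply(qs, function(q) prediction_set(q, method = "esg")), qs)
  )
  tab <- per_protein_recall(preds, truths, dag)
  expect_setequal(unique(tab$method), c("pfp", "blast", "esg"))
  # empty prediction sets score recall 0 and carry the flag
  esg_rows <- tab[tab$method == "esg", ]
  expect_true(all(esg_rows$recall == 0) && all(esg_rows$empty))
  # recomposition oracle: the fixed-cutoff recalls come from confusion_at_cutoff
  for (q in qs) {
    expect_equal(
      tab$recall[tab$method == "blast" & tab$protein == q],
      confusion_at_cutoff(preds$blast[[q]], truth_terms(truths[[q]]),
                          dag, 4)$recall)
    expect_equal(
      tab$recall[tab$method == "pfp" & tab$protein == q],
      confusion_at_cutoff(preds$pfp[[q]], truth_terms(truths[[q]]),
                          dag, 0.5, cutoff_type = "fraction")$recall)
  }
  # full-truth predictor reaches recall 1
  full <- list(blast = lapply(qs, function(q) {
    prediction_set(q, stats::setNames(
      rep(9, length(truths[[q]])), names(truths[[q]])), "blast")
  }))
  names(full$blast) <- qs
  tab_full <- per_protein_recall(full, truths, dag)
  expect_true(all(tab_full$recall == 1))
})

test_that("truth files parse with labels and reject malformed input", {
  dag <- eval_dag()
  path <- tempfile()
  writeLines(c("protein_id\tgo_id\tlabel",
               paste("q1", gid(2), "function1", sep = "\t"),
               paste("q1", gid(11), "function2", sep = "\t"),
               paste("q1", gid(3), "both", sep = "\t")), path)
  tr <- read_truth(path, dag)
  expect_identical(truth_terms(tr$q1, "function2"), gid(11))
  expect_setequal(truth_terms(tr$q1, truth_filter_moonlighting),
                  gid(c(2, 11, 3)))
  writeLines(paste("q1", gid(2), "primary", sep = "\t"), path)
  expect_error(read_truth(path, dag), "invalid truth label")
})
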