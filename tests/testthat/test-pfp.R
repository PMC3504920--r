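test_that("direct scoring reproduces hand-evaluated co-occurrence sums", {
  dag <- toy_dag(flat_parents(4))
  # f1 = gid(2) co-occurs only with itself
  db <- toy_db(dag, list(p1 = gid(2)))
  res <- search_result("q", "p1", 0.01, list(gid(2)))
  pred <- pfp_direct_score(res, db)
  expect_equal(pred$scores, c("GO:0000002" = 4))

  # a hit at the E-value ceiling weighs exactly 0 and yields nothing
  res100 <- search_result("q", "p1", 100, list(gid(2)))
  expect_length(pfp_direct_score(res100, db)$scores, 0L)

  # additivity over hits: two identical hits at E = 1 give 2 * (0 + 2) * 1
  res2 <- search_result("q", c("p1", "p1"), c(1, 1), list(gid(2), gid(2)))
  expect_equal(pfp_direct_score(res2, db)$scores, c("GO:0000002" = 4))
})

test_that("candidate terms are everything co-annotated with a hit annotation", {
  dag <- toy_dag(flat_parents(4))
  db <- toy_db(dag, list(p1 = c(gid(2), gid(3)), p2 = gid(2)))
  res <- search_result("q", "p2", 0.01, list(gid(2)))
  pred <- pfp_direct_score(res, db)
  expect_equal(pred$scores[[gid(2)]], 4 * 1)      # P(f2|f2) = 1
  expect_equal(pred$scores[[gid(3)]], 4 * 0.5)    # P(f3|f2) = 1/2
})

test_that("an annotation unseen in the corpus contributes only the fallback", {
  dag <- toy_dag(flat_parents(4))
  db <- toy_db(dag, list(p1 = gid(2)))
  res <- search_result("q", "x", 0.01, list(gid(4)))  # gid(4) not in corpus
  expect_length(pfp_direct_score(res, db)$scores, 0L)
  cfg <- pfp_config(cond_prob_fallback = 0.5)
  expect_equal(pfp_direct_score(res, db, cfg)$scores, c("GO:0000004" = 2))
})

test_that("parental propagation applies the annotation-proportion rule once per descendant", {
  # chain root <- B: direct(B) = 4, propagated counts B = 5, A(root) = 10
  dag <- toy_dag(list("GO:0000001" = character(0),
                      "GO:0000002" = "GO:0000001"))
  direct_ann <- c(
    stats::setNames(rep(list(gid(2)), 5), sprintf("b%d", 1:5)),
    stats::setNames(rep(list(gid(1)), 5), sprintf("a%d", 1:5))
  )
  db <- toy_db(dag, direct_ann)
  expect_identical(term_count(db, gid(2), TRUE), 5L)
  expect_identical(term_count(db, gid(1), TRUE), 10L)
  res <- search_result("q", "b1", 0.01, list(gid(2)))
  direct <- pfp_direct_score(res, db)
  expect_equal(direct$scores[[gid(2)]], 4)
  raw <- pfp_propagate_parents(direct, dag, db)
  expect_equal(raw$scores[[gid(2)]], 4)
  expect_equal(raw$scores[[gid(1)]], 4 * 5 / 10)
  # the wrapper chains both steps
  expect_equal(pfp_score(res, db, dag)$scores, raw$scores)
})

test_that("a diamond descendant contributes once, not once per path", {
  parents <- list("GO:0000001" = character(0),
                  "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000001",
                  "GO:0000004" = c("GO:0000002", "GO:0000003"))
  dag <- toy_dag(parents)
  db <- toy_db(dag, list(p1 = gid(4), p2 = gid(1)))
  res <- search_result("q", "p1", 0.01, list(gid(4)))
  direct <- pfp_direct_score(res, db)
  raw <- pfp_propagate_parents(direct, dag, db)
  s <- direct$scores[[gid(4)]]
  n4 <- term_count(db, gid(4), TRUE)
  n1 <- term_count(db, gid(1), TRUE)
  # root receives exactly one proportion-scaled contribution from gid(4)
  expect_equal(raw$scores[[gid(1)]], s * n4 / n1)
  # raw score never falls below the direct score
  for (f in names(direct$scores)) {
    expect_gte(raw$scores[[f]], direct$scores[[f]])
  }
})

test_that("direct scores equal the quadruple-loop oracle on random instances", {
  for (seed in 1:20) {
    inst <- random_pfp_instance(seed)
    pred <- pfp_direct_score(inst$result, inst$db)
    oracle <- oracle_pfp_direct(inst$result$hits, inst$direct)
    expect_equal(pred$scores[sort(names(pred$scores))],
                 oracle[sort(names(oracle))], tolerance = 1e-12)
    expect_true(all(pred$scores >= 0))
  }
})

test_that("rank-cutoff prefixes are nested, capped, and tie-broken by accession", {
  scores <- stats::setNames(c(5, 5, 4, 3, 2, 1, 0.5),
                            gid(c(7, 2, 3, 4, 5, 6, 8)))
  pred <- prediction_set("q", scores, "pfp")
  cuts <- pfp_rank_cutoffs(pred, n_top = 1000, interval = 10)
  expect_length(cuts, 100L)
  expect_length(cuts[[1L]], 7L)           # capped at the list length
  # ties at equal score resolve by ascending accession
  expect_identical(pfp_ranked_terms(pred)[1:2], gid(c(2, 7)))
  # nesting across the grid
  for (i in seq_len(length(cuts) - 1L)) {
    expect_true(all(cuts[[i]] %in% cuts[[i + 1L]]))
  }
  # the fractional reading: 0.5 of a top-1000 list is at most 500 terms
  expect_identical(pfp_fraction_terms(pred, 0.5), pfp_ranked_terms(pred))
  big <- prediction_set("q", stats::setNames(seq_len(1000) / 1000,
                                             gid(1:1000)), "pfp")
  expect_length(pfp_fraction_terms(big, 0.5), 500L)
  expect_length(pfp_rank_cutoffs(big)[["1000"]], 1000L)
  expect_identical(pfp_rank_cutoffs(prediction_set("q", method = "pfp")),
                   list())
})
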