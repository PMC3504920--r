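---
title: "Methods: GO-term scorers and moonlighting evaluation in moonscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO-term scorers and moonlighting evaluation in moonscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonscore)
```

`moonscore` scores GO terms for a query protein from the annotations of
its sequence-similarity hits, and evaluates how well such scorers recover
the two functions of moonlighting proteins.  This vignette describes the
models, their assumptions, the tunable parameters, and the design
decisions taken where the methods' published descriptions leave room.

## The ontology model

The Gene Ontology is held as a DAG over accessions with `is_a` parent
edges only.  `part_of`, `regulates` and other relationship types are
ignored: "parental terms" is read minimally, annotation propagation over
`is_a` alone is the most conservative closure, and nothing downstream
depends on richer relation semantics.  The three namespaces are disjoint
DAGs; since `is_a` edges never cross namespaces, propagation stays within
a term's own aspect automatically, and all three aspects are treated
uniformly (the evaluation can be restricted by label, not by namespace —
restricting by aspect was considered and left out because every protocol
step is aspect-symmetric).  Obsolete terms are parsed but carry no
parents and are never reached by traversal; alternate accessions are
resolved to primary ids at every entry point, because annotation corpora
routinely contain them.

Propagation (`go_propagate()`) closes a term set under the ancestor
relation, up to and including the namespace root.  It is idempotent and
monotone, which the evaluation relies on: nested prediction sets stay
nested after propagation, hence recall is monotone along a cutoff grid.

## PFP

The direct score of a candidate term $f_a$ is

$$ s(f_a) = \sum_{i=1}^{N}\sum_{j=1}^{N_{func}(i)}
   \bigl(-\log_{10} E_i + b\bigr)\, P(f_a \mid f_j) $$

over hits $i$ with $E_i \le e_{max}$ and their annotations $f_j$.

* `e_max = 100`, `b = log10(e_max) = 2` — the weight of the weakest
  admissible hit is exactly 0 and all scores are non-negative.  The
  constructor warns if the coupling is broken.
* `e_floor = 1e-180` clamps E-values reported as 0; without it a single
  zero E-value would dominate every cutoff grid with an infinite score.
* $P(f_a|f_j)$ is the co-annotation fraction among proteins directly
  annotated with $f_j$.  The **direct** view is the default: on the
  propagated view every ancestor co-occurs with all of its descendants'
  proteins, which collapses the statistic.  A `cond_prob_view` switch
  exposes the propagated variant.
* When $f_j$ annotates no corpus protein the conditional is undefined;
  the hit annotation then contributes `cond_prob_fallback` (default 0)
  to itself only.  No corpus evidence, no candidate expansion.
* The candidate universe is every term co-annotated with some observed
  $f_j$ — identical to scanning the whole ontology, since all other
  terms score 0.

Parental propagation then forms the raw score:
$raw(p) = direct(p) + \sum_{f_a} direct(f_a)\, n(f_a)/n(p)$ over the
*set* of directly scored descendants $f_a$ of $p$, with $n(\cdot)$ the
propagated annotation counts.  Two choices here were genuinely open:

* each descendant contributes **once**, regardless of how many DAG paths
  connect it to $p$ — annotation-count proportions are path-independent
  quantities, so multiplying by path multiplicity would be an artifact;
* only direct scores are transferred, never already-propagated ones —
  cascading through intermediate ancestors would count a descendant once
  per intermediate level.

Ancestors with zero propagated count cannot receive the proportion rule
and are skipped with a warning.  Raw scores therefore never fall below
direct scores, a property the tests pin.

PFP predictions are ranked (descending score, ties broken by ascending
accession for determinism) and cut by list position: the grid takes the
top 1000 terms at intervals of 10, and a fractional cutoff $c$ keeps the
first $round(c \cdot 1000)$ terms — the reading under which a cutoff of
0.5 yields at most 500 predictions.  Absolute score cutoffs remain
available through the evaluation's `cutoff_type = "score"`.

## ESG

Two search levels.  Within a level, a hit's weight is
$\max(0, -\log_{10} E)$ normalized to sum to 1 over the level's hits;
hits with $E \ge 1$ are clamped to weight 0 rather than given a negative
"proportion", and a level with no positive weight is degenerate.  A
term's score mixes the annotating weight mass of the two levels:

$$ score(f) = a_1 \sum_i w_i\,[f \in ann_i]
            + a_2 \sum_i w_i \sum_j v_{ij}\,[f \in ann_{ij}] $$

The combination rule and expansion breadth are stated only loosely in
the method's description, so both are explicit configuration:

* `level_weights` $(a_1, a_2) = (0.5, 0.5)$ by default.  A convex
  mixture is the simplest combination that guarantees the documented
  $[0,1]$ score range, with the bound attained exactly when one term
  annotates every hit at both levels.
* `n_first_level = 10` hits seed second-level searches.  The seed itself
  and the original query are removed from second-level hit lists — the
  query must never serve as its own evidence.
* A first-level hit contributes its annotations whether or not its
  expansion succeeds; a failed or degenerate expansion forfeits only
  that seed's second-level mass (no renormalization, keeping the score
  a conservative underestimate rather than silently reweighting).

Scorers consume a *search provider* contract rather than a search
binary; the table-backed provider over parsed BLAST tabular files is the
default and the only one tests use.

## PSI-BLAST baseline

Annotated hits with E-value **strictly** better than 0.01 transfer their
terms, scored $-\log_{10} E + 2$; a term reached by several hits keeps
its best hit's score (per-hit provenance — summing would re-invent PFP's
additivity).  The boundary hit at exactly 0.01 is excluded and tested
explicitly.  Recall curves use 100 evenly spaced score cutoffs from 4
(E = 0.01) to 45 (E = 1e-43).  Substitution-matrix variants differ only
in the upstream search; the scoring records a matrix tag for reporting.

## Evaluation protocol

Predictions above a cutoff and the truth set are both propagated to the
root before counting; precision = TP/(TP+FP), recall = TP/(TP+FN).
Decisions taken where the protocol is under-specified:

* **Macro averaging** over proteins is the default (a per-protein mean
  matches the companion per-protein recall view); pooled-count micro
  averaging is behind a flag.
* **Roots count** by default — the literal reading of propagating "to
  the root" — with an `include_roots = FALSE` flag for the stricter
  variant.
* A protein with an empty prediction set has undefined precision
  (dropped from the precision mean) but contributes recall 0 — keeping
  recall honest without manufacturing 0/0 precision.
* The moonlighting filter keeps labels {function1, function2, both}: a
  `both` term belongs to each function, and excluding it would penalize
  correct shared predictions.  The all-labels filter is the identity.
* Fixed operating points follow the methods' conventions: PFP fraction
  0.5, ESG score 0.35, PSI-BLAST E = 0.01 (transfer score 4).

## The synthetic benchmark

`generate_fixtures()` emulates a moonlighting evaluation cohort without
any external database.  Defaults, chosen once as a realistic desk-scale
study and not revisited:

* 3 namespaces × 40 terms, each non-root term drawing 1–3 parents from
  earlier terms (topological-order construction makes acyclicity hold by
  construction rather than by rejection);
* 100 background proteins with 2–5 direct annotations each — enough for
  non-trivial co-occurrence statistics at desk scale;
* 19 moonlighting queries, echoing the size of the experimentally
  curated cohorts such studies use; per query, 3 function-1 terms,
  3 function-2 terms, 1 shared (`both`) term and 2 `neither` terms;
* per query, two hit clusters of 5–7 hits with E-values log-uniform in
  $[10^{-8}, 10]$: the function-1 cluster from the strong half, the
  function-2 cluster from the weak half.  The first function-1 term
  annotates every strong hit (a consensus signal all three scorers
  recover); function-2 terms ride round-robin on single weak hits, so
  some exist only on hits beyond E = 0.01.  This plants the qualitative
  effect of admitting weakly similar sequences (as a more permissive
  substitution matrix does in a real search): widening the admitted
  E-value range strictly increases function-2 recall for the transfer
  baseline.  Strong-cluster members also hit each other, giving ESG a
  coherent second level.

A single seeded RNG stream and fixed file-emission order make fixture
output byte-identical per spec; the manifest records checksums, planted
term classes and per-term counts so loaders can be audited against the
generator.

What the fixtures do **not** emulate: real sequences and alignment
statistics, E-value correlation between related hits, realistic GO depth
(40-term namespaces are far shallower than the real ontology),
evidence-code structure, or annotation incompleteness.  Passing tests
demonstrate correctness of the scoring and evaluation machinery and
recovery of planted signal — not predictive performance on real
proteomes, which depends on the search database and annotation snapshot.

## Numerical and degenerate-input choices

* Logarithms are base 10 throughout (forced by $b = \log_{10} 100$).
* E = 0 clamps to `e_floor = 1e-180` (weight 182 at $b = 2$).
* Ranking ties break by ascending accession; all outputs are sorted so
  files are byte-stable.
* Empty hit lists yield empty prediction sets, not errors; empty truth
  sets are errors (evaluation would be meaningless).
* Self-hits are dropped at parse time — keeping the query among its own
  evidence would leak the answer.
* Problem sizes used by the shipped tests: toy DAGs of 3–10 terms for
  hand-evaluated examples, random instances of ≤ 8 terms / ≤ 8 proteins
  for oracle equivalence, and the 19-query paper-scale fixture for
  protocol-level properties.

## Known limitations

* Only `is_a` edges; no relationship-type reasoning or GO slims.
* ESG's inter-level combination and expansion breadth are documented
  interpretations (configurable), not reverse-engineered constants.
* The PSI-BLAST adapter boundary is a contract: no external binary is
  invoked anywhere in the package or its tests.
* Micro-averaged curves and root-excluded counting are provided but
  lightly exercised compared to the macro/root-included defaults.
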