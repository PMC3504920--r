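Package: moonscore
Title: Sequence-Based GO Function Prediction Scorers for Moonlighting Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three sequence-based automatic function prediction
    scorers over the Gene Ontology: the PFP co-occurrence score with upward
    parental propagation, the two-level Extended Similarity Group (ESG)
    score, and a PSI-BLAST annotation-transfer baseline ranked by
    -log10(E) + 2.  Includes an OBO parser with ancestor propagation, a
    GAF annotation corpus with co-occurrence statistics, BLAST tabular
    readers, a GO-propagated precision/recall evaluation protocol for
    proteins with two labelled (moonlighting) functions, and a deterministic
    synthetic fixture generator with planted dual-function signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
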