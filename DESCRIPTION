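Package: GOmology
Title: Homology-Based Gene Ontology Term Prediction and Assessment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations of proteins by
    nearest-neighbor transfer from precomputed homology hit tables, and
    assesses such predictions against experimentally validated
    annotations. Implements three k-nearest-neighbor predictors that
    transfer GO terms from PSI-BLAST hits, four reference baselines
    (term-frequency priors, a random-neighbor prior, a maximum-identity
    BLAST transfer and a GOtcha-style I-score transfer), a weighted
    least-squares meta-combiner trained with a two-fold protocol, and
    three recall-precision assessment measures (top-20, threshold sweep
    and a leaf-based threshold sweep that scores only the most specific
    predicted terms) summarised by the maximum F1 score. A seeded
    synthetic-benchmark generator produces toy ontologies, annotation
    databases and homology hit tables so that the whole stack is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, MASS
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
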