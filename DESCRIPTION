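Package: trifun
Title: Protein Function Prediction from Domain-Function Associations in
    Tripartite Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein function from domain composition by mining
    tripartite domain-protein-function annotation networks. Domain-function
    association strengths are computed with four indices (Jaccard, Simpson,
    Pearson correlation coefficient on binary profiles, and the hypergeometric
    index), standardized, and combined per protein with Stouffer's Z method or
    Fisher's combined probability test to produce ranked, range-normalized
    function predictions. Includes protein-centric benchmark evaluation
    (Fmax, Smin weighted by information accretion, coverage; full and partial
    modes), pooled precision-recall self-prediction evaluation, a frequency
    naive baseline, a minimal OBO ontology reader with ancestor propagation,
    and seeded synthetic-network generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, FunctionalPrediction, GO, Network, Pathways, Annotation
RoxygenNote: 7.3.3
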