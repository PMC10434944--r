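Package: panaxnet
Title: Environment-to-Saponin Co-Expression Networks and White-Box
    Prediction for Panax ginseng
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted transcript co-expression analysis (power adjacency,
    topological overlap, module detection and eigengenes), construction of
    a layered correlation-directed graph linking environmental factors,
    transcript co-expression modules and ginsenoside (saponin) contents,
    compilation of that graph into a topology-constrained feed-forward
    ("white-box") neural network with training, evaluation and edge-weight
    perturbation, and validity testing via transcript-to-module mapping and
    a chi-square independence test.  Includes a synthetic-data generator
    with known ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
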