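Package: hdbn
Title: High-Definition Brain Network Analysis of Mouse Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Group comparison of diffusion-tractography mouse connectomes over
    a bilateral 72-region parcellation: per-animal streamline-count adjacency
    matrices, ipsilateral and contralateral hemisphere views, weighted
    graph-theory characterization (density, Onnela clustering, transitivity,
    characteristic path length, global and local efficiency, strength
    assortativity, rich club, and small-worldness against degree-preserving
    rewired nulls), tensor-eigenvalue diffusivity scalars (FA, MD, AD, RD)
    with region-wise tests, an edgewise 630-pair comparison with a zero
    filter, log(x+1) transform, pooled t-tests, Benjamini-Hochberg FDR and
    signed p-value matrices, hypothesis-driven circuit comparisons, and a
    zero-inflated lognormal cohort simulator so every stage is testable
    without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
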