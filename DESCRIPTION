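Package: dosesig
Title: Dose-Responsive Expression Signatures, Connectivity Mapping and
    Pathway Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end transcriptomic inference chain for identifying
    the active component of a complex treatment from dose-response
    expression data: microarray-style preprocessing (background filtering,
    quantile normalization, duplicate-probe collapsing, UPGMA display
    clustering), model-profile mining of dose-monotone expression patterns
    with permutation false discovery rates, a local Connectivity-Map-style
    scoring engine (two-sided Kolmogorov-Smirnov tag enrichment against
    rank-ordered reference instances), over-representation analysis with
    the EASE-adjusted Fisher test, repressor-signed pathway activity
    scoring, topology-aware signaling pathway impact analysis, and Markov
    clustering of functional gene networks.  A synthetic-data module
    plants ground truth (reciprocal dose-monotone gene blocks, mimic and
    decoy compendium instances, enriched gene sets, signed pathway
    topologies) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
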