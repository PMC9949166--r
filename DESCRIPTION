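Package: prebioscreen
Title: Precision Prebiotic Screening with Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational screening for precision prebiotics: nutritional
    compounds that selectively boost one target member of a microbial
    community. Provides a flux balance analysis (FBA) engine with
    parsimonious total-flux minimization, metabolic uptake-niche analysis
    with community subsampling, a merged-community FBA formulation, a
    minimal individual-based spatial simulator of bacterial co-culture,
    and a decision layer that intersects the three screening arms, cross
    references Biolog phenotype data, performs compound-class enrichment
    with Fisher's exact test, and compares observed against expected host
    colonization proportions. A synthetic metabolic-model generator with
    planted ground truth makes every pipeline stage testable without
    external model reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
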