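Package: periphyton
Title: Abundant-Taxa Periphyton Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how abundant taxa shape paddy-soil periphyton
    communities. Covers Box-Behnken response-surface optimization of a
    cultivation system (quadratic fit, Type III ANOVA with lack-of-fit,
    constrained optimization of culture conditions), abundant/rare OTU
    partitioning with alpha-diversity estimators (Chao1, ACE, Shannon) and
    STAMP-style group comparison, Sloan neutral community model fitting with
    bootstrap confidence intervals, beta nearest taxon index (betaNTI) null
    models for community assembly inference, and high-throughput qPCR gene-chip
    quantification of carbon, nitrogen, phosphorus and sulfur cycling genes.
    Includes generators for synthetic communities, trees, designs and chips
    with the statistical structure each stage assumes, so the full pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
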