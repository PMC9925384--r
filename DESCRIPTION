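Package: cryptomes
Title: Crypt-Resolved Somatic Mutation Analysis of Normal Small Intestine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutations in whole-genome sequenced
    normal intestinal crypts. Implements the post-calling filter chain
    (read-metric predicate, exact binomial germline test with
    Benjamini-Hochberg correction, beta-binomial overdispersion filter),
    sensitivity-adjusted mutation-burden estimation with linear mixed-effects
    regression on age, region and celiac status, crypt phylogeny
    reconstruction with maximum-likelihood mutation-to-branch assignment and
    SBS1-based fission timing, 96-channel mutational-signature attribution by
    expectation maximization with APOBEC-positivity calling, kataegis
    detection via a negative-binomial cluster test, approximate Bayesian
    computation for crypt stem-cell dynamics, APOBEC YTCA/RTCA
    sequence-context enrichment, and small-versus-large intestine APOBEC
    expression comparison. A synthetic-cohort generator provides fully
    labelled read-count data with the statistical structure the analysis
    assumes, so every stage is testable without access to protected
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    nlme,
    MASS,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
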