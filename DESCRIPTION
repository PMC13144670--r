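Package: regherit
Title: Zygosity-Free Heritability Mapping from Health-Register Twin and Sibling Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates narrow-sense heritability of binary disease phenotypes
    from population-register data without zygosity information. Twin pairs are
    stratified into same-sex and opposite-sex groups; the monozygotic fraction
    of same-sex pairs is obtained from Weinberg's rule; within-group phenotypic
    correlations come from a two-variance-component linear mixed model on paired
    0/1 outcomes; correlations are converted to the liability scale with a
    Reich-type threshold-model transform and combined with a modified Falconer
    estimator. Includes cohort construction from person/diagnosis tables
    (twin and sibling pair identification, phecode mapping with hierarchy
    closure, eligibility filters), stratified pair bootstrap, Benjamini-Hochberg
    FDR, inverse-variance-weighted summaries, weighted cross-cohort comparison
    fits, and a synthetic-registry simulator with a known liability-threshold
    ACE structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
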