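Package: urateh2
Title: Rare-Variant Heritability of Serum Urate by Carrier-Grouped Variance Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of serum-urate variance explained by rare
    function-affecting variants of a urate-transporter gene (URAT1/SLC22A12).
    Provides cohort filtering with overlap-aware exclusion tallies, functional
    classification of transporter variants from oocyte uptake-assay statistics
    (Welch two-sample t-test from summary statistics), CKD-EPI eGFR with the
    Japanese coefficient, sex-stratified covariate adjustment of serum urate,
    a carrier-collapsing burden test, and a carrier-grouped variance
    decomposition yielding the additive variance and heritability share of the
    gene. A seeded synthetic-cohort generator (genotypes, covariates, uptake
    assays) makes every stage testable without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR,
    MASS
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    yaml
Config/testthat/edition: 3
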