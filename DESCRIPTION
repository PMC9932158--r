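Package: dnmrisk
Title: Personalized Recurrence Risk for De Novo Mutations from Deep Trio Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the recurrence risk of a pathogenic de novo mutation
    (DNM) for a couple who have had an affected child, from deep amplicon
    read counts and long-read phasing evidence collected across the
    parent-child trio. Corrected mosaic variant allele fractions are
    obtained from a joint case/control binomial likelihood in which the
    sequencing false-positive rate is a nuisance parameter (marginalized by
    adaptive quadrature for the point estimate, profiled for the 95%
    confidence interval). Parent-of-origin is resolved from phase-set
    annotations in trio VCFs with a read-backed pileup fallback (Fisher's
    exact test on DNM x SNP allele co-occurrence). Each family is
    stratified into one of seven mutational-origin categories (paternal or
    maternal one-off, confined gonadal or mixed mosaicism, or post-zygotic
    in the proband) and a personalized recurrence risk is reported:
    measured in sperm for paternal cases, model-based (category prior times
    germline VAF) for maternal and unresolved cases, and zero for
    post-zygotic probands. A synthetic-family generator emulating the study
    design (multi-tissue triplicate deep sequencing with unrelated
    controls, trio SNP panels, and phasing reads) makes the full workflow
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
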