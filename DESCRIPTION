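Package: nbscreen
Title: Rule-Based Expanded Newborn Screening Analysis for Inborn Errors of
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing expanded newborn-screening programs that use
    flow-injection tandem mass spectrometry on dried blood spots. Provides a
    machine-readable 26-condition screening panel (analytes, derived markers,
    and disjunctive positive rules over amino acids, acylcarnitines, free
    carnitine and succinylacetone), a vectorised rule engine with
    hyperphenylalaninemia subtyping, a seeded synthetic-cohort generator
    (log-normal analyte profiles, condition-specific marker shifts, recall
    regression to the mean, genotypes drawn from allele spectra), a two-tier
    screen-recall-retest-diagnosis cascade simulator, incidence estimation with
    Wilson, Clopper-Pearson and exact-Poisson confidence intervals reported in
    1-in-X form, disease-spectrum and cohort-characteristic statistics, and
    variant-spectrum (hotspot) summaries over HGVS-style allele tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
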