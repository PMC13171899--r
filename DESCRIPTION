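Package: starpgx
Title: Star-Allele Pharmacogenetic Interpretation of Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls star-allele diplotypes for twelve pharmacogenes from
    small-variant calls, translates them into metabolizer and transporter
    phenotypes with guideline-based actionability, overlays exon-level copy
    number variants and rare high-impact variants to revise phenotypes, joins
    medication records into gene-drug pairs classified against a CPIC/DPWG-style
    recommendation table, and aggregates cohort-level statistics. Includes a
    synthetic pedigree cohort simulator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
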