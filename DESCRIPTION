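Package: pgxpop
Title: Comparative Pharmacogenetic Variant Analysis Across Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting pharmacogenetic variant panels between
    small study cohorts and large continental reference populations:
    consequence-based impact classification and annotation summaries,
    detection of cohort-exclusive variants, allele-frequency contrasts
    standardized to a fixed allele total with two-sided Fisher exact tests
    and Hochberg step-up correction, classical multidimensional scaling and
    pairwise PERMANOVA on genotype distance matrices, and a Balding-Nichols
    multi-population genotype simulator so the whole pipeline is testable
    offline. Packaged reference tables describe the glucocorticoid-pathway
    variant panel of two Amazonian indigenous cohorts alongside the 1000
    Genomes continental panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
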