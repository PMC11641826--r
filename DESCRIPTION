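Package: casexnet
Title: Case-Exclusive Variant Prioritization and Interaction-Network Analysis for Small Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare variants in small case-control
    sequencing cohorts. Implements the uncorrected allelic chi-square
    association test with PLINK-style quality control (per-variant
    missingness, minor-allele frequency, and an exact Hardy-Weinberg
    test), consequence-severity ranking of VEP annotations, filtering of
    variants whose alternate alleles occur exclusively in cases,
    gene-level co-occurrence aggregation of case-exclusive allele counts,
    and STRING-style protein-protein interaction network analysis with
    per-gene score normalization and seed-gene subnetwork extraction.
    Includes a synthetic-cohort simulator so every stage can be exercised
    end to end without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
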