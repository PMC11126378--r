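Package: founderseg
Title: Founder Haplotype Mapping by Zygosity-Constrained Shared-Segment Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the maximal founder (identity-by-descent) segment shared
    around an index variant in a multi-sample cohort of small-variant calls,
    using zygosity-constrained consistency rules over homozygous and
    compound-heterozygous carriers, with breaker-delimited margins and
    incremental narrowing. Includes readers for multi-sample VCF genotype
    matrices with exome-capture missingness semantics, a curated variant
    catalog with pathogenicity-score summaries, allele-frequency arithmetic and
    protein-domain localization, classification of predicted splice-donor
    disruption outcomes via a pluggable donor-site scorer, a synthetic
    founder-cohort simulator with recombination-truncated ancestral segments
    for parameter-recovery studies, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
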