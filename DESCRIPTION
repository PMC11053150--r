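Package: transmapr
Title: Trans-Ancestry GWAS Fine-Mapping and Target-Gene Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-maps genome-wide association study (GWAS) risk regions from
    per-population summary statistics and linkage-disequilibrium reference
    panels. Implements region aggregation, approximate conditional/joint
    analysis reconstructed from summary statistics, a forward stepwise search
    for independent association signals with trans-ancestry inverse-variance
    meta-analysis and index stabilization, credible-causal-variant (CCV) sets,
    cis-eQTL/mQTL scans with sample-size-weighted z-score meta-analysis,
    summary-data-based Mendelian randomization (SMR) colocalization, and a
    point-based regulatory evidence score that nominates target genes from
    chromatin interactions, histone marks, TAD boundaries, driver-gene status
    and coding consequences. A synthetic-data generator emulates two-population
    LD-structured cohorts with molecular traits so the full pipeline runs and
    is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    metafor,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
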