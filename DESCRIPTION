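Package: pleiosarc
Title: Pleiotropic Genomic Predictors of Sarcopenia, Sarcopenic Obesity
    and Sarcopenic Diabesity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies pleiotropic genomic predictors of sarcopenia from
    multi-trait GWAS summary statistics. Implements two-stage variant
    selection (genome-wide discovery followed by replication across
    handgrip strength, appendicular lean mass and usual walking pace with
    consistent effect directions), greedy linkage-disequilibrium pruning
    at an r-squared threshold, nested tier classification into sarcopenia,
    sarcopenic obesity and sarcopenic diabesity, unweighted polygenic
    risk-allele scoring with quintile risk-band stratification, and
    direction-concordance evaluation between human allele-expression
    evidence and mouse knockout phenotypes. Ships a synthetic-data module
    that generates genotype panels with block linkage disequilibrium and
    multi-trait summary statistics with planted pleiotropic signals, plus
    packaged transcriptions of the published variant and gene lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
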