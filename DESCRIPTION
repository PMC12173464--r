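Package: panelscan
Title: Longitudinal Mixed-Model GWAS and Molecular QTL Mapping for Mouse Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci in panels of inbred and
    recombinant inbred mouse strains, centered on a longitudinal linear mixed
    model with kinship-structured random intercepts and random day slopes for
    repeated behavioral measurements (intravenous self-administration
    endpoints). Includes rank-based inverse normal (Blom) phenotype
    normalization, REML estimation of the six genetic/individual variance
    components, generalized-least-squares Wald genome scans, permutation-based
    family-wise significance thresholds, and locus calling/merging. A molecular
    layer quantifies transcript abundance (TPM filtering and quantile
    normalization), exon percent-spliced-in, and RNA-editing ratios from count
    tables and maps cis/trans expression, splicing and editing QTLs with a
    spectral single-kinship mixed model. Integration utilities cover QTL
    coincidence, trans-regulation hotspots under a Poisson null with FDR
    control, Fisher exact enrichments, linkage-disequilibrium statistics,
    allelic-effect and SNP-by-infusate interaction tests. A synthetic-data
    generator emulates the panel design end to end so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    jsonlite,
    limma,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
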