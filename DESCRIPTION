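Package: msatimpute
Title: Imputation of Multiallelic Microsatellite Genotypes from Flanking SNP Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bridging microsatellite (STR) and SNP genotyping
    platforms in livestock parentage testing. Implements a Li-Stephens
    haplotype-copying model to impute multiallelic microsatellite genotypes
    from phased SNP haplotypes in flanking windows, together with the
    surrounding pipeline: genotype quality control and VCF-style allele
    recoding, flanking-window selection and low-density panel design,
    ten-fold masking cross-validation with concordance and dosage r-squared
    accuracy metrics and their naive/random null-model expectations,
    VanRaden genomic relationship matrices with kinship-network centrality
    summaries, pedigree-based effective population size, and exclusion-based
    parentage verification. A pedigreed cohort simulator with linked STR and
    SNP variation provides ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
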