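Package: sweepscan
Title: Selection-Signature Scanning and Mixed-Model GWAS for Paired Cattle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects footprints of recent directional selection in phased
    SNP-chip data from a selected and an unselected population. Implements
    extended haplotype homozygosity (EHH) decay curves, the integrated
    haplotype score (iHS) with frequency-bin standardization and its
    -log10 Gaussian tail transform (piHS), the cross-population Rsb
    statistic built on Tang-style site EHH (EHHS/iES), per-SNP and
    genome-wide Fst, identity-by-state MDS, a genomic-relationship-matrix
    mixed-linear-model association scan with leave-one-chromosome-out
    (LOCO) polygenic control, haplotype bifurcation trees, decadal cohort
    trends of allele frequencies and breeding values, and pairwise linkage
    disequilibrium. A forward Wright-Fisher two-population sweep simulator
    generates phased panels with known truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
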