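Package: plastdiv
Title: Comparative Plastome Screening for High-Variation Marker Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast genomes
    aimed at discovering candidate molecular markers. Reads annotated
    plastomes (GenBank flat files or FASTA plus a feature table), infers the
    quadripartite LSC/SSC/IR structure, enumerates long repeated sequences of
    the four orientation types under a Hamming mismatch budget, scans perfect
    microsatellites (SSRs) with per-motif-length unit thresholds and groups
    homologous SSRs across species, derives the shared catalogue of genes,
    introns, intergenic spacers and pseudogenes, scores every shared locus
    with the percent-variation statistic 100 * (substitutions + indel
    events) / alignment length averaged over all species pairs, ranks loci as
    candidate markers with an amplicon-length screen, and exports
    concatenated supermatrices. A seeded simulator of annotated plastome
    datasets with full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
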