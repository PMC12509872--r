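Package: pcscan
Title: Windowed Principal Component Scans Along Chromosomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes, polarizes and visualizes genetic principal components
    in rolling windows along chromosomes at single-sample resolution, from
    hard genotype calls (VCF or TSV) or genotype likelihoods (VCF GL/PL
    fields or BEAGLE files). Missing calls are mean-imputed on the fly;
    low-coverage data can instead be analyzed in a genotype-likelihood
    framework via an iterative individual-allele-frequency PCA. Includes
    adaptive and guide-sample eigenvector polarization across adjacent
    windows, chromosome- and interval-level sign flips, interactive HTML and
    static chromosome/genome plots, a synthetic-cohort simulator with a
    planted inversion polymorphism, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite,
    ggplot2,
    vcfR,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
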