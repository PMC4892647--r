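Package: miRITH
Title: Intratumoral Heterogeneity Analysis of miRNA Expression by
    RT-qPCR and In Situ Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing intratumoral heterogeneity of microRNA
    expression measured by two modalities on multiple samples per tumour:
    relative quantification of RT-qPCR triplicates (delta-Cq against the
    arithmetic mean of reference miRNAs, linearised as 2^-dCq), chromogenic
    in situ hybridization image quantification by nearest-centroid pixel
    classification into colour classes and class-specific area fractions,
    one-way random-effects reliability analysis (intraclass correlation for
    single samples and for means of k samples, with the Spearman-Brown
    relation and an effective group size for unbalanced designs), and
    cross-modality Spearman concordance with common-scale standardisation
    for joint plotting. A synthetic-data generator emulating the study
    design (patients by within-tumour samples, triplicate technical noise,
    detection ceiling, colour-class images with known area fractions) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'concordance.R'
    'experiments.R'
    'io.R'
    'ish.R'
    'miRITH-package.R'
    'qpcr.R'
    'reliability.R'
    'simulate.R'
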