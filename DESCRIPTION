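Package: GranuleKinetics
Title: Quantitative Analysis of Phase-Transitioned Germ Granules from
    Fluorescence Microscopy
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of biomolecular
    condensates such as Drosophila germ granules from fluorescence
    microscopy: granule segmentation and morphometry (size, protein
    abundance, fold enrichment over a reference compartment,
    hollow/small/big classification, two-channel colocalization, 3D
    counting of germ-plasm-associated nuclei, granule tracking and fusion
    detection); photobleaching kinetics (FRAP normalization and
    single-exponential recovery fitting with mobile fraction and
    half-time, FLIP percent-remaining quantification with
    unintentional-bleaching correction, photoconversion retention and
    exchange); population statistics (summaries, percent change, t-tests,
    one-way ANOVA, Dean-Jett-Fox-style cell-cycle deconvolution of DNA
    content histograms); and a synthetic-data module that generates
    granule images, photobleaching traces, two-channel nuclear stacks and
    DNA histograms of known ground truth so that every analysis stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    pracma,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'simulate-histogram.R'
    'cell-cycle.R'
    'io.R'
    'morphometry.R'
    'objects3d.R'
    'photokinetics.R'
    'pipeline.R'
    'population-stats.R'
    'simulate-image.R'
    'simulate-kinetics.R'
    'tracking.R'
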