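Package: cistromeConverge
Title: Transcription-Factor Convergence Analysis for Multi-Condition ChIP-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of multi-factor, multi-condition ChIP-seq
    experiments designed on a 2x2 genotype-by-treatment layout, as used to
    study glucocorticoid receptor (GR) and BMAL1 convergence on metabolic
    gene promoters in skeletal muscle. Provides S4 containers for peak sets,
    step-function signal tracks and motif-site sets; readers and writers for
    BED, bedGraph and gene tables; windowed motif-site occupancy profiles
    with treatment contrasts; peak-to-TSS annotation and the proximal/distal
    10 kb shift statistic; inter-factor peak interdistance histograms with a
    permutation co-occurrence contrast; an RNA polymerase II TSS screen that
    classifies genes into treatment-response quadrants and intersects them
    with promoter-proximal factor signal gains; a seeded synthetic cistrome
    generator with planted, recoverable effect sizes; and the bioenergetic
    and assay-derived measures used alongside the cistrome analysis
    (weight-normalized work, basal oxygen consumption rate, respiratory
    control ratio, 13C labeling ratio, mtDNA/nDNA qPCR ratio, ChIP-qPCR
    percent input, circadian reporter amplitude).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, Coverage, GeneRegulation, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'cistromeConverge-package.R'
    'convergence.R'
    'io.R'
    'methods.R'
    'metrics.R'
    'occupancy.R'
    'pipeline.R'
    'screen.R'
    'signal-ops.R'
    'synthetic.R'
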