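Package: nmjcoloc
Title: Quantitative Analysis of Neuromuscular Junction Disruption
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective threshold-based pixel colocalization scoring of
    multi-channel neuromuscular junction (NMJ) fluorescence micrographs,
    with nested cohort statistics (pooled, per-patient, and
    patient-versus-pool Mann-Whitney comparisons with Bonferroni control,
    plus a logistic-regression diagnosis predictor), transmission electron
    microscopy morphometry from digitized traces (postsynaptic fold length,
    inter-fold spacing, mitochondrial area fraction, inter-rater
    reliability), and efficiency-corrected qPCR relative quantification
    (telomere T/S ratios and expression fold differences). A synthetic-data
    module generates ground-truthed images, traces and plates so every
    stage of the pipeline runs and can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cohortStats.R'
    'imaging.R'
    'colocalization.R'
    'io.R'
    'nmjcoloc-package.R'
    'pipeline.R'
    'qpcr.R'
    'synthetic.R'
    'temMorphometry.R'
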