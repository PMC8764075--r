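Package: HiCOntogeny
Title: Multi-Scale 3D Genome and Chromatin-State Dynamics Across a
    Developmental Trajectory
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates binned Hi-C contact matrices with histone-modification
    and transcription-factor ChIP peak sets and single-cell expression across
    an ordered series of four cell stages, as in hematopoietic stem cell
    ontogeny (eAEC, HEC, pre-HSC, LT-HSC). Provides Knight-Ruiz balancing,
    distance-decay expectation and observed/expected transforms, A/B
    compartment calling at 100 kb with flip classification, insulation-score
    TAD boundary calling and boundary strength at 40 kb, the intra-TAD
    domain-score statistic with a randomized-TAD null, donut-style chromatin
    loop detection at 10 kb with CPM and aggregate (APA) quantification,
    enhancer-promoter loop classification with TF-engagement subtyping, and
    stage-trend statistics (ANOVA with Benjamini-Hochberg correction,
    Wilcoxon rank-sum). A synthetic-data module plants compartments, TADs,
    loops, peaks, TF occupancy and lagged expression with a serialisable
    ground truth, supporting end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: HiC, Epigenetics, FunctionalGenomics, Software
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'HiCOntogeny-package.R'
    'annotate.R'
    'compartments.R'
    'contact-core.R'
    'domains.R'
    'io.R'
    'loops.R'
    'pipeline.R'
    'signal.R'
    'simulate-chip.R'
    'simulate-contacts.R'
    'simulate.R'
    'stats.R'
    'utils.R'
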