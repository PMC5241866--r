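Package: lncScout
Title: Discovery of Transcription-Factor-Regulated, Tissue-Restricted
    Long Non-Coding RNAs from RNA-Seq and ChIP-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative screen for candidate regulatory long non-coding
    RNAs (lncRNAs). Starting from a RefSeq-style transcript annotation, the
    package retains non-coding (NR_) transcripts, quantifies time-course
    RNA-seq as RPKM, applies a summed-expression gate, calls fold-change
    differential expression, and preprocesses and hierarchically clusters
    expression profiles. Transcription-factor regulation is assigned by
    strand-aware promoter windows (5 kb upstream to 0.5 kb downstream of the
    transcription start site) intersected with ChIP-seq peaks, with an
    orientation-aware 25-bp binding-intensity profile and a naive Poisson
    peak caller for peak-free inputs. Differentially expressed and TF-bound
    sets are intersected into a ranked candidate report, optionally filtered
    for tissue-restricted expression. A planted-truth simulator generates
    annotations, negative-binomial counts, strand-shifted ChIP read clusters
    and tissue matrices so every stage, and the end-to-end pipeline, can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
biocViews: GeneRegulation, Transcription, Coverage, ChIPSeq, RNASeq,
    Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotation.R'
    'chip.R'
    'clustering.R'
    'expression.R'
    'integration.R'
    'lncScout-package.R'
    'simulate.R'
    'pipeline.R'
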