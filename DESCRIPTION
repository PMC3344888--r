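Package: fiveDGE
Title: 5'-End Digital Gene Expression Tag Simulation, Mapping and Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for 5'-end digital gene expression (5'-DGE)
    tag sequencing of the CAGE/5'-SAGE family. Simulates in-silico 5'-tag
    libraries (EcoP15I digestion yielding 25 bp tags, antisense read
    orientation, transcription-start-site peaks with exonic background,
    SOLiD di-base color-space encoding with configurable error), maps
    color-space tags to a 60-N-spacer concatenated reference allowing up to
    two color mismatches, accumulates tags into strand-resolved position
    arrays with fractional 1/n multi-hit assignment, counts tags over
    extended gene regions (2 kb 5' / 1 kb 3' with 1:2 gap splitting) and
    converts to tags-per-million (TPM). Includes the accompanying QC metrics
    (restriction-site bias profiles, replicate correlation, length-TPM
    relationship, mapping statistics) and time-course statistics (per-gene
    median normalization, Welch one-way ANOVA with Benjamini-Hochberg FDR,
    3x3 self-organizing-map clustering, Spearman/average-linkage trees).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml,
    ape,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Sequencing, Software
RoxygenNote: 7.3.3
Collate: 
    'fiveDGE-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'colorspace.R'
    'reference.R'
    'mapper.R'
    'counting.R'
    'qc.R'
    'diffexpr.R'
    'regions.R'
    'genome-sim.R'
    'expression-sim.R'
    'library-sim.R'
    'som.R'
    'trees.R'
    'pipeline.R'
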