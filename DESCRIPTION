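Package: panpav
Title: Pan-Genome Presence/Absence Variation and Selective-Sweep Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for plant pan-genome presence/absence variation (PAV)
    analysis and population-genomic scans. Implements iterative pan-reference
    augmentation from genome assemblies (k-mer anchor alignment, trim-and-retain
    of novel sequence), map-to-pan gene presence calling from coverage
    breadth/depth, core/soft-core/shell/cloud pan-gene classification,
    pan/core accumulation curves with saturation-model fits, group-unique
    pan-gene extraction, term enrichment, PAV-based population structure
    (neighbor-joining trees and Ward clustering), windowed nucleotide
    diversity, Weir-Cockerham FST, linkage-disequilibrium decay, and a
    composite selective-sweep filter combining normalized cross-population
    scores with reduction-of-diversity ranking. A synthetic-data module
    generates populations with planted PAV classes, accession-specific novel
    sequence, Balding-Nichols population differentiation and domestication
    sweeps, together with machine-readable ground truth, so the whole pipeline
    can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    GenomeInfoDb,
    ape,
    vcfR,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Genetics, PopulationGenetics, Alignment, Clustering
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'augment.R'
    'pav_analysis.R'
    'pav_build.R'
    'pav_structure.R'
    'simdata.R'
    'popgen.R'
    'pipeline.R'
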