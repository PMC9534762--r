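#' @include AllClasses.R
NULL

#' Extract the presence matrix of a PAVMatrix
#' @param x a [PAVMatrix-class]
#' @return logical matrix, clusters x accessions
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname presence
#' @export
setMethod("presence", "PAVMatrix", function(x) assay(x, "presence"))

#' Presence provenance (annotation vs coverage recovery)
#' @param x a [PAVMatrix-class]
#' @return character matrix or NULL if no provenance was recorded
#' @export
setGeneric("presenceProvenance",
           function(x) standardGeneric("presenceProvenance"))

#' @rdname presenceProvenance
#' @export
setMethod("presenceProvenance", "PAVMatrix", function(x) {
    if ("provenance" %in% assayNames(x)) assay(x, "provenance") else NULL
})

#' Accession group labels
#' @param x a [PAVMatrix-class]
#' @return named character vector of group labels per accession
#' @export
setGeneric("accessionGroups", function(x) standardGeneric("accessionGroups"))

#' @rdname accessionGroups
#' @export
setMethod("accessionGroups", "PAVMatrix", function(x) {
    stats::setNames(as.character(colData(x)$group), colnames(x))
})

#' Allele-dosage matrix of a GenotypeMatrix
#' @param x a [GenotypeMatrix-class]
#' @return integer matrix sites x samples with values 0/1/2/NA
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' Phased haplotypes of a GenotypeMatrix
#' @param x a [GenotypeMatrix-class]
#' @return list with elements `hap1`, `hap2` (0/1 matrices) or NULL when
#'   the genotypes are unphased
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname haplotypes
#' @export
setMethod("haplotypes", "GenotypeMatrix", function(x) {
    if (!all(c("hap1", "hap2") %in% assayNames(x))) return(NULL)
    list(hap1 = assay(x, "hap1"), hap2 = assay(x, "hap2"))
})

#' Pan-reference sequences
#' @param x a [PanReference-class]
#' @return [Biostrings::DNAStringSet] of all pan segments
#' @export
setGeneric("panSequences", function(x) standardGeneric("panSequences"))

#' @rdname panSequences
#' @export
setMethod("panSequences", "PanReference", function(x) x@sequences)

#' Pan-reference segment provenance
#' @param x a [PanReference-class]
#' @return DataFrame of per-segment provenance
#' @export
setGeneric("panProvenance", function(x) standardGeneric("panProvenance"))

#' @rdname panProvenance
#' @export
setMethod("panProvenance", "PanReference", function(x) x@provenance)

#' Total pan-reference size in bp
#' @param x a [PanReference-class]
#' @return integer total bp over all segments
#' @export
setGeneric("panSize", function(x) standardGeneric("panSize"))

#' @rdname panSize
#' @export
setMethod("panSize", "PanReference",
          function(x) sum(Biostrings::width(x@sequences)))

#' Novel (appended) segments of a pan-reference
#' @param x a [PanReference-class]
#' @return [Biostrings::DNAStringSet] of appended novel segments only
#' @export
setGeneric("novelSegments", function(x) standardGeneric("novelSegments"))

#' @rdname novelSegments
#' @export
setMethod("novelSegments", "PanReference", function(x) {
    x@sequences[!is.na(x@provenance$accession)]
})

setMethod("show", "PAVMatrix", function(object) {
    cat(sprintf("PAVMatrix: %d pan-gene clusters x %d accessions\n",
                nrow(object), ncol(object)))
    gr <- table(colData(object)$group)
    cat("groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "),
        "\n")
    occ <- rowSums(assay(object, "presence"))
    cat(sprintf("occupancy: min %d, median %s, max %d of %d\n",
                min(occ), format(stats::median(occ)), max(occ), ncol(object)))
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d biallelic sites x %d samples (%s)\n",
                nrow(object), ncol(object),
                if (!is.null(haplotypes(object))) "phased" else "unphased"))
    cat("chromosomes:", paste(seqlevels(rowRanges(object)), collapse = ", "),
        "\n")
})

setMethod("show", "PanReference", function(object) {
    novel <- !is.na(object@provenance$accession)
    cat(sprintf(
        "PanReference: %d base segments + %d novel segments, %d bp total\n",
        sum(!novel), sum(novel), panSize(object)))
})
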