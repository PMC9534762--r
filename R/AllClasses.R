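#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

#' PAVMatrix: binary pan-gene presence/absence table
#'
#' An S4 container for a pan-gene-cluster x accession presence/absence
#' variation (PAV) table, built on [SummarizedExperiment].  Rows are pan-gene
#' clusters, columns are accessions.  The `"presence"` assay is a logical
#' matrix; the optional `"provenance"` assay records, for each presence,
#' whether it was asserted by gene annotation (`"annotation"`) or recovered
#' by the map-to-pan coverage rule (`"coverage"`).  Accession group labels
#' live in `colData(x)$group`.
#'
#' Validity requires every cluster to be present in at least one accession
#' and group labels to cover all accessions.
#'
#' @seealso [PAVMatrix()], [presence()], [accessionGroups()],
#'   [classifyPanGenes()], [pavDistance()]
#' @export
setClass("PAVMatrix", contains = "SummarizedExperiment")

setValidity("PAVMatrix", function(object) {
    if (!"presence" %in% assayNames(object))
        return("assay 'presence' is required")
    p <- assay(object, "presence")
    if (!is.logical(p))
        return("'presence' assay must be a logical matrix")
    if (anyNA(p))
        return("'presence' assay must not contain NA")
    if (nrow(p) > 0 && any(rowSums(p) == 0))
        return("every cluster must be present in at least one accession")
    if (!"group" %in% colnames(colData(object)))
        return("colData must carry a 'group' label for every accession")
    if (anyNA(colData(object)$group))
        return("group labels must cover all accessions")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("accession ids must be present and unique")
    TRUE
})

#' Construct a PAVMatrix
#'
#' @param presence logical (or 0/1) matrix, clusters x accessions, with
#'   rownames (cluster ids) and colnames (accession ids).
#' @param groups character vector of group labels, one per accession
#'   (recycled if length 1).  Defaults to a single group `"all"`.
#' @param provenance optional character matrix of the same shape recording
#'   `"annotation"` or `"coverage"` for each presence.
#' @return a [PAVMatrix-class] object.
#' @examples
#' m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("acc1", "acc2")))
#' pav <- PAVMatrix(m, groups = c("A", "B"))
#' presence(pav)
#' @export
PAVMatrix <- function(presence, groups = "all", provenance = NULL) {
    presence <- as.matrix(presence)
    if (is.numeric(presence)) {
        if (!all(presence %in% c(0, 1)))
            stop("numeric 'presence' must be 0/1")
        storage.mode(presence) <- "logical"
    }
    if (is.null(rownames(presence)))
        rownames(presence) <- sprintf("cluster%05d", seq_len(nrow(presence)))
    if (is.null(colnames(presence)))
        stop("'presence' must have accession ids as colnames")
    groups <- rep_len(as.character(groups), ncol(presence))
    assays <- list(presence = presence)
    if (!is.null(provenance)) {
        stopifnot(identical(dim(provenance), dim(presence)))
        dimnames(provenance) <- dimnames(presence)
        assays$provenance <- provenance
    }
    se <- SummarizedExperiment(
        assays = assays,
        colData = DataFrame(group = groups, row.names = colnames(presence)))
    new("PAVMatrix", se)
}

#' GenotypeMatrix: biallelic diploid genotype dosages
#'
#' An S4 container (extending [RangedSummarizedExperiment]) for biallelic
#' SNP genotypes: a `"dosage"` assay with values in \{0, 1, 2, NA\} (count of
#' the alternate allele), and optional phased haplotype assays `"hap1"` and
#' `"hap2"` in \{0, 1\}.  Rows are sites, carried as a `GRanges` of 1-based
#' positions (the VCF surface; all other coordinates in the package are
#' 0-based half-open); `ref` and `alt` alleles are row metadata.  Columns
#' are samples.
#'
#' Validity requires sites sorted by (chrom, pos) with no duplicates, and
#' dosage equal to hap1 + hap2 wherever haplotypes are present.
#'
#' @seealso [GenotypeMatrix()], [dosage()], [windowPi()],
#'   [weirCockerhamFst()], [ldDecay()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    if (!"dosage" %in% assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    ok <- d[!is.na(d)]
    if (length(ok) && !all(ok %in% 0:2))
        return("dosage values must be 0, 1, 2 or NA")
    rr <- rowRanges(object)
    if (length(rr) > 1) {
        o <- order(as.character(seqnames(rr)), start(rr))
        if (!identical(o, seq_along(rr)))
            return("sites must be sorted by (chrom, pos)")
        key <- paste(as.character(seqnames(rr)), start(rr))
        if (anyDuplicated(key))
            return("duplicate (chrom, pos) sites are not allowed")
    }
    if (all(c("hap1", "hap2") %in% assayNames(object))) {
        h <- assay(object, "hap1") + assay(object, "hap2")
        idx <- !is.na(h) & !is.na(d)
        if (any(h[idx] != d[idx]))
            return("dosage must equal hap1 + hap2 where phased")
    }
    TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix (sites x samples) with values 0/1/2/NA and
#'   sample ids as colnames.
#' @param chrom,pos character/integer vectors of site coordinates
#'   (`pos` is 1-based, as in VCF).
#' @param ref,alt single-base alleles per site.
#' @param hap1,hap2 optional phased haplotype matrices in \{0,1\}.
#' @param chromLengths optional named vector of chromosome lengths (bp),
#'   used to bound window tiling.
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                           hap1 = NULL, hap2 = NULL, chromLengths = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
    o <- order(as.character(chrom), pos)
    rr <- GRanges(as.character(chrom)[o], IRanges(pos[o], width = 1))
    if (is.null(ref)) ref <- rep("A", length(pos))
    if (is.null(alt)) alt <- rep("T", length(pos))
    S4Vectors::mcols(rr)$ref <- as.character(ref)[o]
    S4Vectors::mcols(rr)$alt <- as.character(alt)[o]
    if (!is.null(chromLengths)) {
        sl <- chromLengths[seqlevels(rr)]
        names(sl) <- seqlevels(rr)
        seqlengths(rr) <- sl
    }
    assays <- list(dosage = dosage[o, , drop = FALSE])
    if (!is.null(hap1) && !is.null(hap2)) {
        assays$hap1 <- as.matrix(hap1)[o, , drop = FALSE]
        assays$hap2 <- as.matrix(hap2)[o, , drop = FALSE]
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = rr)
    new("GenotypeMatrix", se)
}

#' PanReference: base reference plus appended novel segments
#'
#' Holds the growing pan-reference of the iterative augmentation strategy:
#' the base reference chromosomes plus every retained novel segment, each
#' novel segment carrying its provenance (source accession, contig, interval
#' within that contig, and the iteration at which it was appended).
#'
#' @slot sequences a [Biostrings::DNAStringSet] of all pan segments (base
#'   chromosomes first, then novel segments in append order).
#' @slot provenance a [S4Vectors::DataFrame] with one row per segment:
#'   `segment_id`, `accession` (NA for base segments), `contig`, `start`,
#'   `end` (0-based half-open in the source contig) and `iteration`
#'   (0 for base segments).
#' @seealso [PanReference()], [augmentIterative()], [panSize()]
#' @export
setClass("PanReference",
         representation(sequences = "DNAStringSet", provenance = "DataFrame"))

setValidity("PanReference", function(object) {
    if (length(object@sequences) != nrow(object@provenance))
        return("one provenance row per segment is required")
    ids <- names(object@sequences)
    if (is.null(ids) || anyDuplicated(ids))
        return("segment ids must be present and unique")
    if (!identical(ids, as.character(object@provenance$segment_id)))
        return("provenance segment_id must match sequence names in order")
    pr <- object@provenance
    novel <- !is.na(pr$accession)
    if (any(novel)) {
        w <- pr$end[novel] - pr$start[novel]
        if (any(w < 1) || any(pr$start[novel] < 0))
            return("novel-segment provenance intervals must be valid")
        if (any(w != Biostrings::width(object@sequences)[novel]))
            return("novel-segment length must equal its provenance interval")
    }
    TRUE
})

#' Construct a PanReference from a base reference
#'
#' @param reference a named [Biostrings::DNAStringSet] (or named character
#'   vector) of base reference sequences.
#' @return a [PanReference-class] with no novel segments yet.
#' @export
PanReference <- function(reference) {
    seqs <- asDNAStringSet(reference)
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("reference sequences must have unique names")
    prov <- DataFrame(segment_id = names(seqs),
                      accession = NA_character_,
                      contig = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      iteration = 0L)
    new("PanReference", sequences = seqs, provenance = prov)
}

# internal: coerce character vectors / DNAStringSet uniformly
asDNAStringSet <- function(x) {
    if (methods::is(x, "DNAStringSet")) return(x)
    Biostrings::DNAStringSet(toupper(unlist(x)))
}
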