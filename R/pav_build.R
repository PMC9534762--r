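#' @include AllClasses.R augment.R
NULL

#' Greedy clustering of gene sequences into pan-gene clusters
#'
#' A length-sorted greedy stand-in for orthogroup inference: genes are
#' processed in order of decreasing sequence length (ties by id); each gene
#' joins the first existing cluster whose representative shares gap-free
#' k-mer-anchored identity >= `identityThreshold` (identity over the longer
#' sequence, both strands considered), otherwise it founds a new cluster
#' whose representative it becomes.  Deterministic given the input.
#'
#' @param genes data.frame with columns `accession`, `gene_id`, `sequence`
#' @param identityThreshold minimum identity to join a cluster (default
#'   0.90)
#' @param k k-mer size for identity estimation
#' @return data.frame with columns `cluster_id`, `accession`, `gene_id`,
#'   plus attribute `"representatives"` (named character vector of cluster
#'   representative sequences)
#' @export
greedyClusterGenes <- function(genes, identityThreshold = 0.90, k = 11L) {
    if (nrow(genes) == 0) {
        out <- data.frame(cluster_id = character(0),
                          accession = character(0), gene_id = character(0))
        attr(out, "representatives") <- character(0)
        return(out)
    }
    stopifnot(all(c("accession", "gene_id", "sequence") %in% names(genes)))
    if (any(nchar(genes$sequence) == 0)) stop("empty gene sequence")
    genes <- genes[order(-nchar(genes$sequence), genes$gene_id), ,
                   drop = FALSE]
    reps <- character(0)
    assign <- integer(nrow(genes))
    for (i in seq_len(nrow(genes))) {
        s <- toupper(genes$sequence[i])
        hit <- 0L
        for (j in seq_along(reps)) {
            id <- .cppPairIdentity(reps[j], s, k = as.integer(k))$identity
            if (id >= identityThreshold) { hit <- j; break }
        }
        if (hit == 0L) {
            reps <- c(reps, s)
            hit <- length(reps)
        }
        assign[i] <- hit
    }
    ids <- sprintf("pan%05d", seq_along(reps))
    out <- data.frame(cluster_id = ids[assign],
                      accession = genes$accession,
                      gene_id = genes$gene_id,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "representatives") <- stats::setNames(reps, ids)
    pavLog("cluster", "%d genes -> %d clusters", nrow(out), length(reps))
    out
}

#' Map-to-pan presence call from coverage breadth and depth
#'
#' A gene is called present in an accession when its read coverage spans at
#' least `breadthMin` of the gene length AND its mean depth is at least
#' `depthMin`; both thresholds are inclusive.
#'
#' @param breadth fraction of gene length covered, in `[0, 1]`
#' @param depth mean fold-coverage, `>= 0`
#' @param breadthMin,depthMin inclusive thresholds (defaults 0.99 and 3)
#' @return logical vector of presence calls
#' @examples
#' callPresence(1.00, 5.2)   # TRUE
#' callPresence(0.98, 10)    # FALSE (breadth fails)
#' callPresence(0.995, 3.0)  # TRUE  (boundaries inclusive)
#' @export
callPresence <- function(breadth, depth, breadthMin = 0.99, depthMin = 3.0) {
    stopifnot(all(breadth >= 0 & breadth <= 1), all(depth >= 0))
    breadth >= breadthMin & depth >= depthMin
}

#' Build a PAV matrix from cluster memberships and coverage evidence
#'
#' Presence of a cluster in an accession is the union of two rules:
#' the accession contributed an annotated member gene to the cluster
#' (`"annotation"`), or its coverage record passes [callPresence()]
#' (`"coverage"`, the map-to-pan recovery).  The provenance assay records
#' which rule fired (annotation wins when both do).  Clusters with zero
#' presences are dropped with a logged count.
#'
#' @param members data.frame with columns `accession`, `cluster_id` (one
#'   row per annotated member gene)
#' @param coverage data.frame with columns `accession`, `cluster_id`,
#'   `breadth`, `depth`; may be empty.  Coverage rows for clusters absent
#'   from `clusterIds` are a hard error.
#' @param groups named character vector of group labels per accession, or a
#'   single label
#' @param accessions accession universe (defaults to those seen in
#'   `members`/`coverage`)
#' @param clusterIds cluster universe (defaults to those seen in `members`)
#' @param breadthMin,depthMin thresholds for [callPresence()]
#' @return a [PAVMatrix-class] with presence and provenance assays
#' @export
buildPavMatrix <- function(members, coverage = NULL, groups = "all",
                           accessions = NULL, clusterIds = NULL,
                           breadthMin = 0.99, depthMin = 3.0) {
    if (is.null(clusterIds)) clusterIds <- unique(members$cluster_id)
    if (is.null(accessions))
        accessions <- sort(unique(c(members$accession,
                                    coverage$accession)))
    if (!is.null(coverage) && nrow(coverage) > 0) {
        unknown <- setdiff(unique(coverage$cluster_id), clusterIds)
        if (length(unknown))
            stop("coverage references unknown cluster(s): ",
                 paste(utils::head(unknown, 5), collapse = ", "))
        unknownAcc <- setdiff(unique(coverage$accession), accessions)
        if (length(unknownAcc))
            stop("coverage references unknown accession(s): ",
                 paste(utils::head(unknownAcc, 5), collapse = ", "))
    }
    m <- matrix(FALSE, length(clusterIds), length(accessions),
                dimnames = list(clusterIds, accessions))
    prov <- matrix(NA_character_, length(clusterIds), length(accessions),
                   dimnames = list(clusterIds, accessions))
    if (nrow(members) > 0) {
        im <- cbind(match(members$cluster_id, clusterIds),
                    match(members$accession, accessions))
        if (anyNA(im)) stop("member references unknown cluster/accession")
        m[im] <- TRUE
        prov[im] <- "annotation"
    }
    if (!is.null(coverage) && nrow(coverage) > 0) {
        pres <- callPresence(coverage$breadth, coverage$depth,
                             breadthMin = breadthMin, depthMin = depthMin)
        ic <- cbind(match(coverage$cluster_id, clusterIds),
                    match(coverage$accession, accessions))[pres, ,
                                                           drop = FALSE]
        recovered <- !m[ic]
        m[ic] <- TRUE
        prov[ic[recovered, , drop = FALSE]] <- "coverage"
    }
    empty <- rowSums(m) == 0
    if (any(empty)) {
        pavLog("pav", "dropped %d cluster(s) with zero presences",
               sum(empty))
        m <- m[!empty, , drop = FALSE]
        prov <- prov[!empty, , drop = FALSE]
    }
    g <- if (length(groups) == 1) groups else unname(groups[accessions])
    PAVMatrix(m, groups = g, provenance = prov)
}
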