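#' @include AllClasses.R
NULL

#' Pairwise distances between accessions (or genes) of a PAV matrix
#'
#' Simple-matching distance is the proportion of clusters at which two
#' accessions differ in presence; Jaccard distance is 1 - |intersection| /
#' |union| over presences.  A pair with zero union under Jaccard gets
#' distance 0 with a warning.
#'
#' @param pav a [PAVMatrix-class] or a logical/0-1 matrix (columns =
#'   objects to compare)
#' @param metric `"simple-matching"` (default) or `"jaccard"`
#' @return a symmetric `dist`-compatible matrix with zero diagonal
#' @export
pavDistance <- function(pav, metric = c("simple-matching", "jaccard")) {
    metric <- match.arg(metric)
    m <- if (methods::is(pav, "PAVMatrix")) presence(pav) else pav > 0
    if (ncol(m) < 2) stop("need at least 2 columns")
    storage.mode(m) <- "numeric"
    inter <- crossprod(m)                       # shared presences
    ones <- crossprod(m, 1 - m) + crossprod(1 - m, m)  # mismatches
    if (metric == "simple-matching") {
        d <- ones / nrow(m)
    } else {
        uni <- inter + ones
        if (any(uni == 0 & upper.tri(uni)))
            warning("pair(s) with zero union; Jaccard distance set to 0")
        d <- ifelse(uni == 0, 0, 1 - inter / uni)
    }
    diag(d) <- 0
    dimnames(d) <- list(colnames(m), colnames(m))
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]) on a symmetric distance
#' matrix; reconstructs any additive distance matrix exactly.  Negative
#' branch lengths are reported as computed unless `clampNegative = TRUE`.
#'
#' @param d symmetric distance matrix (n >= 3) with labels
#' @param clampNegative clamp negative branch lengths at zero (off by
#'   default)
#' @return an unrooted `phylo` tree, serializable with [writeNewick()]
#' @export
njTree <- function(d, clampNegative = FALSE) {
    d <- as.matrix(d)
    if (nrow(d) < 3) stop("neighbor joining needs n >= 3")
    if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
    tree <- ape::nj(stats::as.dist(d))
    if (clampNegative) tree$edge.length <- pmax(tree$edge.length, 0)
    tree
}

#' Ward hierarchical clustering of binary PAV rows cut into K groups
#'
#' Agglomerative clustering with the ward.D Lance-Williams update applied
#' to squared-Euclidean dissimilarities of binary rows (for 0/1 rows the
#' squared Euclidean distance is the Hamming count).  The tree is cut into
#' exactly K clusters, labeled `A`, `B`, ... in order of decreasing cluster
#' size (ties broken by smallest first-row index).
#'
#' @param pav a [PAVMatrix-class] or a 0/1 matrix; rows are clustered
#'   (pass `t(presence(pav))` semantics via `axis`)
#' @param K number of clusters (<= number of rows)
#' @param axis `"genes"` clusters the PAV rows (pan-genes, as in a PAV
#'   heat map); `"accessions"` clusters the columns
#' @return list with `labels` (named character vector `A`..), `hclust`
#'   (the merge history), `heights`
#' @export
wardCluster <- function(pav, K = 8L, axis = c("genes", "accessions")) {
    axis <- match.arg(axis)
    m <- if (methods::is(pav, "PAVMatrix")) presence(pav) * 1 else pav * 1
    if (axis == "accessions") m <- t(m)
    if (K > nrow(m)) stop("K exceeds the number of rows to cluster")
    d2 <- stats::dist(m)^2          # squared Euclidean = Hamming count
    hc <- stats::hclust(d2, method = "ward.D")
    cut <- stats::cutree(hc, k = K)
    sizes <- table(cut)
    firstRow <- vapply(names(sizes), function(g)
        min(which(cut == as.integer(g))), 0L)
    ord <- order(-as.integer(sizes), firstRow)
    lab <- if (K <= 26) LETTERS[seq_len(K)]
           else sprintf("C%02d", seq_len(K))
    relabel <- stats::setNames(lab, names(sizes)[ord])
    labels <- stats::setNames(unname(relabel[as.character(cut)]),
                              rownames(m))
    list(labels = labels, hclust = hc, heights = hc$height)
}
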