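#' @include AllClasses.R io.R
#' @useDynLib panpav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

segColumns <- c("contig_start", "contig_end", "target_id", "target_start",
                "target_end", "strand", "length", "matches", "identity")

emptySegments <- function() {
    data.frame(contig_start = integer(0), contig_end = integer(0),
               target_id = character(0), target_start = integer(0),
               target_end = integer(0), strand = character(0),
               length = integer(0), matches = integer(0),
               identity = numeric(0))
}

#' Anchor-based alignment of a contig against a pan-reference
#'
#' Finds exact k-mer anchors between the contig and every pan segment,
#' chains them per (target, strand, diagonal), extends each chain gap-free
#' with an x-drop rule, and reports segments with identity = exact matching
#' positions / segment length under the induced gap-free correspondence.
#' N bases never count as matches.  Reverse-strand matches are found via
#' the contig's reverse complement.  Coordinates are 0-based half-open;
#' segments are sorted by contig start.
#'
#' @param contig a single sequence (character or DNAStringSet element)
#' @param pan a [PanReference-class] or named DNAStringSet of targets
#' @param k anchor k-mer size (>= 11; default 21)
#' @param maxGap maximum distance (bp) between chained anchors on one
#'   diagonal
#' @param maxOcc k-mers occurring more often than this in the pan are
#'   skipped as repetitive
#' @return data.frame of alignment segments (`contig_start`, `contig_end`,
#'   `target_id`, `target_start`, `target_end`, `strand`, `length`,
#'   `matches`, `identity`); empty when no anchors are found
#' @export
anchorAlign <- function(contig, pan, k = 21L, maxGap = 500L, maxOcc = 50L) {
    if (k < 11) stop("k must be >= 11")
    cseq <- if (methods::is(contig, "DNAStringSet"))
        as.character(contig[[1]]) else toupper(as.character(contig)[1])
    if (nchar(cseq) < k) stop("contig shorter than k")
    targets <- if (methods::is(pan, "PanReference")) panSequences(pan)
               else asDNAStringSet(pan)
    res <- alignContigSet(list(contig = cseq), targets, k = k,
                          maxGap = maxGap, maxOcc = maxOcc)[[1]]
    res
}

# align a set of contigs against targets with a single shared k-mer index
alignContigSet <- function(contigs, targets, k = 21L, maxGap = 500L,
                           maxOcc = 50L) {
    tnames <- names(targets)
    raw <- .cppAlignContigs(vapply(contigs, as.character, ""),
                            as.character(targets),
                            k = as.integer(k), maxGap = as.integer(maxGap),
                            maxOcc = as.integer(maxOcc))
    lapply(raw, function(df) {
        if (nrow(df) == 0) return(emptySegments())
        out <- data.frame(
            contig_start = df$contig_start, contig_end = df$contig_end,
            target_id = tnames[df$target],
            target_start = df$target_start, target_end = df$target_end,
            strand = df$strand,
            length = df$contig_end - df$contig_start,
            matches = df$matches,
            identity = df$matches / (df$contig_end - df$contig_start))
        out <- out[order(out$contig_start, out$contig_end), , drop = FALSE]
        rownames(out) <- NULL
        out
    })
}

#' Trim qualifying aligned segments out of a contig and retain the rest
#'
#' Segments with identity >= `identityMin` and length >= `alignedLenMin`
#' qualify; their union is subtracted from the contig, and complement
#' intervals of length >= `minRetainedLen` are returned as retained novel
#' sequence.  Overlapping qualifying segments are unioned, never double
#' counted.  Qualifying, retained and discarded-short intervals exactly
#' partition the contig.
#'
#' @param contig the contig sequence (character or DNAStringSet element)
#' @param segments data.frame from [anchorAlign()]
#' @param identityMin,alignedLenMin qualifying thresholds (defaults 0.90
#'   identity, 100 bp)
#' @param minRetainedLen shortest retained complement interval (default
#'   100 bp)
#' @return list with `retained` (data.frame: start, end, sequence),
#'   `qualifying` (unioned intervals), `discarded` (complement intervals
#'   shorter than `minRetainedLen`)
#' @export
trimAndRetain <- function(contig, segments, identityMin = 0.90,
                          alignedLenMin = 100L, minRetainedLen = 100L) {
    cseq <- if (methods::is(contig, "DNAStringSet"))
        as.character(contig[[1]]) else toupper(as.character(contig)[1])
    L <- nchar(cseq)
    qual <- segments[segments$identity >= identityMin &
                     segments$length >= alignedLenMin, , drop = FALSE]
    union <- if (nrow(qual) == 0)
        data.frame(start = integer(0), end = integer(0))
    else {
        m <- mergeIntervals(data.frame(chrom = "c", start = qual$contig_start,
                                       end = qual$contig_end))
        data.frame(start = m$start, end = m$end)
    }
    # complement of the union within [0, L)
    compl <- data.frame(start = integer(0), end = integer(0))
    cur <- 0L
    for (i in seq_len(nrow(union))) {
        if (union$start[i] > cur)
            compl <- rbind(compl, data.frame(start = cur,
                                             end = union$start[i]))
        cur <- max(cur, union$end[i])
    }
    if (cur < L) compl <- rbind(compl, data.frame(start = cur, end = L))
    keep <- (compl$end - compl$start) >= minRetainedLen
    retained <- compl[keep, , drop = FALSE]
    discarded <- compl[!keep, , drop = FALSE]
    retained$sequence <- if (nrow(retained) == 0) character(0)
        else substring(cseq, retained$start + 1L, retained$end)
    rownames(retained) <- rownames(discarded) <- NULL
    list(retained = retained, qualifying = union, discarded = discarded)
}

#' Iterative pan-reference augmentation
#'
#' Starting from the base reference, each assembly (in a fixed order,
#' lexicographic by accession id by default) is aligned against the current
#' pan-reference; qualifying aligned segments are trimmed out and the
#' retained sequences are appended as new pan segments with provenance, so
#' they serve as reference for the next accession.
#'
#' @param reference named DNAStringSet (or [PanReference-class]) to start
#'   from
#' @param assemblies named list of per-accession DNAStringSet contig sets
#' @param identityMin,alignedLenMin,minRetainedLen see [trimAndRetain()]
#' @param k,maxGap,maxOcc see [anchorAlign()]
#' @param order accession processing order; default sorts ids
#'   lexicographically
#' @return list with `pan` (the augmented [PanReference-class]) and
#'   `report` (per-accession data.frame: accession, assembly_bp, novel_bp,
#'   novel_frac, pan_bp_after, iteration)
#' @export
augmentIterative <- function(reference, assemblies,
                             identityMin = 0.90, alignedLenMin = 100L,
                             minRetainedLen = 100L, k = 21L, maxGap = 500L,
                             maxOcc = 50L, order = NULL) {
    if (length(assemblies) == 0) stop("no assemblies supplied")
    if (is.null(names(assemblies)) || anyDuplicated(names(assemblies)))
        stop("duplicate or missing accession id in assemblies")
    pan <- if (methods::is(reference, "PanReference")) reference
           else PanReference(reference)
    accOrder <- if (is.null(order)) sort(names(assemblies)) else order
    stopifnot(setequal(accOrder, names(assemblies)))
    report <- list()
    for (it in seq_along(accOrder)) {
        acc <- accOrder[it]
        contigs <- asDNAStringSet(assemblies[[acc]])
        segsList <- alignContigSet(as.list(as.character(contigs)),
                                   panSequences(pan), k = k,
                                   maxGap = maxGap, maxOcc = maxOcc)
        novelBp <- 0L
        newSeqs <- character(0); newProv <- list()
        for (ci in seq_along(contigs)) {
            tr <- trimAndRetain(as.character(contigs[[ci]]), segsList[[ci]],
                                identityMin = identityMin,
                                alignedLenMin = alignedLenMin,
                                minRetainedLen = minRetainedLen)
            if (nrow(tr$retained) == 0) next
            for (ri in seq_len(nrow(tr$retained))) {
                segId <- sprintf("novel_%s_%s_%d", acc, names(contigs)[ci],
                                 tr$retained$start[ri])
                newSeqs[segId] <- tr$retained$sequence[ri]
                newProv[[length(newProv) + 1L]] <- DataFrame(
                    segment_id = segId, accession = acc,
                    contig = names(contigs)[ci],
                    start = tr$retained$start[ri],
                    end = tr$retained$end[ri], iteration = it)
                novelBp <- novelBp + nchar(tr$retained$sequence[ri])
            }
        }
        if (length(newSeqs)) {
            add <- Biostrings::DNAStringSet(newSeqs)
            pan <- new("PanReference",
                       sequences = c(panSequences(pan), add),
                       provenance = rbind(panProvenance(pan),
                                          do.call(rbind, newProv)))
        }
        asmBp <- sum(Biostrings::width(contigs))
        report[[acc]] <- data.frame(
            accession = acc, assembly_bp = asmBp, novel_bp = novelBp,
            novel_frac = novelBp / asmBp, pan_bp_after = panSize(pan),
            iteration = it, stringsAsFactors = FALSE)
        pavLog("augment", "%s: %d bp novel (%.3f%%), pan now %d bp",
               acc, novelBp, 100 * novelBp / asmBp, panSize(pan))
    }
    list(pan = pan, report = do.call(rbind, c(report,
                                              make.row.names = FALSE)))
}

#' Base-level recall and precision of augmentation against planted truth
#'
#' Aligns every planted novel segment against the appended pan novelty (and
#' vice versa) with [anchorAlign()]; a base counts as recovered/true when it
#' lies in an alignment segment of identity >= `identityMin`.  Shared
#' planted segments are appended only once, so both directions are needed.
#'
#' @param pan an augmented [PanReference-class]
#' @param truth data.frame of planted segments from [simulateAssemblies()]
#' @param identityMin identity needed to count aligned bases
#' @param k anchor size used for the evaluation alignments
#' @return list with `recall`, `precision`, `novel_bp`, `truth_bp`
#' @export
augmentRecallPrecision <- function(pan, truth, identityMin = 0.90, k = 21L) {
    novel <- novelSegments(pan)
    truthBp <- sum(nchar(truth$sequence))
    novelBp <- sum(Biostrings::width(novel))
    if (nrow(truth) == 0 || length(novel) == 0)
        return(list(recall = as.numeric(nrow(truth) == 0),
                    precision = as.numeric(length(novel) == 0),
                    novel_bp = novelBp, truth_bp = truthBp))
    coveredBases <- function(queries, targets) {
        segs <- alignContigSet(as.list(queries), targets, k = k)
        vapply(seq_along(queries), function(i) {
            s <- segs[[i]]
            s <- s[s$identity >= identityMin, , drop = FALSE]
            if (nrow(s) == 0) return(0L)
            m <- mergeIntervals(data.frame(chrom = "q", start = s$contig_start,
                                           end = s$contig_end))
            sum(m$end - m$start)
        }, 0L)
    }
    tseqs <- stats::setNames(truth$sequence,
                             sprintf("t%04d", seq_len(nrow(truth))))
    recall <- sum(coveredBases(tseqs, novel)) / truthBp
    truthSet <- Biostrings::DNAStringSet(tseqs)
    precision <- sum(coveredBases(stats::setNames(as.character(novel),
                                                  names(novel)),
                                  truthSet)) / novelBp
    list(recall = recall, precision = precision,
         novel_bp = novelBp, truth_bp = truthBp)
}
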