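#' @include AllClasses.R
NULL

# per-stage logging contract: counters and progress go to stderr
pavLog <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Convert between 1-based (VCF) and 0-based half-open (BED) coordinates
#'
#' All genomic intervals inside the package are 0-based half-open; VCF
#' positions are the only 1-based surface.  `toZeroBased()` maps a 1-based
#' position to its 0-based offset; `toOneBased()` is the inverse.
#'
#' @param pos integer vector of positions
#' @return integer vector
#' @examples
#' toZeroBased(1)  # 0
#' toOneBased(0)   # 1
#' @export
toZeroBased <- function(pos) as.integer(pos) - 1L

#' @rdname toZeroBased
#' @export
toOneBased <- function(pos) as.integer(pos) + 1L

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet] with the package's contracts:
#' records are returned in file order, lowercase bases are uppercased,
#' ids are the first whitespace-delimited token of each header and must be
#' unique, and an empty file is an error.
#'
#' @param path FASTA file path
#' @return a [Biostrings::DNAStringSet], names = record ids
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
    names(seqs) <- ids
    if (any(Biostrings::width(seqs) < 1)) stop("zero-length sequence in ", path)
    # normalize case (readDNAStringSet preserves input case)
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- ids
    seqs
}

#' Write sequences as FASTA (80-column wrap)
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path) {
    seqs <- asDNAStringSet(seqs)
    if (is.null(names(seqs))) stop("sequences must be named")
    Biostrings::writeXStringSet(seqs, path, width = 80L)
    invisible(path)
}

#' Read diploid GT genotypes from a VCF file
#'
#' Parses the GT-only subset of VCF v4.2 via [vcfR::read.vcfR]: biallelic
#' SNP rows are converted to alternate-allele dosages (`0/0` -> 0, `0/1` or
#' `1/0` -> 1, `1/1` -> 2, `./.` -> NA); pipe-separated records additionally
#' populate phased haplotypes.  Multiallelic or non-SNP rows are skipped and
#' the skip count is logged to stderr.  A malformed GT field is a hard error
#' reporting the offending file line.
#'
#' @param path VCF file path (plain text or bgzip)
#' @param chromLengths optional named chromosome lengths passed to
#'   [GenotypeMatrix()]
#' @return a [GenotypeMatrix-class]
#' @export
readVcfGenotypes <- function(path, chromLengths = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE, convertNA = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(
        NULL, names(fix)))
    gt <- v@gt
    nMeta <- length(v@meta)          # '##' lines; '#CHROM' header follows
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    snp <- nchar(ref) == 1 & nchar(alt) == 1 &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    nSkip <- sum(!snp)
    if (nSkip > 0)
        pavLog("read_vcf", "skipped %d multiallelic/non-SNP row(s)", nSkip)
    if (!any(snp)) stop("no biallelic SNP rows in ", path)

    fmt <- gt[, 1]
    samples <- colnames(gt)[-1]
    gtField <- function(x, i) {
        # GT is a FORMAT field; locate it per row (usually first)
        idx <- match("GT", strsplit(fmt[i], ":", fixed = TRUE)[[1]])
        vapply(strsplit(x, ":", fixed = TRUE), function(p) p[idx], "")
    }
    rows <- which(snp)
    n <- length(rows)
    dos <- matrix(NA_integer_, n, length(samples),
                  dimnames = list(NULL, samples))
    h1 <- h2 <- matrix(NA_integer_, n, length(samples),
                       dimnames = list(NULL, samples))
    phasedAny <- FALSE
    for (j in seq_len(n)) {
        i <- rows[j]
        g <- gtField(gt[i, -1], i)
        g[is.na(g)] <- "./."
        m <- regmatches(g, regexec("^([0-9.])([/|])([0-9.])$", g))
        bad <- vapply(m, length, 0L) == 0
        if (any(bad))
            stop(sprintf("malformed GT field '%s' at VCF line %d",
                         g[which(bad)[1]], nMeta + 1L + i))
        a1 <- vapply(m, `[`, "", 2)
        sep <- vapply(m, `[`, "", 3)
        a2 <- vapply(m, `[`, "", 4)
        if (any((a1 %in% c("0", "1")) != (a2 %in% c("0", "1"))))
            stop(sprintf("malformed GT (half-missing) at VCF line %d",
                         nMeta + 1L + i))
        miss <- a1 == "."
        dv <- ifelse(miss, NA_integer_,
                     as.integer(a1 == "1") + as.integer(a2 == "1"))
        dos[j, ] <- dv
        ph <- sep == "|" & !miss
        if (any(ph)) {
            phasedAny <- TRUE
            h1[j, ph] <- as.integer(a1[ph] == "1")
            h2[j, ph] <- as.integer(a2[ph] == "1")
        }
    }
    GenotypeMatrix(dos,
                   chrom = fix[rows, "CHROM"],
                   pos = as.integer(fix[rows, "POS"]),
                   ref = ref[rows], alt = alt[rows],
                   hap1 = if (phasedAny) h1 else NULL,
                   hap2 = if (phasedAny) h2 else NULL,
                   chromLengths = chromLengths)
}

#' Write a GenotypeMatrix as a minimal GT-only VCF v4.2
#'
#' @param geno a [GenotypeMatrix-class]
#' @param path output path
#' @param phased write `|`-separated haplotypes when present
#' @return `path`, invisibly
#' @export
writeVcfGenotypes <- function(geno, path, phased = TRUE) {
    rr <- rowRanges(geno)
    d <- dosage(geno)
    hp <- haplotypes(geno)
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    if (!is.null(hp) && phased) {
        gtxt <- matrix(paste0(hp$hap1, "|", hp$hap2), nrow(d), ncol(d))
        gtxt[is.na(hp$hap1)] <- "./."
    } else {
        gtxt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
        gtxt[is.na(d)] <- "./."
    }
    body <- paste(as.character(seqnames(rr)), start(rr), ".",
                  S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt,
                  ".", "PASS", ".", "GT",
                  apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(lines, body), path)
    invisible(path)
}

#' Write intervals as BED
#'
#' Intervals must be 0-based half-open and sorted by (chrom, start);
#' unsorted input is a hard error.  Columns written: chrom, start, end,
#' then `name` and `score` when present.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optional `name`, `score`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeBed <- function(intervals, path) {
    stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
    if (nrow(intervals) > 1) {
        o <- order(intervals$chrom, intervals$start)
        if (!identical(o, seq_len(nrow(intervals))))
            stop("intervals must be sorted by (chrom, start)")
    }
    if (any(intervals$start >= intervals$end))
        stop("intervals must satisfy start < end")
    cols <- c("chrom", "start", "end",
              intersect(c("name", "score"), names(intervals)))
    utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# recursive Newick serializer with fixed 6-decimal branch lengths
newickString <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    rec <- function(node) {
        kids <- children[[as.character(node)]]
        if (is.null(kids)) return(tree$tip.label[node])
        parts <- vapply(kids, function(e) {
            child <- tree$edge[e, 2]
            paste0(rec(child), ":",
                   sprintf("%.6f", tree$edge.length[e]))
        }, "")
        paste0("(", paste(parts, collapse = ","), ")")
    }
    paste0(rec(root), ";")
}

#' Write a tree in Newick format
#'
#' Serializes an `ape` \code{phylo} tree with branch lengths printed to six
#' decimal places and a terminating semicolon, so output is deterministic.
#'
#' @param tree a \code{phylo} object with branch lengths
#' @param path output path
#' @return the Newick string, invisibly
#' @export
writeNewick <- function(tree, path) {
    if (is.null(tree$edge.length)) stop("tree must have branch lengths")
    s <- newickString(tree)
    writeLines(s, path)
    invisible(s)
}

#' Read/write a PAV matrix as TSV
#'
#' The on-disk format is a header row of accession ids, a first column of
#' cluster ids, and `0`/`1` cells.  Group labels are not stored in the
#' matrix file; supply them on read (or a labels TSV with columns
#' `accession`, `group`).
#'
#' @param pav a [PAVMatrix-class]
#' @param path file path
#' @param groups optional labels for [readPavTsv()]: a named character
#'   vector or a labels TSV path
#' @return `writePavTsv`: `path` invisibly; `readPavTsv`: a
#'   [PAVMatrix-class]
#' @export
writePavTsv <- function(pav, path) {
    m <- presence(pav)
    df <- data.frame(cluster = rownames(m), m * 1L, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePavTsv
#' @export
readPavTsv <- function(path, groups = NULL) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c(cluster = "character"))
    m <- as.matrix(df[, -1, drop = FALSE]) == 1
    rownames(m) <- df$cluster
    if (is.character(groups) && length(groups) == 1 && file.exists(groups))
        groups <- readGroupLabels(groups)
    g <- if (is.null(groups)) "all" else unname(groups[colnames(m)])
    PAVMatrix(m, groups = g)
}

#' Read accession group labels from a TSV
#'
#' @param path TSV with columns `accession` and `group`
#' @return named character vector (names = accession ids)
#' @export
readGroupLabels <- function(path) {
    df <- utils::read.delim(path, colClasses = "character")
    stopifnot(all(c("accession", "group") %in% names(df)))
    stats::setNames(df$group, df$accession)
}

#' Window tracks: one statistic over ordered genomic windows
#'
#' A window track is a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open) and `value`, sorted by (chrom, start), carrying the
#' statistic name in `attr(x, "stat")`.  `windowTrack()` validates and
#' normalizes; `readWindowTrack()`/`writeWindowTrack()` round-trip the TSV
#' form (columns chrom/start/end/value).
#'
#' @param chrom,start,end window coordinates (start < end)
#' @param value one finite (or NA) value per window
#' @param stat statistic label
#' @return a `WindowTrack` data.frame
#' @export
windowTrack <- function(chrom, start, end, value, stat = "stat") {
    df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                     end = as.integer(end), value = as.numeric(value))
    if (any(df$start >= df$end)) stop("windows must satisfy start < end")
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    if (any(!is.na(df$value) & !is.finite(df$value)))
        stop("window values must be finite or NA")
    attr(df, "stat") <- stat
    class(df) <- c("WindowTrack", "data.frame")
    df
}

#' @rdname windowTrack
#' @param track a `WindowTrack`
#' @param path TSV path
#' @export
writeWindowTrack <- function(track, path) {
    utils::write.table(as.data.frame(track)[, c("chrom", "start", "end",
                                                "value")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname windowTrack
#' @export
readWindowTrack <- function(path, stat = "stat") {
    df <- utils::read.delim(path)
    windowTrack(df$chrom, df$start, df$end, df$value, stat = stat)
}
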