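# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately written as plain transcriptions (loops, enumeration), kept
# independent of the package implementation paths they check.

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# exactly nSub substitutions, each to a different base
mutateSeq <- function(seq, nSub) {
    ch <- strsplit(seq, "")[[1]]
    idx <- sample(length(ch), nSub)
    ch[idx] <- vapply(ch[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
}

revCompStr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# random PAVMatrix fixture with no empty rows
randomPav <- function(nGene = 20, nAcc = 6, p = 0.5, groups = "all") {
    m <- matrix(stats::runif(nGene * nAcc) < p, nGene, nAcc,
                dimnames = list(sprintf("g%03d", seq_len(nGene)),
                                sprintf("a%02d", seq_len(nAcc))))
    empty <- rowSums(m) == 0
    m[empty, sample(nAcc, 1)] <- TRUE
    PAVMatrix(m, groups = groups)
}

# O(n^2) nucleotide-diversity oracle: per site, enumerate every pair of
# sampled alleles and count differing pairs
piPairwiseOracle <- function(dos, span) {
    total <- 0
    for (s in seq_len(nrow(dos))) {
        x <- dos[s, ]
        x <- x[!is.na(x)]
        alleles <- unlist(lapply(x, function(d) c(rep(1, d), rep(0, 2 - d))))
        n <- length(alleles)
        if (n < 2) next
        diffs <- 0; pairs <- 0
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            pairs <- pairs + 1
            if (alleles[i] != alleles[j]) diffs <- diffs + 1
        }
        total <- total + diffs / pairs
    }
    total / span
}

# independent transcription of the Weir & Cockerham (1984) a/b/c variance
# components for one site, diploid data; returns c(a, b, c)
wcSiteOracle <- function(genos, pops) {
    pops <- as.character(pops)
    pn <- unique(pops)
    r <- length(pn)
    ni <- pi_ <- hi <- numeric(r)
    for (k in seq_len(r)) {
        g <- genos[pops == pn[k]]
        g <- g[!is.na(g)]
        ni[k] <- length(g)
        pi_[k] <- if (length(g)) sum(g) / (2 * length(g)) else NA
        hi[k] <- if (length(g)) mean(g == 1) else NA
    }
    if (any(ni < 1)) return(c(NA, NA, NA))
    nbar <- mean(ni)
    if (nbar <= 1) return(c(NA, NA, NA))
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    if (nc <= 0) return(c(NA, NA, NA))
    pbar <- sum(ni * pi_) / sum(ni)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
}

wcOracle <- function(dos, pops) {
    comp <- t(vapply(seq_len(nrow(dos)), function(s)
        wcSiteOracle(dos[s, ], pops), c(0, 0, 0)))
    ok <- stats::complete.cases(comp)
    sum(comp[ok, 1]) / sum(comp[ok, ])
}

# brute-force re-implementation of the composite sweep filter, written
# directly from its three stages
bruteSweepFilter <- function(score, piW, piD, topScore = 0.05,
                             topRod = 0.5) {
    W <- nrow(score)
    sdv <- stats::sd(score$value)
    z <- if (sdv > 0) (score$value - mean(score$value)) / sdv else rep(0, W)
    ord <- order(-z, score$chrom, score$start)
    sel <- sort(ord[seq_len(ceiling(topScore * W))])
    sel <- sel[piW$value[sel] != 0]
    rod <- piW$value[sel] / piD$value[sel]
    keep <- sort(sel[order(-rod, score$chrom[sel],
                           score$start[sel])[seq_len(ceiling(topRod *
                                                             length(sel)))]])
    # merge overlapping/bookended kept windows
    merged <- list()
    for (i in keep) {
        iv <- c(score$start[i], score$end[i])
        last <- if (length(merged)) merged[[length(merged)]] else NULL
        if (!is.null(last) && iv[1] <= last[2])
            merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
        else merged[[length(merged) + 1L]] <- iv
    }
    list(selected = sel, survivors = keep,
         sweeps = do.call(rbind, merged))
}

# exact hypergeometric upper-tail by enumeration of the binomial
# coefficients (log scale for stability)
hyperTailOracle <- function(k, K, N, nFg) {
    hi <- min(K, nFg)
    if (k > hi) return(0)
    terms <- vapply(k:hi, function(x)
        exp(lchoose(K, x) + lchoose(N - K, nFg - x) - lchoose(N, nFg)), 0)
    sum(terms)
}

# base-level Jaccard of two interval sets on one chromosome
intervalJaccard <- function(a, b, len) {
    covA <- rep(FALSE, len); covB <- rep(FALSE, len)
    for (i in seq_len(nrow(a))) covA[(a$start[i] + 1):a$end[i]] <- TRUE
    for (i in seq_len(nrow(b))) covB[(b$start[i] + 1):b$end[i]] <- TRUE
    sum(covA & covB) / sum(covA | covB)
}
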