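#' @include AllClasses.R simdata.R io.R
NULL

# chromosome lengths for window tiling: declared seqlengths, else max pos
chromLengthsOf <- function(geno) {
    rr <- rowRanges(geno)
    sl <- seqlengths(rr)
    out <- integer(0)
    for (ch in seqlevels(rr)) {
        out[ch] <- if (!is.na(sl[ch])) as.integer(sl[ch])
                   else max(start(rr)[as.character(seqnames(rr)) == ch])
    }
    out
}

# per-site pi from allele counts: with n sampled alleles and c alternate
# copies, pi = 2 c (n - c) / (n (n - 1)) (mean pairwise difference)
sitePi <- function(n, c) ifelse(n < 2, NA_real_, 2 * c * (n - c) /
                                                 (n * (n - 1)))

#' Windowed nucleotide diversity (pi)
#'
#' Per biallelic site with n non-missing alleles and alternate count c,
#' pi_site = 2c(n-c) / (n(n-1)); the window value is the sum of pi_site
#' over sites in the window divided by the window span in bp.  Windows tile
#' each chromosome (full windows only) with the given step; sites with
#' fewer than 2 sampled alleles are skipped with a log message.  At most
#' `maxSitesPerWindow` sites (lowest positions first) are assayed per
#' window.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param samples optional sample-id subset
#' @param window,step window and step size in bp (defaults 1,000 kb /
#'   100 kb)
#' @param maxSitesPerWindow per-window SNP cap (default 600)
#' @return a [windowTrack()] of per-window pi
#' @export
windowPi <- function(geno, samples = NULL, window = 1000000L,
                     step = 100000L, maxSitesPerWindow = 600L) {
    if (window < step) stop("window must be >= step")
    d <- dosage(geno)
    if (!is.null(samples)) d <- d[, samples, drop = FALSE]
    if (ncol(d) == 0) stop("empty sample subset")
    nAll <- 2L * rowSums(!is.na(d))
    cAlt <- rowSums(d, na.rm = TRUE)
    skipped <- sum(nAll < 2)
    if (skipped > 0)
        pavLog("pi", "skipped %d site(s) with fewer than 2 alleles", skipped)
    ps <- sitePi(nAll, cAlt)
    rr <- rowRanges(geno)
    chrom <- as.character(seqnames(rr))
    pos0 <- start(rr) - 1L                      # 0-based site offset
    lens <- chromLengthsOf(geno)
    out <- list()
    for (ch in names(lens)) {
        if (lens[ch] < window) next
        win <- tileWindows(ch, lens[ch], window, step)
        idx <- which(chrom == ch & !is.na(ps))
        val <- vapply(seq_len(nrow(win)), function(w) {
            inw <- idx[pos0[idx] >= win$start[w] & pos0[idx] < win$end[w]]
            if (length(inw) > maxSitesPerWindow)
                inw <- inw[seq_len(maxSitesPerWindow)]
            sum(ps[inw]) / (win$end[w] - win$start[w])
        }, 0)
        out[[ch]] <- cbind(win, value = val)
    }
    df <- do.call(rbind, out)
    windowTrack(df$chrom, df$start, df$end, df$value, stat = "pi")
}

# WC84 variance components per site for diploid data.
# Inputs are S x r matrices: nInd (individuals with data), pFreq (alt
# frequency) and hObs (observed heterozygote frequency).
wcComponents <- function(nInd, pFreq, hObs) {
    r <- ncol(nInd)
    nbar <- rowMeans(nInd)
    sumN <- rowSums(nInd)
    nc <- (sumN - rowSums(nInd^2) / sumN) / (r - 1)
    pbar <- rowSums(nInd * pFreq) / sumN
    s2 <- rowSums(nInd * (pFreq - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(nInd * hObs) / sumN
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) /
             (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    bad <- nbar <= 1 | nc <= 0 | apply(nInd, 1, min) < 1
    a[bad] <- b[bad] <- cc[bad] <- NA_real_
    data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST
#'
#' The Weir & Cockerham (1984) theta estimator for diploid genotypes:
#' per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are computed
#' from per-population sample sizes, allele frequencies and observed
#' heterozygosity; the genome-wide (and optionally per-window) estimate is
#' the ratio of sums, sum(a) / sum(a + b + c).  Sites with undefined
#' components are skipped.  Negative estimates are reported raw unless
#' `clamp = TRUE`.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param groups named group label per sample (names = sample ids), or an
#'   unnamed vector aligned with the samples; >= 2 groups with >= 2
#'   diploids each
#' @param window,step optional window grid for a per-window track; NULL
#'   (default) computes the genome-wide estimate only
#' @param clamp clamp negative estimates at zero
#' @return list with `fst` (genome-wide estimate), `components`
#'   (summed a, b, c) and, when windowed, `track` (a [windowTrack()])
#' @export
weirCockerhamFst <- function(geno, groups, window = NULL, step = NULL,
                             clamp = FALSE) {
    d <- dosage(geno)
    if (!is.null(names(groups))) groups <- groups[colnames(d)]
    groups <- as.character(groups)
    if (length(groups) != ncol(d)) stop("one group label per sample needed")
    gnames <- unique(groups)
    if (length(gnames) < 2) stop("need >= 2 groups")
    sizes <- table(groups)
    if (any(sizes < 2))
        stop("every group needs >= 2 diploid samples")
    S <- nrow(d)
    r <- length(gnames)
    nInd <- pFreq <- hObs <- matrix(0, S, r, dimnames = list(NULL, gnames))
    for (g in gnames) {
        dg <- d[, groups == g, drop = FALSE]
        nInd[, g] <- rowSums(!is.na(dg))
        tot <- 2 * nInd[, g]
        pFreq[, g] <- ifelse(tot > 0, rowSums(dg, na.rm = TRUE) / tot, NA)
        hObs[, g] <- ifelse(nInd[, g] > 0,
                            rowSums(dg == 1, na.rm = TRUE) / nInd[, g], NA)
    }
    comp <- wcComponents(nInd, pFreq, hObs)
    ok <- stats::complete.cases(comp)
    est <- function(idx) {
        den <- sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
        v <- if (den == 0) NA_real_ else sum(comp$a[idx]) / den
        if (clamp && !is.na(v)) max(v, 0) else v
    }
    res <- list(fst = est(which(ok)),
                components = c(a = sum(comp$a[ok]), b = sum(comp$b[ok]),
                               c = sum(comp$c[ok])))
    if (!is.null(window)) {
        if (is.null(step)) step <- window
        rr <- rowRanges(geno)
        chrom <- as.character(seqnames(rr))
        pos0 <- start(rr) - 1L
        lens <- chromLengthsOf(geno)
        out <- list()
        for (ch in names(lens)) {
            if (lens[ch] < window) next
            win <- tileWindows(ch, lens[ch], window, step)
            val <- vapply(seq_len(nrow(win)), function(w) {
                idx <- which(ok & chrom == ch & pos0 >= win$start[w] &
                             pos0 < win$end[w])
                if (!length(idx)) return(NA_real_)
                est(idx)
            }, 0)
            out[[ch]] <- cbind(win, value = val)
        }
        df <- do.call(rbind, out)
        res$track <- windowTrack(df$chrom, df$start, df$end, df$value,
                                 stat = "fst")
    }
    res
}

#' Linkage-disequilibrium decay and half-decay distance
#'
#' Pairwise r-squared for site pairs within `maxDist` on the same
#' chromosome: with phased haplotypes, r^2 = D^2 / (pA qA pB qB) computed
#' from haplotype frequencies (equivalently the squared correlation of the
#' two haplotype indicator columns); without phasing, the squared Pearson
#' correlation of dosages.  Pair values are averaged per distance bin; the
#' half-decay distance is the smallest bin midpoint at which the smoothed
#' (3-bin running mean) curve drops to half its maximum.
#'
#' @param geno a [GenotypeMatrix-class]
#' @param maxDist maximum pair distance in bp
#' @param binWidth distance bin width in bp
#' @param usePhased use haplotypes when available (default)
#' @return list with `bins` (data.frame: mid, mean_r2, n_pairs),
#'   `half_decay_distance` (bp, NA when the curve never halves)
#' @export
ldDecay <- function(geno, maxDist = 500000L, binWidth = 1000L,
                    usePhased = TRUE) {
    hp <- haplotypes(geno)
    rr <- rowRanges(geno)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    X <- if (!is.null(hp) && usePhased)
        cbind(hp$hap1, hp$hap2)            # sites x (2 * samples)
    else dosage(geno)
    keep <- apply(X, 1, function(x) stats::sd(x, na.rm = TRUE) > 0)
    dists <- numeric(0); r2s <- numeric(0)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch & keep)
        if (length(idx) < 2) next
        p <- pos[idx]
        for (ii in seq_len(length(idx) - 1)) {
            jj <- which(p > p[ii] & p - p[ii] <= maxDist)
            jj <- jj[jj > ii]
            if (!length(jj)) next
            r <- suppressWarnings(stats::cor(
                X[idx[ii], ], t(X[idx[jj], , drop = FALSE]),
                use = "pairwise.complete.obs"))
            r2 <- as.numeric(r)^2
            okp <- !is.na(r2)
            dists <- c(dists, (p[jj] - p[ii])[okp])
            r2s <- c(r2s, r2[okp])
        }
    }
    if (!length(r2s))
        return(list(bins = data.frame(mid = numeric(0),
                                      mean_r2 = numeric(0),
                                      n_pairs = integer(0)),
                    half_decay_distance = NA_real_))
    bin <- floor((dists - 1) / binWidth)
    agg <- tapply(r2s, bin, mean)
    cnt <- tapply(r2s, bin, length)
    mids <- (as.numeric(names(agg)) + 0.5) * binWidth
    o <- order(mids)
    bins <- data.frame(mid = mids[o], mean_r2 = as.numeric(agg)[o],
                       n_pairs = as.integer(cnt)[o])
    list(bins = bins, half_decay_distance = halfDecayFromBins(bins))
}

# smallest bin midpoint at which the smoothed (3-bin running mean) curve
# drops to half its maximum
halfDecayFromBins <- function(bins) {
    if (nrow(bins) == 0) return(NA_real_)
    sm <- if (nrow(bins) >= 3)
        as.numeric(stats::filter(bins$mean_r2, rep(1 / 3, 3), sides = 2))
    else rep(NA_real_, nrow(bins))
    sm[is.na(sm)] <- bins$mean_r2[is.na(sm)]
    half <- which(sm <= max(sm) / 2)
    if (length(half)) bins$mid[min(half)] else NA_real_
}

# shared window-grid check
sameGrid <- function(a, b) {
    identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
        identical(a$end, b$end)
}

#' Composite selective-sweep filter
#'
#' The two-stage filter applied to a cross-population selection-score track:
#' (1) scores are z-normalized genome-wide and the top
#' `ceiling(topScore * W)` windows by normalized score are selected (ties
#' broken by genomic order); (2) the reduction of diversity
#' ROD = pi_wild / pi_dom is computed per selected window and the top
#' `ceiling(topRod * n_selected)` by ROD are kept, with infinite ROD
#' (pi_dom = 0) ranked highest; (3) surviving windows that overlap or are
#' bookended are merged into sweep intervals.  Windows with pi_wild = 0 are
#' excluded from the selected set with a log message.  All intermediate
#' window sets are returned for audit.
#'
#' @param score,piWild,piDom [windowTrack()]s on an identical window grid
#' @param topScore fraction of windows passing the score stage (default
#'   0.05)
#' @param topRod fraction of selected windows kept by ROD (default 0.50)
#' @return list with `sweeps` (data.frame: chrom, start, end, n_windows,
#'   max_score_z, min_rod), `selected`, `survivors` (audit window sets with
#'   normalized score and ROD), `score_z` (normalized score track)
#' @export
sweepFilter <- function(score, piWild, piDom, topScore = 0.05,
                        topRod = 0.50) {
    if (!sameGrid(score, piWild) || !sameGrid(score, piDom))
        stop("score and pi tracks must share an identical window grid")
    W <- nrow(score)
    sdv <- stats::sd(score$value)
    z <- if (sdv > 0) (score$value - mean(score$value)) / sdv
         else rep(0, W)
    ordSel <- order(-z, score$chrom, score$start)
    nSel <- ceiling(topScore * W)
    sel <- sort(ordSel[seq_len(nSel)])
    zeroPi <- piWild$value[sel] == 0
    if (any(zeroPi)) {
        pavLog("sweep", "excluded %d selected window(s) with pi_wild = 0",
               sum(zeroPi))
        sel <- sel[!zeroPi]
    }
    rod <- piWild$value[sel] / piDom$value[sel]
    selected <- data.frame(chrom = score$chrom[sel],
                           start = score$start[sel], end = score$end[sel],
                           score_z = z[sel], rod = rod)
    nKeep <- ceiling(topRod * length(sel))
    ordRod <- order(-rod, selected$chrom, selected$start)
    keep <- sort(ordRod[seq_len(nKeep)])
    survivors <- selected[keep, , drop = FALSE]
    rownames(survivors) <- NULL
    sweeps <- if (nrow(survivors) == 0)
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), n_windows = integer(0),
                   max_score_z = numeric(0), min_rod = numeric(0))
    else {
        mg <- mergeIntervals(survivors[, c("chrom", "start", "end")])
        mg$n_windows <- mg$max_score_z <- mg$min_rod <- NA
        for (i in seq_len(nrow(mg))) {
            inm <- survivors$chrom == mg$chrom[i] &
                survivors$start >= mg$start[i] &
                survivors$end <= mg$end[i]
            mg$n_windows[i] <- sum(inm)
            mg$max_score_z[i] <- max(survivors$score_z[inm])
            mg$min_rod[i] <- min(survivors$rod[inm])
        }
        mg
    }
    list(sweeps = sweeps, selected = selected, survivors = survivors,
         score_z = windowTrack(score$chrom, score$start, score$end, z,
                               stat = "score_z"))
}

#' LTR Assembly Index
#'
#' LAI = intact LTR-RT length / total LTR-RT length x 100.
#'
#' @param intactBp total length of intact LTR retrotransposons (bp)
#' @param totalBp total LTR retrotransposon length (bp, > 0)
#' @return the LAI value
#' @examples
#' lai(500, 2000)  # 25
#' @export
lai <- function(intactBp, totalBp) {
    if (any(totalBp <= 0)) stop("total LTR-RT length must be > 0")
    if (any(intactBp < 0) || any(intactBp > totalBp))
        stop("intact length must be in [0, total]")
    intactBp / totalBp * 100
}
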