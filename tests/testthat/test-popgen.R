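genoFromDosage <- function(dos, pos = NULL, chromLen = NULL,
                           chrom = "chr1") {
    if (is.null(pos)) pos <- seq_len(nrow(dos)) * 10L
    cl <- if (!is.null(chromLen)) setNames(chromLen, chrom) else NULL
    GenotypeMatrix(dos, chrom = rep(chrom, nrow(dos)), pos = pos,
                   chromLengths = cl)
}

test_that("window pi reproduces the single-site hand computation", {
    # one site, 2 diploids, dosages (1,1): n = 4 alleles, c = 2,
    # pi_site = 8/12; over a 100 bp window: 0.0066667
    d <- matrix(c(1L, 1L), 1, 2, dimnames = list(NULL, c("s1", "s2")))
    g <- genoFromDosage(d, pos = 50L, chromLen = 100L)
    tr <- windowPi(g, window = 100L, step = 100L)
    expect_equal(tr$value, (2 * 2 * 2 / (4 * 3)) / 100)
    # monomorphic window: pi = 0
    d0 <- matrix(0L, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
    g0 <- genoFromDosage(d0, pos = c(10L, 20L, 30L), chromLen = 100L)
    expect_equal(windowPi(g0, window = 100L, step = 100L)$value, 0)
})

test_that("window pi equals the all-pairs pairwise-difference oracle", {
    set.seed(51)
    for (rep in 1:10) {
        n <- sample(2:10, 1); S <- sample(5:60, 1)
        d <- matrix(sample(c(0:2, NA), S * n, replace = TRUE,
                           prob = c(.3, .3, .3, .1)), S, n,
                    dimnames = list(NULL, paste0("s", 1:n)))
        g <- genoFromDosage(d, pos = sort(sample.int(5000, S)),
                            chromLen = 5000L)
        tr <- suppressMessages(windowPi(g, window = 5000L, step = 5000L))
        expect_equal(tr$value, piPairwiseOracle(d, 5000), tolerance = 1e-12)
    }
})

test_that("WC84 FST handles the fixed-difference and no-variance limits", {
    # two pops of 2 diploids, fixed difference: theta = 1
    d <- matrix(c(2L, 2L, 0L, 0L), 1, 4,
                dimnames = list(NULL, c("p1a", "p1b", "p2a", "p2b")))
    g <- genoFromDosage(d)
    grp <- c(p1a = "P1", p1b = "P1", p2a = "P2", p2b = "P2")
    expect_equal(weirCockerhamFst(g, grp)$fst, 1)
    # identical allele frequencies 0.5, het-free and balanced: theta <= 0
    d2 <- matrix(c(2L, 0L, 2L, 0L), 1, 4,
                 dimnames = list(NULL, names(grp)))
    expect_lte(weirCockerhamFst(genoFromDosage(d2), grp)$fst, 0)
})

test_that("WC84 matches the component oracle on a mixed-genotype case", {
    # pop1 {AA, Aa}, pop2 {aa, aa}
    d <- matrix(c(2L, 1L, 0L, 0L), 1, 4,
                dimnames = list(NULL, c("p1a", "p1b", "p2a", "p2b")))
    grp <- c(p1a = "P1", p1b = "P1", p2a = "P2", p2b = "P2")
    got <- weirCockerhamFst(genoFromDosage(d), grp)
    comp <- wcSiteOracle(d[1, ], grp)
    expect_equal(got$fst, comp[1] / sum(comp), tolerance = 1e-12)
    expect_equal(unname(got$components), comp, tolerance = 1e-12)
})

test_that("WC84 agrees with the oracle across random small datasets", {
    set.seed(53)
    for (rep in 1:25) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        S <- sample(3:30, 1)
        d <- matrix(sample(c(0:2, NA), S * (n1 + n2), replace = TRUE,
                           prob = c(.35, .3, .3, .05)), S, n1 + n2,
                    dimnames = list(NULL, paste0("s", seq_len(n1 + n2))))
        grp <- setNames(rep(c("A", "B"), c(n1, n2)), colnames(d))
        got <- weirCockerhamFst(genoFromDosage(d), grp)$fst
        want <- wcOracle(d, rep(c("A", "B"), c(n1, n2)))
        if (is.nan(want)) next
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("groups smaller than two diploids are rejected", {
    d <- matrix(0:2, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_error(weirCockerhamFst(genoFromDosage(d),
                                  c(a = "X", b = "X", c = "Y")),
                 ">= 2 diploid")
})

test_that("LD r-squared matches hand computations", {
    # duplicated column: r^2 = 1
    h <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 1, 6)
    h2 <- rbind(h, h)
    g <- GenotypeMatrix(h2[, 1:3] + h2[, 4:6],
                        chrom = c("c", "c"), pos = c(100L, 200L),
                        hap1 = h2[, 1:3], hap2 = h2[, 4:6])
    ld <- ldDecay(g, maxDist = 1000L, binWidth = 100L)
    expect_equal(ld$bins$mean_r2, 1)
    # haplotypes (A,B),(A,b),(a,B),(A,B): r^2 = 1/9
    hapA <- c(1L, 1L, 0L, 1L)
    hapB <- c(1L, 0L, 1L, 1L)
    h1 <- rbind(hapA[c(1, 3)], hapB[c(1, 3)])
    h2b <- rbind(hapA[c(2, 4)], hapB[c(2, 4)])
    gg <- GenotypeMatrix(h1 + h2b, chrom = c("c", "c"),
                         pos = c(100L, 200L), hap1 = h1, hap2 = h2b)
    ld2 <- ldDecay(gg, maxDist = 1000L, binWidth = 100L)
    expect_equal(ld2$bins$mean_r2, 1 / 9, tolerance = 1e-12)
})

test_that("half-decay distance matches the analytic closed form", {
    lambda <- 2000
    d <- seq(50, 20000, by = 100)
    bins <- data.frame(mid = d, mean_r2 = exp(-d / lambda),
                       n_pairs = 100L)
    hd <- panpav:::halfDecayFromBins(bins)
    expect_lt(abs(hd - lambda * log(2)), 100)  # within one bin
})

test_that("sweep filter keeps exactly ceil(5%) then ceil(50%) windows", {
    set.seed(61)
    W <- 100
    win <- windowTrack(rep("c", W), (0:(W - 1)) * 100000L,
                       (0:(W - 1)) * 100000L + 1000000L,
                       sample(seq_len(W)))  # distinct scores
    piW <- windowTrack(win$chrom, win$start, win$end, runif(W, 1e-4, 1e-3))
    piD <- windowTrack(win$chrom, win$start, win$end, runif(W, 1e-4, 1e-3))
    sf <- sweepFilter(win, piW, piD)
    expect_equal(nrow(sf$selected), 5)
    expect_equal(nrow(sf$survivors), 3)
})

test_that("bookended surviving windows merge into one sweep", {
    win <- windowTrack(rep("c", 2), c(0L, 100000L),
                       c(1000000L, 1100000L), c(10, 9))
    piW <- windowTrack(win$chrom, win$start, win$end, c(1e-3, 1e-3))
    piD <- windowTrack(win$chrom, win$start, win$end, c(1e-4, 1e-4))
    sf <- sweepFilter(win, piW, piD, topScore = 1, topRod = 1)
    expect_equal(nrow(sf$sweeps), 1)
    expect_equal(sf$sweeps$start, 0)
    expect_equal(sf$sweeps$end, 1100000)
    # mismatched grids are a hard error
    bad <- windowTrack("c", 50000L, 1050000L, 1)
    expect_error(sweepFilter(win, bad, piD), "identical window grid")
})

test_that("sweep filter agrees with a brute-force oracle on random tracks", {
    set.seed(63)
    for (rep in 1:25) {
        W <- sample(20:120, 1)
        st <- (0:(W - 1)) * 100000L
        sc <- windowTrack(rep("c", W), st, st + 1000000L,
                          rlnorm(W, 0, 1))
        pw <- windowTrack(sc$chrom, sc$start, sc$end, runif(W, 0, 1e-3))
        pw$value[sample(W, 2)] <- 0   # exercise the pi_wild = 0 exclusion
        pd <- windowTrack(sc$chrom, sc$start, sc$end, runif(W, 1e-5, 1e-3))
        got <- suppressMessages(sweepFilter(sc, pw, pd))
        want <- bruteSweepFilter(sc, pw, pd)
        expect_equal(match(paste(got$selected$start),
                           paste(sc$start)), want$selected)
        expect_equal(match(paste(got$survivors$start),
                           paste(sc$start)), want$survivors)
        expect_equal(got$sweeps$start, want$sweeps[, 1])
        expect_equal(got$sweeps$end, want$sweeps[, 2])
    }
})

test_that("planted sweeps are recovered from simulated tracks", {
    cfg <- simConfig(seed = 65)
    tracks <- simulateSweepTracks(cfg)
    sf <- sweepFilter(tracks$score, tracks$pi_wild, tracks$pi_dom)
    expect_gte(intervalJaccard(sf$sweeps, tracks$truth,
                               cfg$chrom_length), 0.8)
})

test_that("LAI follows its defining formula", {
    expect_equal(lai(2000, 2000), 100)
    expect_equal(lai(0, 2000), 0)
    expect_equal(lai(500, 2000), 25)
    expect_error(lai(10, 0), "> 0")
    expect_error(lai(30, 20), "\\[0, total\\]")
})
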