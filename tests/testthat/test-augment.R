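test_that("an exact substring aligns as one full-identity segment", {
    set.seed(1)
    pan <- setNames(randomSeq(10000), "ref")
    contig <- substring(pan, 2001, 3000)
    seg <- anchorAlign(contig, pan)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$contig_start, 0)
    expect_equal(seg$contig_end, 1000)
    expect_equal(seg$identity, 1.0)
    expect_equal(seg$target_start, 2000)
    expect_equal(seg$strand, "+")
})

test_that("reverse-complement contigs align with the strand flag set", {
    set.seed(2)
    pan <- setNames(randomSeq(10000), "ref")
    fwd <- substring(pan, 5001, 6000)
    seg <- anchorAlign(revCompStr(fwd), pan)
    expect_equal(nrow(seg), 1)
    expect_equal(seg$strand, "-")
    expect_equal(seg$identity, 1.0)
    expect_equal(seg$target_start, 5000)
    expect_equal(seg$target_end, 6000)
})

test_that("reported identity tracks a dynamic-programming oracle", {
    set.seed(3)
    for (rep in 1:5) {
        pan <- setNames(randomSeq(5000), "ref")
        frag <- substring(pan, 1001, 2000)
        contig <- mutateSeq(frag, 50)          # 5% substitutions
        seg <- anchorAlign(contig, pan)
        seg <- seg[which.max(seg$length), ]
        ali <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(contig), Biostrings::DNAString(frag),
            type = "global")
        oracleId <- Biostrings::nmatch(ali) / Biostrings::nchar(ali)
        expect_lt(abs(seg$identity - oracleId), 0.01)
    }
})

test_that("trim-and-retain applies the printed thresholds and partitions", {
    contig <- strrep("A", 1000)   # content irrelevant to the arithmetic
    segs <- data.frame(contig_start = c(0L, 550L), contig_end = c(400L,
                                                                  1000L),
                       target_id = "r", target_start = 0L, target_end = 1L,
                       strand = "+", length = c(400L, 450L),
                       matches = c(390L, 440L),
                       identity = c(0.975, 0.978))
    tr <- trimAndRetain(contig, segs)
    expect_equal(tr$retained$start, 400)
    expect_equal(tr$retained$end, 550)
    expect_equal(nchar(tr$retained$sequence), 150)

    # full coverage retains nothing
    one <- data.frame(contig_start = 0L, contig_end = 1000L,
                      target_id = "r", target_start = 0L,
                      target_end = 1000L, strand = "+", length = 1000L,
                      matches = 1000L, identity = 1)
    expect_equal(nrow(trimAndRetain(contig, one)$retained), 0)

    # an 80 bp segment at identity 0.95 fails the length floor: its bases
    # stay in the retained complement
    short <- data.frame(contig_start = 100L, contig_end = 180L,
                        target_id = "r", target_start = 0L,
                        target_end = 80L, strand = "+", length = 80L,
                        matches = 76L, identity = 0.95)
    tr2 <- trimAndRetain(contig, short)
    expect_equal(nrow(tr2$retained), 1)
    expect_equal(tr2$retained$start, 0)
    expect_equal(tr2$retained$end, 1000)
})

test_that("qualifying, retained and short intervals partition every contig", {
    set.seed(4)
    for (rep in 1:20) {
        L <- sample(500:3000, 1)
        n <- sample(0:5, 1)
        segs <- if (n == 0) data.frame(contig_start = integer(0),
                                       contig_end = integer(0),
                                       identity = numeric(0),
                                       length = integer(0))
        else {
            st <- sample(0:(L - 50), n)
            en <- pmin(st + sample(30:500, n, replace = TRUE), L)
            data.frame(contig_start = st, contig_end = en,
                       identity = runif(n, 0.85, 1),
                       length = en - st)
        }
        tr <- trimAndRetain(strrep("A", L), segs)
        covered <- sum(tr$qualifying$end - tr$qualifying$start) +
            sum(tr$retained$end - tr$retained$start) +
            sum(tr$discarded$end - tr$discarded$start)
        expect_equal(covered, L)
    }
})

test_that("augmenting the reference with itself adds nothing", {
    set.seed(5)
    ref <- Biostrings::DNAStringSet(setNames(randomSeq(50000), "chr1"))
    res <- augmentIterative(ref, list(self = ref))
    expect_equal(res$report$novel_bp, 0)
    expect_equal(panSize(res$pan), 50000)
})

test_that("augmentation recovers planted novelty and is idempotent", {
    cfg <- simConfig(seed = 17, chrom_length = 1000000L,
                     n_assemblies = 3L, n_contigs = 3L,
                     contig_length = 100000L, sweep_specs = list())
    ref <- simulateReference(cfg)
    asm <- simulateAssemblies(cfg, ref)
    res <- augmentIterative(ref, asm$assemblies)
    rp <- augmentRecallPrecision(res$pan, asm$truth)
    expect_gte(rp$recall, 0.99)
    expect_gte(rp$precision, 0.99)
    # provenance rows describe real intervals of the source contigs
    prov <- panProvenance(res$pan)
    novel <- prov[!is.na(prov$accession), ]
    for (i in seq_len(nrow(novel))) {
        src <- asm$assemblies[[novel$accession[i]]][[novel$contig[i]]]
        expect_identical(
            as.character(Biostrings::subseq(src, novel$start[i] + 1,
                                            novel$end[i])),
            as.character(panSequences(res$pan)[[novel$segment_id[i]]]))
    }
    # a second pass over already-augmented accessions adds 0 bp
    res2 <- augmentIterative(res$pan, asm$assemblies)
    expect_equal(sum(res2$report$novel_bp), 0)
    expect_equal(panSize(res2$pan), panSize(res$pan))
})

test_that("total novel bp is insensitive to accession order", {
    cfg <- simConfig(seed = 19, chrom_length = 1000000L,
                     n_assemblies = 3L, n_contigs = 3L,
                     contig_length = 100000L, sweep_specs = list())
    asm <- simulateAssemblies(cfg)
    ids <- names(asm$assemblies)
    r1 <- augmentIterative(simulateReference(cfg), asm$assemblies,
                           order = ids)
    r2 <- augmentIterative(simulateReference(cfg), asm$assemblies,
                           order = rev(ids))
    t1 <- sum(r1$report$novel_bp); t2 <- sum(r2$report$novel_bp)
    expect_lt(abs(t1 - t2) / max(t1, t2), 0.01)
})

test_that("duplicate accession ids are rejected", {
    s <- Biostrings::DNAStringSet(setNames(randomSeq(1000), "c"))
    expect_error(augmentIterative(s, setNames(list(s, s), c("a", "a"))),
                 "duplicate")
})
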