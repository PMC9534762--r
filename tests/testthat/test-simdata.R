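smallCfg <- function(...) {
    args <- list(groups = c(A = 10L, B = 10L),
                 group_preferred = c(A = 2L, B = 2L),
                 n_core = 10L, n_softcore = 5L, n_shell = 10L,
                 n_cloud = 10L, chrom_length = 2000000L, n_sites = 200L,
                 sweep_specs = list(), n_assemblies = 2L, n_contigs = 2L,
                 contig_length = 50000L)
    over <- list(...)
    args[names(over)] <- over
    do.call(simConfig, args)
}

test_that("unknown or invalid sim configuration is rejected", {
    expect_error(simConfig(fst_param = 1.2), "fst_param")
    expect_error(simConfig(bogus_key = 1), "unused argument")
    expect_error(simConfig(sweep_specs = list(list(start = 0,
                                                   end = 2e8))),
                 "outside chromosome")
})

test_that("planted PAV occupancies respect their class bands", {
    cfg <- simConfig(seed = 3, n_cloud = 200L)
    sp <- simulatePav(cfg)
    N <- ncol(presence(sp$pav))
    expect_equal(N, 116L)
    occ <- rowSums(presence(sp$pav))
    tr <- sp$truth
    expect_true(all(occ[tr$class == "core"] >= ceiling(0.99 * N)))
    sc <- occ[tr$class == "softcore"]
    expect_true(all(sc >= ceiling(0.90 * N) & sc < ceiling(0.99 * N)))
    sh <- occ[tr$class == "shell"]
    expect_true(all(sh >= ceiling(0.15 * N) & sh < ceiling(0.90 * N)))
    expect_true(all(occ[tr$class == "cloud"] < ceiling(0.15 * N)))
    # planted core at N = 116 means occupancy >= 115 (0.99 * 116 = 114.84)
    expect_true(all(occ[tr$class == "core"] >= 115))
})

test_that("a config with no shell/cloud genes gives occupancy >= 90%", {
    cfg <- simConfig(seed = 5, groups = c(A = 20L, B = 20L),
                     n_shell = 0L, n_cloud = 0L,
                     group_preferred = c(A = 0L, B = 0L),
                     sweep_specs = list())
    sp <- simulatePav(cfg)
    expect_true(all(rowSums(presence(sp$pav)) >= 0.90 * 40))
})

test_that("group-preferred genes stay in band and leak at most 5%", {
    cfg <- simConfig(seed = 9)
    sp <- simulatePav(cfg)
    m <- presence(sp$pav)
    grp <- accessionGroups(sp$pav)
    pref <- sp$truth[!is.na(sp$truth$pref_group), ]
    for (g in unique(pref$pref_group)) {
        rows <- pref$cluster[pref$pref_group == g]
        own <- m[rows, grp == g, drop = FALSE]
        oth <- m[rows, grp != g, drop = FALSE]
        expect_true(all(rowSums(own) >= 0.8 * ncol(own)))
        expect_true(all(rowSums(oth) <= 0.05 * ncol(oth)))
    }
})

test_that("infeasible class bands are a hard error", {
    expect_error(simulatePav(smallCfg(groups = c(A = 3L, B = 3L),
                                      group_preferred = c(A = 0L, B = 0L))),
                 "band.*empty|empty.*band")
})

test_that("generators are deterministic under the config seed", {
    cfg <- smallCfg(seed = 13)
    expect_identical(presence(simulatePav(cfg)$pav),
                     presence(simulatePav(cfg)$pav))
    expect_identical(dosage(simulateGenotypes(cfg)),
                     dosage(simulateGenotypes(cfg)))
    a1 <- simulateAssemblies(cfg)
    a2 <- simulateAssemblies(cfg)
    expect_identical(lapply(a1$assemblies, as.character),
                     lapply(a2$assemblies, as.character))
    cfgSw <- smallCfg(seed = 13, sweep_specs = list(
        list(start = 200000L, end = 1400000L)))
    expect_identical(simulateSweepTracks(cfgSw)$score$value,
                     simulateSweepTracks(cfgSw)$score$value)
})

test_that("zero noise and zero novelty give exact reference substrings", {
    cfg <- smallCfg(seed = 21, backbone_divergence = 0,
                    novel_per_accession = 0L)
    ref <- simulateReference(cfg)
    asm <- simulateAssemblies(cfg, ref)
    expect_equal(nrow(asm$truth), 0)
    refStr <- as.character(ref[[1]])
    for (acc in names(asm$assemblies))
        for (ctg in as.character(asm$assemblies[[acc]]))
            expect_true(grepl(ctg, refStr, fixed = TRUE))
})

test_that("planted novel inserts are recorded at their true coordinates", {
    cfg <- smallCfg(seed = 22, novel_per_accession = 2L,
                    novel_length_range = c(150L, 150L))
    asm <- simulateAssemblies(cfg)
    expect_equal(nrow(asm$truth), 4)
    expect_true(all(asm$truth$end - asm$truth$start == 150))
    for (i in seq_len(nrow(asm$truth))) {
        ctg <- as.character(
            asm$assemblies[[asm$truth$accession[i]]][[asm$truth$contig[i]]])
        expect_identical(substring(ctg, asm$truth$start[i] + 1,
                                   asm$truth$end[i]),
                         asm$truth$sequence[i])
    }
})

test_that("Balding-Nichols genotypes match the model's moments", {
    # F -> 0: group allele-frequency differences vanish
    cfg <- simConfig(seed = 31, groups = c(A = 50L, B = 50L),
                     fst_param = 1e-6, n_sites = 5000L,
                     group_preferred = c(A = 0L, B = 0L),
                     sweep_specs = list())
    g <- simulateGenotypes(cfg)
    d <- dosage(g)
    pg <- S4Vectors::metadata(g)$group_freq
    # latent group allele frequencies coincide as F -> 0
    expect_lt(mean(abs(pg[, "A"] - pg[, "B"])), 0.01)
    # dosage mean per site ~ 2 p within binomial error: standardized
    # residuals have unit variance
    n <- ncol(d)
    pbar <- rowMeans(pg)
    z <- (rowMeans(d) - 2 * pbar) /
        sqrt(2 * pbar * (1 - pbar) / n)
    expect_gt(mean(z^2), 0.9); expect_lt(mean(z^2), 1.1)
})

test_that("phased haplotypes sum to the dosage", {
    g <- simulateGenotypes(smallCfg(seed = 41))
    hp <- haplotypes(g)
    expect_identical(hp$hap1 + hp$hap2, dosage(g))
})

test_that("sweep windows inside a planted sweep exceed the background", {
    cfg <- simConfig(seed = 51)    # one sweep, multiplier 10
    tracks <- simulateSweepTracks(cfg)
    sw <- cfg$sweep_specs[[1]]
    inside <- tracks$score$start >= sw$start & tracks$score$end <= sw$end
    bg <- tracks$score$value[!inside]
    expect_true(all(tracks$score$value[inside] >
                    stats::quantile(bg, 0.95)))
    # domesticated pi reduced inside the sweep
    rod <- tracks$pi_wild$value / tracks$pi_dom$value
    expect_gt(min(rod[inside]), max(rod[!inside]))
})

test_that("overlapping planted sweeps are merged in the truth", {
    cfg <- smallCfg(seed = 55, sweep_specs = list(
        list(start = 0L, end = 1200000L),
        list(start = 1100000L, end = 1800000L)))
    expect_warning(tracks <- simulateSweepTracks(cfg), "merged")
    expect_equal(nrow(tracks$truth), 1)
    expect_equal(tracks$truth$end, 1800000)
})

test_that("coverage simulation is exact truth at zero noise", {
    cfg <- smallCfg(seed = 61, coverage_dropout = 0, annotation_dropout = 0)
    sp <- simulatePav(cfg)
    cov <- simulateCoverage(cfg, sp$pav)
    rebuilt <- buildPavMatrix(cov$members, cov$coverage,
                              groups = accessionGroups(sp$pav),
                              accessions = colnames(presence(sp$pav)),
                              clusterIds = rownames(presence(sp$pav)))
    expect_identical(presence(rebuilt), presence(sp$pav))
})
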