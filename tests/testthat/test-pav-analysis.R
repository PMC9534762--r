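pavFromCounts <- function(counts, N) {
    # build a PAV matrix whose rows have exactly the requested occupancies
    m <- t(vapply(counts, function(k) {
        v <- logical(N); v[seq_len(k)] <- TRUE; v
    }, logical(N)))
    rownames(m) <- sprintf("g%03d", seq_along(counts))
    colnames(m) <- sprintf("a%03d", seq_len(N))
    PAVMatrix(m)
}

test_that("classification bands are exact at the printed boundaries", {
    pav <- pavFromCounts(c(116, 115, 114, 105, 104, 18, 17, 1), 116)
    cl <- classifyPanGenes(pav)
    expect_equal(cl$classes$class,
                 c("core", "core", "softcore", "softcore", "shell",
                   "shell", "cloud", "cloud"))
    expect_equal(unname(cl$totals),
                 c(2L, 2L, 2L, 2L))
    # N = 2: both present => fraction 1 => core
    expect_equal(classifyPanGenes(pavFromCounts(2, 2))$classes$class,
                 "core")
    expect_equal(sum(cl$totals), nrow(presence(pav)))
})

test_that("every occupancy fraction is classified exactly once", {
    for (N in c(2, 7, 50, 116)) {
        pav <- pavFromCounts(seq_len(N), N)
        cl <- classifyPanGenes(pav)$classes
        expect_false(anyNA(cl$class))
        expect_equal(sum(table(cl$class)), N)
        # bands partition: class is a function of fraction with the
        # documented cut points
        expected <- ifelse(cl$fraction >= 0.99, "core",
                    ifelse(cl$fraction >= 0.90, "softcore",
                    ifelse(cl$fraction >= 0.15, "shell", "cloud")))
        expect_identical(cl$class, expected)
    }
})

test_that("group-restricted classification uses the group's columns", {
    m <- cbind(matrix(TRUE, 4, 3), matrix(FALSE, 4, 3))
    m[4, ] <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
    dimnames(m) <- list(paste0("g", 1:4), paste0("a", 1:6))
    pav <- PAVMatrix(m, groups = rep(c("X", "Y"), each = 3))
    clX <- classifyPanGenes(pav, group = "X")
    expect_equal(clX$classes$class[1], "core")
})

test_that("accumulation curves match exhaustive enumeration at N = 4", {
    set.seed(23)
    pav <- randomPav(15, 4)
    cv <- panCoreCurves(pav, nPerm = 100, seed = 1)   # 4! = 24 <= 100
    m <- presence(pav)
    perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
    perms <- perms[apply(perms, 1, function(x)
        length(unique(x)) == 4), , drop = FALSE]
    panEx <- coreEx <- matrix(0, nrow(perms), 4)
    for (i in seq_len(nrow(perms))) for (n in 1:4) {
        sub <- m[, perms[i, 1:n], drop = FALSE]
        panEx[i, n] <- sum(rowSums(sub) > 0)
        coreEx[i, n] <- sum(rowSums(sub) == n)
    }
    expect_equal(cv$pan_mean, colMeans(panEx))
    expect_equal(cv$core_mean, colMeans(coreEx))
    # n = 1: pan = core = genes present in that accession
    expect_equal(cv$pan_mean[1], cv$core_mean[1])
})

test_that("identical accessions give constant curves", {
    m <- matrix(TRUE, 5, 4, dimnames = list(paste0("g", 1:5),
                                            paste0("a", 1:4)))
    m[4:5, ] <- FALSE; m[4, 1:4] <- TRUE   # keep rows non-empty
    m[5, ] <- TRUE
    cv <- panCoreCurves(PAVMatrix(m), nPerm = 10, seed = 2)
    expect_true(all(cv$pan_mean == cv$pan_mean[1]))
    expect_true(all(cv$core_mean == cv$core_mean[1]))
})

test_that("curve means are monotone on generated data", {
    set.seed(29)
    for (rep in 1:5) {
        cv <- panCoreCurves(randomPav(30, 8, p = runif(1, 0.2, 0.8)),
                            nPerm = 20, seed = rep)
        expect_true(all(diff(cv$pan_mean) >= -1e-9))
        expect_true(all(diff(cv$core_mean) <= 1e-9))
    }
})

test_that("saturation fits recover parameters from noiseless curves", {
    n <- 1:40
    curve <- data.frame(n = n, pan_mean = 500 * n^0.3 + 100, pan_sd = 0,
                        core_mean = 900 * exp(-n / 4) + 250, core_sd = 0)
    ft <- fitSaturationModels(curve)
    expect_lt(abs(ft$pan$gamma - 0.3), 0.02)
    expect_lt(abs(ft$core$Omega - 250) / 250, 0.01)
    # constant core curve is flagged, never fitted silently
    curve$core_mean <- 300
    ft2 <- fitSaturationModels(curve)
    expect_equal(ft2$core$flag, "degenerate-constant")
    expect_equal(ft2$core$Omega, 300)
})

test_that("core-model intercept recovers the planted strict core", {
    cfg <- simConfig(seed = 37, groups = c(A = 25L, B = 25L),
                     group_preferred = c(A = 5L, B = 5L),
                     n_core = 80L, n_softcore = 30L, n_shell = 100L,
                     n_cloud = 100L, sweep_specs = list())
    sp <- simulatePav(cfg)
    strictCore <- sum(rowSums(presence(sp$pav)) ==
                      ncol(presence(sp$pav)))
    cv <- panCoreCurves(sp$pav, nPerm = 100, seed = 3)
    ft <- fitSaturationModels(cv)
    expect_lt(abs(ft$core$Omega - strictCore) / max(strictCore, 1), 0.05)
})

test_that("group-unique gene extraction follows the sharing rule", {
    m <- rbind(onlyA = c(TRUE, TRUE, FALSE, FALSE),
               shared = c(TRUE, FALSE, TRUE, FALSE),
               onlyB = c(FALSE, FALSE, TRUE, TRUE))
    colnames(m) <- paste0("a", 1:4)
    pav <- PAVMatrix(m, groups = c("A", "A", "B", "B"))
    u <- uniqueGroupGenes(pav)
    expect_equal(u$A$unique_pan, "onlyA")
    expect_equal(u$B$unique_pan, "onlyB")
    expect_equal(u$A$unique_core, "onlyA")   # present in 2/2 of group A
})

test_that("group-preferred genes are recovered exactly at zero leakage", {
    cfg <- simConfig(seed = 41, pref_leakage = 0)
    sp <- simulatePav(cfg)
    u <- uniqueGroupGenes(sp$pav)
    tr <- sp$truth
    for (g in names(u)) {
        planted <- tr$cluster[!is.na(tr$pref_group) & tr$pref_group == g]
        found <- intersect(u[[g]]$unique_pan, tr$cluster[
            !is.na(tr$pref_group)])
        expect_setequal(found, planted)
    }
})

test_that("enrichment p-values equal the hypergeometric tail", {
    # universe 20, term covers the whole 10-gene foreground
    genes <- paste0("g", 1:20)
    tm <- data.frame(gene = genes[1:10], term = "T1")
    r <- enrichTerms(genes[1:10], genes, tm)
    expect_equal(r$p, 1 / choose(20, 10), tolerance = 1e-12)
    # overlap at independence is not significant for a one-sided test
    tm2 <- data.frame(gene = genes[c(1:5, 11:15)], term = "T2")
    r2 <- enrichTerms(genes[1:10], genes, tm2)
    expect_gte(r2$p, 0.5)
})

test_that("BH adjustment reproduces the textbook example", {
    genes <- paste0("g", 1:100)
    df <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
    expect_equal(stats::p.adjust(df$p, "BH"), rep(0.04, 4))
    # and through the enrichment surface: q = p * m / rank, cummin-ed
    tm <- data.frame(gene = rep(genes[1:40], times = 1),
                     term = rep(paste0("T", 1:4), each = 10))
    r <- enrichTerms(genes[1:20], genes, tm)
    expect_equal(r$q, stats::p.adjust(r$p, "BH"))
})
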