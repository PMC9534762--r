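#' @include AllClasses.R io.R
NULL

# run expr under a fixed seed, restoring the caller's RNG state afterwards,
# so every generator is a pure function of (config, seed)
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# fixed per-stage seed offsets, so stages can be rerun independently
.stageOffset <- c(reference = 11L, pav = 23L, assemblies = 37L,
                  genotypes = 53L, tracks = 71L, curves = 89L)

#' Simulation configuration
#'
#' Builds the validated configuration object consumed by the `simulate*`
#' generators.  Defaults emulate the statistical structure of a 116-accession
#' pea-like panel at desk scale: three species-like groups (79 + 22 + 15
#' accessions), pan-gene classes in roughly the published proportions
#' (scaled down ~50x), group-preferred genes, a single 10-Mb chromosome,
#' Balding-Nichols population differentiation and one planted domestication
#' sweep.  Unknown arguments are rejected.
#'
#' @param seed integer master seed; per-stage seeds are derived by fixed
#'   offsets.
#' @param groups named integer vector: accessions per group.
#' @param n_core,n_softcore,n_shell,n_cloud planted pan-gene class counts.
#' @param group_preferred genes preferred per group (present in >= 80% of
#'   the own group, <= 5% elsewhere); default 40 per group.
#' @param pref_leakage per-accession leak probability of a group-preferred
#'   gene into other groups (capped at 5% of the other accessions).
#' @param fst_param Balding-Nichols differentiation parameter F in (0, 1).
#' @param n_sites number of simulated biallelic SNP sites.
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param gc GC content of simulated sequence.
#' @param window,step window and step size (bp) for score/diversity tracks.
#' @param sweep_specs list of planted sweeps; each element a list with
#'   `start`, `end` (0-based half-open), `multiplier` (score inflation) and
#'   `pi_reduction` (factor < 1 applied to domesticated-population pi).
#' @param n_assemblies number of accessions for which genome assemblies are
#'   simulated (desk-scale subset, spread across groups).
#' @param n_contigs,contig_length contigs per assembly and their length (bp).
#' @param backbone_divergence substitution rate applied to assembly
#'   backbones (<= 0.02).
#' @param novel_per_accession,novel_length_range planted novel segments per
#'   assembly and their length range (bp).
#' @param novel_shared_frac fraction of novel inserts drawn from a shared
#'   pool (so the same novel sequence can occur in several accessions).
#' @param coverage_dropout probability that a truly present gene's coverage
#'   record falls below the presence thresholds.
#' @param annotation_dropout probability that a truly present gene lacks an
#'   annotated member (to be recovered by map-to-pan).
#' @param depth_mean,depth_sdlog lognormal read-depth model for present
#'   genes.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      groups = c(PS = 79L, PF = 22L, PA = 15L),
                      n_core = 310L, n_softcore = 123L,
                      n_shell = 820L, n_cloud = 1002L,
                      group_preferred = NULL,
                      pref_leakage = 0.02,
                      fst_param = 0.45,
                      n_sites = 5000L,
                      chrom = "chr1", chrom_length = 10000000L,
                      gc = 0.38,
                      window = 1000000L, step = 100000L,
                      sweep_specs = list(list(start = 4000000L,
                                              end = 5200000L,
                                              multiplier = 10,
                                              pi_reduction = 0.2)),
                      n_assemblies = 6L,
                      n_contigs = 5L, contig_length = 300000L,
                      backbone_divergence = 0.02,
                      novel_per_accession = 3L,
                      novel_length_range = c(150L, 2000L),
                      novel_shared_frac = 0.25,
                      coverage_dropout = 0.02,
                      annotation_dropout = 0.10,
                      depth_mean = 12, depth_sdlog = 0.4) {
    cfg <- as.list(environment())
    stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
    if (is.null(names(cfg$groups)) || any(cfg$groups < 1))
        stop("'groups' must be a named vector of positive counts")
    if (is.null(cfg$group_preferred))
        cfg$group_preferred <- stats::setNames(
            rep(40L, length(cfg$groups)), names(cfg$groups))
    counts <- c(cfg$n_core, cfg$n_softcore, cfg$n_shell, cfg$n_cloud,
                cfg$group_preferred)
    if (any(counts < 0)) stop("gene counts must be >= 0")
    if (!is.null(names(cfg$group_preferred)) &&
        !all(names(cfg$group_preferred) %in% names(cfg$groups)))
        stop("group_preferred names must match group names")
    if (cfg$fst_param <= 0 || cfg$fst_param >= 1)
        stop("fst_param must be in (0, 1)")
    for (sw in cfg$sweep_specs) {
        stopifnot(all(c("start", "end") %in% names(sw)))
        if (sw$start < 0 || sw$end > cfg$chrom_length || sw$start >= sw$end)
            stop("sweep interval outside chromosome")
    }
    if (cfg$window < cfg$step) stop("window must be >= step")
    if (cfg$backbone_divergence < 0 || cfg$backbone_divergence > 0.5)
        stop("backbone_divergence out of range")
    structure(cfg, class = c("SimConfig", "list"))
}

# integer occupancy bands for the four pan-gene classes given N accessions;
# errors when a band is empty (infeasible for that N)
classBands <- function(N) {
    b <- list(core     = c(ceiling(0.99 * N), N),
              softcore = c(ceiling(0.90 * N), ceiling(0.99 * N) - 1),
              shell    = c(ceiling(0.15 * N), ceiling(0.90 * N) - 1),
              cloud    = c(1, ceiling(0.15 * N) - 1))
    for (cl in names(b))
        if (b[[cl]][1] > b[[cl]][2])
            stop(sprintf(
                "occupancy band for class '%s' is empty at N = %d", cl, N))
    b
}

#' Simulate a PAV matrix with planted classes and group-preferred genes
#'
#' Core genes are planted with occupancy >= 99% of accessions, soft-core in
#' [90%, 99%), shell in [15%, 90%) and cloud in (0, 15%); occupancy counts
#' are sampled uniformly within each band.  Group-preferred genes are
#' present in >= 80% of their own group and in <= 5% of the remaining
#' accessions.  Output is deterministic under the config seed.
#'
#' @param config a [simConfig()] object
#' @return list with elements `pav` (a [PAVMatrix-class]) and `truth`
#'   (data.frame: cluster, class, pref_group, occupancy)
#' @export
simulatePav <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    groups <- config$groups
    N <- sum(groups)
    bands <- classBands(N)
    accGroup <- rep(names(groups), groups)
    accIds <- sprintf("%s_%02d", accGroup, unlist(lapply(groups, seq_len)))

    withSeed(config$seed + .stageOffset[["pav"]], {
        nClass <- c(core = config$n_core, softcore = config$n_softcore,
                    shell = config$n_shell, cloud = config$n_cloud)
        rows <- list(); classes <- character(0); prefs <- character(0)
        for (cl in names(nClass)) {
            n <- nClass[[cl]]
            if (n == 0) next
            lo <- bands[[cl]][1]; hi <- bands[[cl]][2]
            for (i in seq_len(n)) {
                occ <- if (lo == hi) lo else sample(lo:hi, 1)
                v <- logical(N)
                v[sample.int(N, occ)] <- TRUE
                rows[[length(rows) + 1L]] <- v
                classes <- c(classes, cl)
                prefs <- c(prefs, NA_character_)
            }
        }
        gp <- config$group_preferred
        for (g in names(gp)) {
            own <- which(accGroup == g)
            other <- which(accGroup != g)
            capOther <- floor(0.05 * length(other))
            for (i in seq_len(gp[[g]])) {
                lo <- ceiling(0.8 * length(own))
                occOwn <- if (lo == length(own)) lo
                          else sample(lo:length(own), 1)
                nLeak <- min(stats::rbinom(1, length(other),
                                           config$pref_leakage), capOther)
                v <- logical(N)
                v[sample(own, occOwn)] <- TRUE
                if (nLeak > 0) v[sample(other, nLeak)] <- TRUE
                rows[[length(rows) + 1L]] <- v
                classes <- c(classes, NA_character_)
                prefs <- c(prefs, g)
            }
        }
        m <- do.call(rbind, rows)
        rownames(m) <- sprintf("cluster%05d", seq_len(nrow(m)))
        colnames(m) <- accIds
        occ <- rowSums(m)
        # group-preferred genes get the class their realized occupancy implies
        implied <- classifyOccupancy(occ, N)
        classes[is.na(classes)] <- implied[is.na(classes)]
        truth <- data.frame(cluster = rownames(m), class = classes,
                            pref_group = prefs, occupancy = occ,
                            stringsAsFactors = FALSE, row.names = NULL)
        list(pav = PAVMatrix(m, groups = accGroup), truth = truth)
    })
}

# uniform integer draw from [lo, hi] (safe when lo == hi)
sampleRange <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

# random DNA with a given GC content
randomSequence <- function(n, gc = 0.38) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

#' Simulate a reference genome
#'
#' @param config a [simConfig()] object
#' @return a single-chromosome [Biostrings::DNAStringSet]
#' @export
simulateReference <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    withSeed(config$seed + .stageOffset[["reference"]], {
        s <- Biostrings::DNAStringSet(randomSequence(config$chrom_length,
                                                     config$gc))
        names(s) <- config$chrom
        s
    })
}

# apply substitution noise at the given rate; substituted base always differs
substituteNoise <- function(seq, rate) {
    if (rate <= 0) return(seq)
    n <- nchar(seq)
    idx <- which(stats::runif(n) < rate)
    if (!length(idx)) return(seq)
    ch <- strsplit(seq, "")[[1]]
    repl <- vapply(ch[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    ch[idx] <- repl
    paste(ch, collapse = "")
}

#' Simulate genome assemblies with planted novel segments
#'
#' Each simulated accession's contigs are fragments of the reference with
#' substitution noise at the configured backbone divergence, plus inserted
#' GC-matched random novel segments at recorded positions.  Novel segments
#' are inserted verbatim (noise applies to the backbone only), and a
#' configurable fraction is drawn from a shared pool so the same novel
#' sequence can occur in several accessions.  The truth records every
#' planted segment as (accession, contig, interval in final contig
#' coordinates, sequence).
#'
#' @param config a [simConfig()] object
#' @param reference a [Biostrings::DNAStringSet]; defaults to
#'   [simulateReference()]
#' @return list with `assemblies` (named list of DNAStringSet, one per
#'   accession) and `truth` (data.frame: accession, contig, start, end,
#'   sequence)
#' @export
simulateAssemblies <- function(config, reference = simulateReference(config)) {
    stopifnot(inherits(config, "SimConfig"))
    reference <- asDNAStringSet(reference)
    if (sum(Biostrings::width(reference)) == 0) stop("empty reference")
    refChrom <- as.character(reference[[1]])
    refName <- names(reference)[1]
    refLen <- nchar(refChrom)
    if (config$contig_length > refLen)
        stop("contig_length exceeds reference length")
    grp <- rep(names(config$groups), config$groups)
    ids <- sprintf("%s_%02d", grp, unlist(lapply(config$groups, seq_len)))
    # spread the assembled subset across groups
    pick <- unlist(lapply(split(seq_along(ids), grp), function(i)
        utils::head(i, ceiling(config$n_assemblies / length(config$groups)))))
    pick <- sort(utils::head(pick, config$n_assemblies))
    accs <- ids[pick]

    withSeed(config$seed + .stageOffset[["assemblies"]], {
        if (any(config$novel_length_range > config$contig_length))
            stop("requested novel length exceeds contig length")
        poolSize <- max(1L, ceiling(config$novel_per_accession *
                                    length(accs) * config$novel_shared_frac))
        pool <- replicate(poolSize, randomSequence(
            sampleRange(config$novel_length_range[1],
                        config$novel_length_range[2]), config$gc))
        assemblies <- list()
        truth <- list()
        for (acc in accs) {
            starts <- sample.int(refLen - config$contig_length + 1L,
                                 config$n_contigs)
            contigs <- vapply(starts, function(s)
                substr(refChrom, s, s + config$contig_length - 1L), "")
            contigs <- vapply(contigs, substituteNoise,
                              rate = config$backbone_divergence, "")
            names(contigs) <- sprintf("%s_ctg%02d", acc,
                                      seq_len(config$n_contigs))
            nNovel <- config$novel_per_accession
            if (nNovel > 0) {
                tgt <- sample(seq_along(contigs), nNovel, replace = TRUE)
                for (ti in unique(tgt)) {
                    kk <- sum(tgt == ti)
                    ctg <- contigs[[ti]]
                    inserts <- lapply(seq_len(kk), function(z) {
                        if (stats::runif(1) < config$novel_shared_frac)
                            pool[[sample.int(poolSize, 1)]]
                        else randomSequence(
                            sampleRange(config$novel_length_range[1],
                                        config$novel_length_range[2]),
                            config$gc)
                    })
                    pos <- sort(sample.int(nchar(ctg) - 1L, kk)) # 0-based
                    # insert right-to-left; then shift recorded intervals
                    newCtg <- ctg
                    for (z in rev(seq_len(kk)))
                        newCtg <- paste0(substr(newCtg, 1, pos[z]),
                                         inserts[[z]],
                                         substr(newCtg, pos[z] + 1L,
                                                nchar(newCtg)))
                    shift <- cumsum(c(0, vapply(inserts, nchar,
                                                0)[-kk]))
                    for (z in seq_len(kk)) {
                        s0 <- pos[z] + shift[z]
                        truth[[length(truth) + 1L]] <- data.frame(
                            accession = acc, contig = names(contigs)[ti],
                            start = s0, end = s0 + nchar(inserts[[z]]),
                            sequence = inserts[[z]],
                            stringsAsFactors = FALSE)
                    }
                    contigs[[ti]] <- newCtg
                }
            }
            assemblies[[acc]] <- Biostrings::DNAStringSet(contigs)
        }
        truthDf <- if (length(truth)) do.call(rbind, truth)
                   else data.frame(accession = character(0),
                                   contig = character(0),
                                   start = integer(0), end = integer(0),
                                   sequence = character(0))
        pavLog("simulate", "assemblies: %d accessions, %d planted novel segments",
               length(assemblies), nrow(truthDf))
        list(assemblies = assemblies, truth = truthDf, reference = refName)
    })
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per site, an ancestral allele frequency p ~ Uniform(0.05, 0.95) is drawn;
#' each group's frequency follows Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = `fst_param`; diploid genotypes are Binomial(2, group frequency) and
#' phased haplotypes are emitted.  F equals the expected Weir-Cockerham
#' theta, which makes differentiation recoverable by the estimator.
#'
#' @param config a [simConfig()] object
#' @return a phased [GenotypeMatrix-class]; group labels are recoverable
#'   from the sample ids (`<group>_<nn>`)
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    F <- config$fst_param
    groups <- config$groups
    grp <- rep(names(groups), groups)
    ids <- sprintf("%s_%02d", grp, unlist(lapply(groups, seq_len)))
    S <- config$n_sites
    withSeed(config$seed + .stageOffset[["genotypes"]], {
        pos <- sort(sample.int(config$chrom_length, S))
        p <- stats::runif(S, 0.05, 0.95)
        h1 <- h2 <- matrix(0L, S, length(ids), dimnames = list(NULL, ids))
        pgMat <- matrix(0, S, length(groups),
                        dimnames = list(NULL, names(groups)))
        for (g in names(groups)) {
            cols <- which(grp == g)
            pg <- stats::rbeta(S, p * (1 - F) / F, (1 - p) * (1 - F) / F)
            pgMat[, g] <- pg
            h1[, cols] <- stats::rbinom(S * length(cols), 1L, pg)
            h2[, cols] <- stats::rbinom(S * length(cols), 1L, pg)
        }
        ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
        alt <- vapply(ref, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        cl <- stats::setNames(config$chrom_length, config$chrom)
        geno <- GenotypeMatrix(h1 + h2, chrom = rep(config$chrom, S),
                               pos = pos, ref = ref, alt = alt,
                               hap1 = h1, hap2 = h2, chromLengths = cl)
        # latent per-group frequencies, for moment checks and audits
        metadata(geno)$ancestral_freq <- p
        metadata(geno)$group_freq <- pgMat
        geno
    })
}

# full (non-partial) window grid over one chromosome
tileWindows <- function(chrom, chromLength, window, step) {
    starts <- seq(0L, chromLength - window, by = step)
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(starts + window))
}

#' Simulate sweep-scan input tracks
#'
#' Generates, on a shared window grid, a cross-population selection-score
#' track (lognormal background, planted sweeps inflated by their
#' `multiplier`) and nucleotide-diversity tracks for a wild and a
#' domesticated population (domesticated pi multiplied by `pi_reduction`
#' inside planted sweeps).  A window counts as inside a sweep when it is
#' fully contained in the planted interval, so the truth interval equals the
#' union of its elevated windows.  Overlapping planted sweeps are merged in
#' the truth with a warning.
#'
#' @param config a [simConfig()] object
#' @param genotypes optional [GenotypeMatrix-class]; when supplied, its
#'   chromosome name/length override the config values
#' @param sdlog_score lognormal sdlog of the background score
#' @param pi_base baseline per-window diversity of the wild population
#' @return list with `score`, `pi_wild`, `pi_dom` ([windowTrack()]s) and
#'   `truth` (data.frame of merged planted sweep intervals)
#' @export
simulateSweepTracks <- function(config, genotypes = NULL,
                                sdlog_score = 0.4, pi_base = 9.4e-4) {
    stopifnot(inherits(config, "SimConfig"))
    chrom <- config$chrom; L <- config$chrom_length
    if (!is.null(genotypes)) {
        chrom <- seqlevels(rowRanges(genotypes))[1]
        sl <- seqlengths(rowRanges(genotypes))[chrom]
        if (!is.na(sl)) L <- as.integer(sl)
    }
    win <- tileWindows(chrom, L, config$window, config$step)
    W <- nrow(win)
    specs <- config$sweep_specs
    withSeed(config$seed + .stageOffset[["tracks"]], {
        score <- stats::rlnorm(W, 0, sdlog_score)
        piW <- pi_base * stats::rlnorm(W, 0, 0.15)
        piD <- piW * stats::rlnorm(W, log(0.9), 0.1)
        inside <- rep(FALSE, W)
        for (sw in specs) {
            inSw <- win$start >= sw$start & win$end <= sw$end
            mult <- if (is.null(sw$multiplier)) 10 else sw$multiplier
            red <- if (is.null(sw$pi_reduction)) 0.2 else sw$pi_reduction
            score[inSw] <- score[inSw] * mult
            piD[inSw] <- piD[inSw] * red
            inside <- inside | inSw
        }
        truth <- mergeIntervals(data.frame(
            chrom = chrom,
            start = vapply(specs, function(s) as.integer(s$start), 0L),
            end = vapply(specs, function(s) as.integer(s$end), 0L)))
        if (length(specs) > 1 && nrow(truth) < length(specs))
            warning("overlapping planted sweeps merged in truth")
        list(score = windowTrack(win$chrom, win$start, win$end, score,
                                 stat = "score"),
             pi_wild = windowTrack(win$chrom, win$start, win$end, piW,
                                   stat = "pi"),
             pi_dom = windowTrack(win$chrom, win$start, win$end, piD,
                                  stat = "pi"),
             truth = truth)
    })
}

# merge overlapping or bookended sorted intervals (0-based half-open)
mergeIntervals <- function(df) {
    if (nrow(df) == 0) return(df)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    out <- df[1, , drop = FALSE]
    for (i in seq_len(nrow(df))[-1]) {
        last <- nrow(out)
        if (df$chrom[i] == out$chrom[last] && df$start[i] <= out$end[last]) {
            out$end[last] <- max(out$end[last], df$end[i])
        } else {
            out <- rbind(out, df[i, , drop = FALSE])
        }
    }
    rownames(out) <- NULL
    out
}

#' Simulate map-to-pan coverage and annotation evidence for a planted PAV
#'
#' Derives, from a planted PAV matrix, the two evidence sources the PAV
#' builder consumes: per-accession annotated gene memberships (truly present
#' genes minus annotation dropout) and a coverage table (breadth/depth) in
#' which truly present genes pass the presence thresholds unless hit by
#' coverage dropout, and absent genes fall below them.  At zero dropout the
#' rebuilt PAV equals the planted truth exactly.
#'
#' @param config a [simConfig()] object
#' @param pav the planted [PAVMatrix-class]
#' @return list with `members` (data.frame: accession, cluster_id, gene_id)
#'   and `coverage` (data.frame: accession, cluster_id, breadth, depth)
#' @export
simulateCoverage <- function(config, pav) {
    stopifnot(inherits(config, "SimConfig"), methods::is(pav, "PAVMatrix"))
    m <- presence(pav)
    withSeed(config$seed + .stageOffset[["pav"]] + 1L, {
        idx <- which(m, arr.ind = TRUE)
        acc <- colnames(m)[idx[, 2]]
        cl <- rownames(m)[idx[, 1]]
        nP <- nrow(idx)
        annotated <- stats::runif(nP) >= config$annotation_dropout
        members <- data.frame(accession = acc[annotated],
                              cluster_id = cl[annotated],
                              gene_id = sprintf("%s.%s", acc[annotated],
                                                cl[annotated]),
                              stringsAsFactors = FALSE)
        dropped <- stats::runif(nP) < config$coverage_dropout
        breadth <- ifelse(dropped, stats::runif(nP, 0.5, 0.98),
                          stats::runif(nP, 0.99, 1.0))
        depth <- ifelse(dropped, stats::runif(nP, 0, 2.9),
                        pmax(3, stats::rlnorm(nP, log(config$depth_mean),
                                              config$depth_sdlog)))
        presentCov <- data.frame(accession = acc, cluster_id = cl,
                                 breadth = breadth, depth = depth,
                                 stringsAsFactors = FALSE)
        # absent genes: sparse sub-threshold coverage records
        aidx <- which(!m, arr.ind = TRUE)
        if (nrow(aidx) > 0) {
            keep <- stats::runif(nrow(aidx)) < 0.2
            aidx <- aidx[keep, , drop = FALSE]
        }
        absentCov <- data.frame(
            accession = colnames(m)[aidx[, 2]],
            cluster_id = rownames(m)[aidx[, 1]],
            breadth = stats::runif(nrow(aidx), 0, 0.9),
            depth = stats::runif(nrow(aidx), 0, 2.5),
            stringsAsFactors = FALSE)
        list(members = members, coverage = rbind(presentCov, absentCov))
    })
}
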