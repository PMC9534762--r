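#' @include AllClasses.R simdata.R augment.R pav_build.R pav_analysis.R
#' @include pav_structure.R popgen.R io.R
NULL

.pipelineKeys <- c("seed", "outdir", "sim", "identity_min",
                   "aligned_len_min", "min_retained_len", "breadth_min",
                   "depth_min", "window", "step", "top_score", "top_rod",
                   "ward_k", "n_perm", "nj_metric")

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()].  Every
#' threshold defaults to the pipeline's canonical value: alignment trimming
#' at identity >= 0.90 over >= 100 bp, presence at breadth >= 0.99 and
#' depth >= 3x, occupancy bands 0.99 / 0.90 / 0.15, 1,000-kb windows with
#' 100-kb steps, top 5% scores then top 50% ROD, and K = 8 Ward clusters.
#' Unknown keys are rejected before any stage runs.
#'
#' @param config named list (e.g. parsed from YAML) overriding defaults;
#'   the `sim` element is passed to [simConfig()]
#' @return validated config list
#' @export
pipelineConfig <- function(config = list()) {
    defaults <- list(seed = 1L, outdir = "panpav_out", sim = list(),
                     identity_min = 0.90, aligned_len_min = 100L,
                     min_retained_len = 100L, breadth_min = 0.99,
                     depth_min = 3.0, window = 1000000L, step = 100000L,
                     top_score = 0.05, top_rod = 0.50, ward_k = 8L,
                     n_perm = 30L, nj_metric = "simple-matching")
    unknown <- setdiff(names(config), .pipelineKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    simArgs <- cfg$sim
    simArgs$seed <- cfg$seed
    badSim <- setdiff(names(simArgs), names(formals(simConfig)))
    if (length(badSim))
        stop("unknown sim config key(s): ", paste(badSim, collapse = ", "))
    cfg$sim <- do.call(simConfig, simArgs)
    cfg
}

#' Run the full synthetic pan-genome pipeline
#'
#' Chains simulate -> augment -> PAV build -> classification / accumulation
#' curves / group-unique genes / enrichment -> structure (NJ + Ward) ->
#' windowed diversity and the composite sweep filter, writing every
#' artifact under `outdir` and returning a manifest of output files with
#' content hashes.  Identical config + seed gives identical hashes.  Any
#' stage failure aborts with the failing stage named.
#'
#' @param config a [pipelineConfig()] list, a named list of overrides, or
#'   a YAML file path
#' @param outdir overrides `config$outdir` when given
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`)
#' @export
runPipeline <- function(config = list(), outdir = NULL) {
    if (is.character(config) && length(config) == 1)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML path")
    cfg <- pipelineConfig(config)
    if (!is.null(outdir)) cfg$outdir <- outdir
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(cfg$outdir, ...)
    sim <- cfg$sim
    stage <- function(name, expr) {
        pavLog("pipeline", "stage %s", name)
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }

    ## --- simulate ------------------------------------------------------
    art <- stage("simulate", {
        ref <- simulateReference(sim)
        asm <- simulateAssemblies(sim, ref)
        pavSim <- simulatePav(sim)
        cov <- simulateCoverage(sim, pavSim$pav)
        geno <- simulateGenotypes(sim)
        tracks <- simulateSweepTracks(sim, geno)
        writeFasta(ref, out("reference.fa"))
        for (acc in names(asm$assemblies))
            writeFasta(asm$assemblies[[acc]],
                       out(sprintf("assembly_%s.fa", acc)))
        writeVcfGenotypes(geno, out("genotypes.vcf"))
        utils::write.table(cov$coverage, out("coverage.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(cov$members, out("members.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        labels <- data.frame(accession = colnames(presence(pavSim$pav)),
                             group = accessionGroups(pavSim$pav))
        utils::write.table(labels, out("labels.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeWindowTrack(tracks$score, out("scores.tsv"))
        writeWindowTrack(tracks$pi_wild, out("pi_wild_track.tsv"))
        writeWindowTrack(tracks$pi_dom, out("pi_dom_track.tsv"))
        jsonlite::write_json(
            list(pav_truth = pavSim$truth,
                 novel_segments = asm$truth[, c("accession", "contig",
                                                "start", "end")],
                 sweep_truth = tracks$truth,
                 fst_param = sim$fst_param),
            out("truth.json"), auto_unbox = TRUE, digits = NA)
        list(ref = ref, asm = asm, pavSim = pavSim, cov = cov,
             geno = geno, tracks = tracks)
    })

    ## --- augment -------------------------------------------------------
    aug <- stage("augment", {
        res <- augmentIterative(art$ref, art$asm$assemblies,
                                identityMin = cfg$identity_min,
                                alignedLenMin = cfg$aligned_len_min,
                                minRetainedLen = cfg$min_retained_len)
        writeFasta(panSequences(res$pan), out("pan.fa"))
        utils::write.table(as.data.frame(panProvenance(res$pan)),
                           out("pan_provenance.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(res$report, out("augment_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
    })

    ## --- pav build -----------------------------------------------------
    pav <- stage("pav", {
        groups <- accessionGroups(art$pavSim$pav)
        p <- buildPavMatrix(art$cov$members, art$cov$coverage,
                            groups = groups,
                            accessions = names(groups),
                            clusterIds = rownames(presence(art$pavSim$pav)),
                            breadthMin = cfg$breadth_min,
                            depthMin = cfg$depth_min)
        writePavTsv(p, out("pav.tsv"))
        p
    })

    ## --- classify / curves / unique / enrich ---------------------------
    stage("classify", {
        cl <- classifyPanGenes(pav)
        utils::write.table(cl$classes, out("classes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(as.list(cl$totals), out("class_totals.json"),
                             auto_unbox = TRUE)
    })
    stage("curves", {
        cv <- panCoreCurves(pav, nPerm = cfg$n_perm, seed = cfg$seed)
        utils::write.table(cv, out("curves.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        ft <- fitSaturationModels(cv)
        jsonlite::write_json(ft, out("curve_fits.json"),
                             auto_unbox = TRUE, digits = NA)
    })
    uniq <- stage("unique", {
        u <- uniqueGroupGenes(pav)
        jsonlite::write_json(u, out("unique_genes.json"))
        u
    })
    stage("enrich", {
        # synthetic term map: random terms plus one term planted on the
        # first group's unique pan-genes
        withSeed(cfg$seed + 101L, {
            genes <- rownames(presence(pav))
            tm <- data.frame(
                gene = sample(genes, length(genes), replace = FALSE),
                term = sample(sprintf("T%02d", 1:20), length(genes),
                              replace = TRUE))
            fg <- uniq[[1]]$unique_pan
            if (length(fg) >= 5)
                tm <- rbind(tm, data.frame(
                    gene = fg, term = "T_planted"))
            res <- enrichTerms(if (length(fg)) fg else genes[1:5], genes,
                               tm)
            utils::write.table(res, out("enrichment.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        })
    })

    ## --- structure -----------------------------------------------------
    stage("structure", {
        d <- pavDistance(pav, metric = cfg$nj_metric)
        tree <- njTree(d)
        writeNewick(tree, out("pav_nj.nwk"))
        wc <- wardCluster(pav, K = cfg$ward_k, axis = "genes")
        utils::write.table(
            data.frame(id = names(wc$labels), cluster = wc$labels),
            out("ward_clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    })

    ## --- popgen + sweep ------------------------------------------------
    stage("popgen", {
        grp <- sub("_[0-9]+$", "", colnames(dosage(art$geno)))
        for (g in unique(grp)) {
            tr <- windowPi(art$geno,
                           samples = colnames(dosage(art$geno))[grp == g],
                           window = cfg$window, step = cfg$step)
            writeWindowTrack(tr, out(sprintf("pi_%s.tsv", g)))
        }
        fst <- weirCockerhamFst(art$geno, stats::setNames(
            grp, colnames(dosage(art$geno))))
        jsonlite::write_json(list(fst = fst$fst,
                                  components = as.list(fst$components)),
                             out("fst.json"), auto_unbox = TRUE,
                             digits = NA)
    })
    sweeps <- stage("sweep", {
        sf <- sweepFilter(art$tracks$score, art$tracks$pi_wild,
                          art$tracks$pi_dom, topScore = cfg$top_score,
                          topRod = cfg$top_rod)
        bed <- sf$sweeps[, c("chrom", "start", "end")]
        bed$name <- sprintf("sweep%d", seq_len(nrow(bed)))
        writeBed(bed, out("sweeps.bed"))
        utils::write.table(sf$selected, out("sweep_selected.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sf$survivors, out("sweep_survivors.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sf
    })

    ## --- manifest ------------------------------------------------------
    files <- sort(setdiff(list.files(cfg$outdir), "manifest.json"))
    hashes <- as.list(tools::md5sum(file.path(cfg$outdir, files)))
    names(hashes) <- files
    manifest <- list(seed = cfg$seed, files = hashes)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    pavLog("pipeline", "done: %d artifacts in %s", length(files),
           cfg$outdir)
    invisible(manifest)
}

#' Run the bundled end-to-end demo
#'
#' Runs [runPipeline()] with the default desk-scale study configuration
#' (116 accessions, 10-Mb chromosome, one planted sweep).
#'
#' @param outdir output directory
#' @param seed master seed
#' @return the manifest, invisibly
#' @export
runDemo <- function(outdir = "panpav_demo", seed = 1L) {
    runPipeline(list(seed = as.integer(seed)), outdir = outdir)
}
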