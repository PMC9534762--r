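#' @include AllClasses.R
NULL

# all permutations of 1..n (n small), in lexicographic order
allPermutations <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
        rest <- allPermutations(n - 1L)
        for (r in rest)
            out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
    }
    out
}

# occupancy-fraction class bands: core [0.99, 1], soft-core [0.90, 0.99),
# shell [0.15, 0.90), cloud (0, 0.15); the bands partition (0, 1]
classifyOccupancy <- function(count, N) {
    frac <- count / N
    ifelse(frac >= 0.99, "core",
    ifelse(frac >= 0.90, "softcore",
    ifelse(frac >= 0.15, "shell", "cloud")))
}

#' Classify pan-genes into core / soft-core / shell / cloud
#'
#' Occupancy fraction is presences / N over the (optionally
#' group-restricted) accession columns; classes follow the occupancy bands
#' core >= 99%, soft-core [90%, 99%), shell [15%, 90%) and cloud < 15% of
#' genomes.  A cluster with zero presences in the restricted columns
#' violates the PAV invariant and is a hard error.
#'
#' @param pav a [PAVMatrix-class] (N >= 2 accessions)
#' @param group optional group label: classify within that group's columns
#'   only
#' @return list with `classes` (data.frame: cluster_id, count, fraction,
#'   class) and `totals` (named integer vector per class)
#' @export
classifyPanGenes <- function(pav, group = NULL) {
    m <- presence(pav)
    if (!is.null(group)) {
        cols <- accessionGroups(pav) == group
        if (!any(cols)) stop("no accessions in group ", group)
        m <- m[, cols, drop = FALSE]
    }
    N <- ncol(m)
    if (N < 2) stop("classification needs at least 2 accessions")
    count <- rowSums(m)
    if (any(count == 0))
        stop("cluster with zero presences: ",
             paste(utils::head(rownames(m)[count == 0], 5), collapse = ", "))
    cls <- classifyOccupancy(count, N)
    classes <- data.frame(cluster_id = rownames(m), count = count,
                          fraction = count / N, class = cls,
                          stringsAsFactors = FALSE, row.names = NULL)
    totals <- vapply(c("core", "softcore", "shell", "cloud"),
                     function(x) sum(cls == x), 0L)
    list(classes = classes, totals = totals)
}

#' Pan- and core-genome accumulation curves over accession permutations
#'
#' For each of `nPerm` random permutations of the accession order and each
#' prefix size n, pan(n) is the number of clusters present in at least one
#' of the first n accessions (union) and core(n) the number present in all
#' of them (strict intersection — distinct from the >= 99% classification
#' band).  Means and standard deviations over permutations are returned.
#' When N! <= `nPerm` the full set of N! orders is enumerated exactly once
#' instead of sampling, so small-N curves are exact.
#'
#' @param pav a [PAVMatrix-class]
#' @param nPerm number of permutations (>= 1)
#' @param seed RNG seed for the permutations
#' @return data.frame with columns `n`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`
#' @export
panCoreCurves <- function(pav, nPerm = 100L, seed = 1L) {
    stopifnot(nPerm >= 1)
    m <- presence(pav) * 1L
    N <- ncol(m)
    tri <- upper.tri(matrix(0, N, N), diag = TRUE) * 1L  # cumsum operator
    exhaustive <- N <= 8 && factorial(N) <= nPerm
    orders <- if (exhaustive) allPermutations(N) else NULL
    if (exhaustive) nPerm <- length(orders)
    withSeed(seed, {
        pan <- core <- matrix(0, nPerm, N)
        for (p in seq_len(nPerm)) {
            ord <- if (exhaustive) orders[[p]] else sample.int(N)
            cnt <- m[, ord, drop = FALSE] %*% tri
            pan[p, ] <- colSums(cnt > 0L)
            core[p, ] <- colSums(cnt == rep(seq_len(N), each = nrow(m)))
        }
        data.frame(n = seq_len(N),
                   pan_mean = colMeans(pan),
                   pan_sd = apply(pan, 2, stats::sd),
                   core_mean = colMeans(core),
                   core_sd = apply(core, 2, stats::sd))
    })
}

#' Fit saturation models to pan/core accumulation curves
#'
#' Nonlinear least squares on the permutation means: a Heaps-type power law
#' P(n) = A n^gamma + C for the pan curve and exponential decay
#' K(n) = kappa exp(-n / tau) + Omega for the core curve.  A pan exponent
#' gamma whose 95% confidence interval excludes zero indicates an open
#' pan-genome.  Degenerate inputs (constant curves, non-convergence) are
#' flagged, never silent.
#'
#' @param curve data.frame from [panCoreCurves()] with >= 4 points
#' @return list with `pan` (A, gamma, C, residual norm, open verdict,
#'   flag), `core` (kappa, tau, Omega, residual norm, flag)
#' @export
fitSaturationModels <- function(curve) {
    stopifnot(nrow(curve) >= 4)
    n <- curve$n
    fitOne <- function(y, formula, start) {
        if (stats::sd(y) < 1e-12)
            return(list(fit = NULL, flag = "degenerate-constant"))
        fit <- tryCatch(
            minpack.lm::nlsLM(formula, data = data.frame(n = n, y = y),
                              start = start,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
            error = function(e) NULL)
        if (is.null(fit)) return(list(fit = NULL, flag = "non-convergence"))
        list(fit = fit, flag = "ok")
    }
    yp <- curve$pan_mean
    panFit <- fitOne(yp, y ~ A * n^gamma + C,
                     list(A = max(yp[1], 1), gamma = 0.5, C = 0))
    pan <- if (panFit$flag == "ok") {
        cf <- stats::coef(panFit$fit)
        se <- tryCatch(summary(panFit$fit)$coefficients["gamma",
                                                        "Std. Error"],
                       error = function(e) NA_real_)
        list(A = cf[["A"]], gamma = cf[["gamma"]], C = cf[["C"]],
             rss = sum(stats::resid(panFit$fit)^2),
             open = is.finite(se) && cf[["gamma"]] - 1.96 * se > 0,
             flag = "ok")
    } else list(A = NA, gamma = NA, C = NA, rss = NA, open = NA,
                flag = panFit$flag)
    yc <- curve$core_mean
    coreFit <- fitOne(yc, y ~ kappa * exp(-n / tau) + Omega,
                      list(kappa = max(yc[1] - min(yc), 1), tau = 2,
                           Omega = min(yc)))
    core <- if (coreFit$flag == "ok") {
        cf <- stats::coef(coreFit$fit)
        list(kappa = cf[["kappa"]], tau = cf[["tau"]],
             Omega = cf[["Omega"]], rss = sum(stats::resid(coreFit$fit)^2),
             flag = "ok")
    } else list(kappa = NA, tau = NA,
                Omega = if (coreFit$flag == "degenerate-constant") yc[1]
                        else NA,
                rss = NA, flag = coreFit$flag)
    list(pan = pan, core = core)
}

#' Group-unique pan-genes and group-unique core genes
#'
#' A cluster is unique to a group when it is present in at least one
#' accession of exactly one group (clusters shared between two or more
#' groups are removed).  Unique core genes additionally reach core status
#' (occupancy >= 99%) within the owning group's columns.
#'
#' @param pav a [PAVMatrix-class] with >= 2 groups
#' @return named list per group, each with `unique_pan` and `unique_core`
#'   character vectors of cluster ids
#' @export
uniqueGroupGenes <- function(pav) {
    m <- presence(pav)
    grp <- accessionGroups(pav)
    gnames <- unique(grp)
    if (length(gnames) < 2) stop("need at least 2 groups")
    sizes <- table(grp)
    if (any(sizes == 0)) stop("group with zero accessions")
    inGroup <- vapply(gnames, function(g)
        rowSums(m[, grp == g, drop = FALSE]) > 0, logical(nrow(m)))
    if (is.null(dim(inGroup)))    # single-cluster matrix
        inGroup <- matrix(inGroup, nrow = 1,
                          dimnames = list(rownames(m), gnames))
    nGroups <- rowSums(inGroup)
    out <- list()
    for (g in gnames) {
        uniq <- rownames(m)[inGroup[, g] & nGroups == 1]
        cols <- grp == g
        cnt <- rowSums(m[uniq, cols, drop = FALSE])
        core <- uniq[cnt / sum(cols) >= 0.99]
        out[[g]] <- list(unique_pan = uniq, unique_core = core)
    }
    out
}

#' Term enrichment by one-sided Fisher's exact test with BH correction
#'
#' For each term, the one-sided (enrichment) Fisher exact p-value is the
#' hypergeometric upper tail of the foreground/term overlap given the
#' background universe; q-values are Benjamini-Hochberg over the tested
#' terms only.  Terms with zero background members are skipped with a log
#' message.
#'
#' @param foreground,background character vectors of gene ids
#'   (`foreground` must be a subset of `background`)
#' @param termMap data.frame with columns `gene`, `term`
#' @return data.frame per term: `term`, `overlap`, `fg_size`, `term_size`,
#'   `universe`, `p`, `q`, sorted by p
#' @export
enrichTerms <- function(foreground, background, termMap) {
    stopifnot(all(foreground %in% background))
    background <- unique(background)
    foreground <- unique(foreground)
    termMap <- termMap[termMap$gene %in% background, , drop = FALSE]
    allTerms <- unique(termMap$term)
    skipped <- 0L
    rows <- list()
    for (tm in allTerms) {
        genes <- unique(termMap$gene[termMap$term == tm])
        K <- length(genes)
        if (K == 0) { skipped <- skipped + 1L; next }
        Nn <- length(background)
        k <- sum(foreground %in% genes)
        nFg <- length(foreground)
        # hypergeometric upper tail: P(X >= k)
        p <- stats::phyper(k - 1, K, Nn - K, nFg, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            term = tm, overlap = k, fg_size = nFg, term_size = K,
            universe = Nn, p = p, stringsAsFactors = FALSE)
    }
    if (skipped > 0)
        pavLog("enrich", "skipped %d term(s) with zero background members",
               skipped)
    if (!length(rows))
        return(data.frame(term = character(0), overlap = integer(0),
                          fg_size = integer(0), term_size = integer(0),
                          universe = integer(0), p = numeric(0),
                          q = numeric(0)))
    df <- do.call(rbind, rows)
    df$q <- stats::p.adjust(df$p, method = "BH")
    df <- df[order(df$p), , drop = FALSE]
    rownames(df) <- NULL
    df
}
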