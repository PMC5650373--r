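#' Default signed inter-module factor correlation
#'
#' Rank-one sign structure over five latent programs (two upregulated,
#' three downregulated): programs on the same side of the tumor/normal
#' contrast are positively coupled (+0.9) and programs on opposite sides
#' anti-coupled (-0.9), with unit diagonal. Built as `a a' + (1 -
#' diag(a^2))` with loadings `a = (+.95, +.95, -.95, -.95, -.95)`, hence
#' positive semidefinite by construction.
#'
#' @return a 5 x 5 correlation matrix.
#' @export
defaultInterModuleCorr <- function() {
    a <- c(0.95, 0.95, -0.95, -0.95, -0.95)
    R <- tcrossprod(a)
    diag(R) <- 1
    dimnames(R) <- list(paste0("M", 1:5), paste0("M", 1:5))
    R
}

.defaultHubSpec <- function() {
    data.frame(
        direction = rep(c("up", "down"), each = 5L),
        n_partners = rep(c(80L, 60L, 45L, 25L, 15L), 2L),
        stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort simulation configuration
#'
#' Returns a validated [SimulationConfig-class]. The defaults encode the
#' cohort the package emulates: 79 tumor/normal pairs; 10,000 genes of
#' which 35% are forced below mean FPKM 1; 10% of expressed genes carry
#' true multiplicative tumor effects drawn log-uniformly between 2- and
#' 250-fold; five correlated modules (sizes 344, 184, 610, 164, 53) with
#' the signed structure of [defaultInterModuleCorr()]; ten planted hub
#' genes (five up with 176/150/145/109/106 coupled partners, five down
#' spanning up to 383); tumors split 2:1 high:low stage. Noise is
#' log-normal: Gaussian on the log2 scale with between-subject SD 1 and
#' residual SD 0.5.
#'
#' @param nPairs,nGenes cohort dimensions.
#' @param fracDE fraction of genes with true condition effects.
#' @param foldChangeRange multiplicative effect envelope (log-uniform).
#' @param nModules,moduleSizes,interModuleCorr latent-factor module
#'   layout; pass explicit `moduleSizes` (and optionally
#'   `interModuleCorr`) when `nModules != 5`. `nModules = 0` disables
#'   modules.
#' @param intraModuleLoading member-gene loading on its module factor.
#' @param hubSpec data.frame with columns `direction`, `n_partners`;
#'   `data.frame()` disables hubs. Partners are allocated disjointly
#'   across the hubs of a direction, in row order, truncating with a
#'   warning when the direction's affected-gene pool runs out.
#' @param hubCor,partnerCor target within-condition correlations with
#'   the hub latent factor. A hub is realized as a driver gene whose
#'   between-subject profile is the factor itself (only residual noise
#'   separates the two, giving correlation `hubCor`); partner loadings
#'   are calibrated against their subject + residual variance.
#' @param subjectSD,noiseSD log2-scale SDs of the subject effect and the
#'   residual.
#' @param baselineLog2MeanRange log2 baseline range of expressed genes.
#' @param fracLowAbundance fraction of genes forced below mean FPKM 1.
#' @param stageHighFraction fraction of tumors labelled high stage.
#' @param tumorVarMultiplier,normalVarMultiplier per-condition residual
#'   variance multipliers.
#' @param seed integer RNG seed (one global stream).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nPairs = 79L, nGenes = 10000L, fracDE = 0.10,
        foldChangeRange = c(2, 250), nModules = 5L, moduleSizes = NULL,
        interModuleCorr = NULL, intraModuleLoading = 0.9,
        hubSpec = NULL, hubCor = 0.99, partnerCor = 0.85,
        subjectSD = 1.0, noiseSD = 0.5,
        baselineLog2MeanRange = c(0, 8), fracLowAbundance = 0.35,
        stageHighFraction = 53 / 79, tumorVarMultiplier = 1,
        normalVarMultiplier = 1, seed = 1L) {
    nModules <- as.integer(nModules)
    if (is.null(moduleSizes)) {
        if (nModules == 5L) moduleSizes <- c(344L, 184L, 610L, 164L, 53L)
        else if (nModules == 0L) moduleSizes <- integer()
        else stop("pass explicit moduleSizes when nModules != 5")
    }
    if (is.null(interModuleCorr)) {
        interModuleCorr <- if (nModules == 5L) defaultInterModuleCorr()
            else diag(nModules)
    }
    if (nModules == 0L) interModuleCorr <- matrix(numeric(), 0L, 0L)
    if (is.null(hubSpec)) hubSpec <- .defaultHubSpec()
    new("SimulationConfig", nPairs = as.integer(nPairs),
        nGenes = as.integer(nGenes), fracDE = fracDE,
        foldChangeRange = as.numeric(foldChangeRange),
        nModules = nModules, moduleSizes = as.integer(moduleSizes),
        interModuleCorr = as.matrix(interModuleCorr),
        intraModuleLoading = intraModuleLoading, hubSpec = hubSpec,
        hubCor = hubCor, partnerCor = partnerCor,
        subjectSD = subjectSD, noiseSD = noiseSD,
        baselineLog2MeanRange = as.numeric(baselineLog2MeanRange),
        fracLowAbundance = fracLowAbundance,
        stageHighFraction = stageHighFraction,
        tumorVarMultiplier = tumorVarMultiplier,
        normalVarMultiplier = normalVarMultiplier,
        seed = as.integer(seed))
}

.factorSqrt <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop("inter-module correlation matrix is not positive semidefinite")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic paired tumor/normal FPKM cohort
#'
#' Draws a cohort from the additive log2-scale model
#' \deqn{y_{gs} = b_g + u_{g,subj(s)} + \delta_g 1[s\ tumor] +
#'   \sum_m \lambda_m 1[g \in m] f_{m,s} + \sum_h c_{gh} h_{h,s} +
#'   \epsilon_{gs}}
#' with gene baselines `b`, per-gene subject effects `u` shared within a
#' pair, planted condition effects `delta = sign * log2(fold)` on tumor
#' samples only, per-sample module factors `f` drawn from the signed
#' inter-module correlation, hub latent factors `h` (drawn per subject,
#' shared within a pair) loading on each hub gene and its coupled
#' partners, and Gaussian residual noise; FPKM is `2^y`. Truly affected genes are drawn from the expressed (non
#' low-abundance) fraction; module members from the unaffected genes;
#' hubs and their partners from the affected genes of the matching
#' direction. Identical seeds give bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `cohort` (a [PairedCohort-class]) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' gen <- generateCohort(simulationConfig(nPairs = 6, nGenes = 50,
#'     nModules = 0, hubSpec = data.frame(), seed = 1))
#' gen$cohort
#' @export
generateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (length(config@interModuleCorr)) .factorSqrt(config@interModuleCorr)
    set.seed(config@seed)
    nP <- config@nPairs; nG <- config@nGenes; nS <- 2L * nP
    wP <- max(2L, nchar(as.character(nP)))
    subjects <- sprintf("S%0*d", wP, seq_len(nP))
    tumorIds <- sprintf("T%0*d", wP, seq_len(nP))
    normalIds <- sprintf("N%0*d", wP, seq_len(nP))
    samples <- c(tumorIds, normalIds)
    isTumor <- rep(c(TRUE, FALSE), each = nP)
    genes <- sprintf("g%0*d", max(5L, nchar(as.character(nG))), seq_len(nG))

    ## -- design: stage and grade of each tumor
    nHigh <- round(config@stageHighFraction * nP)
    highSubj <- sample(seq_len(nP), nHigh)
    stageNum <- integer(nP)
    stageNum[highSubj] <- sample(3:4, nHigh, replace = TRUE)
    stageNum[-highSubj] <- sample(1:2, nP - nHigh, replace = TRUE)
    grade <- sample(c("well", "moderate", "poor"), nP, replace = TRUE,
        prob = c(17, 36, 26) / 79)

    ## -- gene architecture
    nLow <- round(config@fracLowAbundance * nG)
    lowIdx <- if (nLow > 0) sample(seq_len(nG), nLow) else integer()
    baseline <- stats::runif(nG, config@baselineLog2MeanRange[1L],
        config@baselineLog2MeanRange[2L])
    if (nLow > 0) baseline[lowIdx] <- stats::runif(nLow, -5, -1)

    expressedIdx <- setdiff(seq_len(nG), lowIdx)
    nDE <- round(config@fracDE * nG)
    if (nDE > length(expressedIdx))
        stop("fracDE too large for the expressed gene fraction")
    deIdx <- if (nDE > 0) sort(sample(expressedIdx, nDE)) else integer()
    # exact half/half direction split (randomly assigned) so the planted
    # up/down pools have deterministic sizes
    deDir <- if (nDE > 0)
        sample(rep(c("up", "down"), length.out = nDE)) else character()
    lfr <- log(config@foldChangeRange)
    deFold <- if (nDE > 0) exp(stats::runif(nDE, lfr[1L], lfr[2L]))
        else numeric()
    delta <- numeric(nG)
    delta[deIdx] <- ifelse(deDir == "up", 1, -1) * log2(deFold)

    ## -- modules among unaffected genes
    moduleOf <- rep(NA_character_, nG)
    nM <- config@nModules
    modNames <- if (nM > 0) paste0("M", seq_len(nM)) else character()
    if (nM > 0 && sum(config@moduleSizes) > 0) {
        pool <- setdiff(seq_len(nG), deIdx)
        if (sum(config@moduleSizes) > length(pool))
            stop("module sizes exceed the number of unaffected genes")
        picked <- sample(pool, sum(config@moduleSizes))
        moduleOf[picked] <- rep(modNames, times = config@moduleSizes)
    }

    ## -- hubs among affected genes of the matching direction; partner
    ##    sets are disjoint within a direction so each partner's coupling
    ##    is unambiguous
    hs <- config@hubSpec
    hubGene <- character(); hubDir <- character()
    hubPartners <- list(); hubN <- integer()
    if (nrow(hs)) {
        for (d in c("up", "down")) {
            want <- which(hs$direction == d)
            if (!length(want)) next
            dirPool <- deIdx[deDir == d]
            if (length(dirPool) < length(want)) {
                warning("not enough '", d,
                    "'-regulated genes to plant the requested hubs")
                want <- want[seq_len(length(dirPool))]
            }
            hubs_d <- sample(dirPool, length(want))
            avail <- setdiff(dirPool, hubs_d)
            for (j in seq_along(want)) {
                np <- hs$n_partners[want[j]]
                if (np > length(avail)) {
                    warning(sprintf(
                        "hub partner count %d truncated to pool size %d",
                        np, length(avail)))
                    np <- length(avail)
                }
                p <- if (np > 0) sample(avail, np) else integer()
                avail <- setdiff(avail, p)
                hubGene <- c(hubGene, genes[hubs_d[j]])
                hubDir <- c(hubDir, d)
                hubPartners <- c(hubPartners, list(genes[p]))
                hubN <- c(hubN, np)
            }
        }
    }

    ## -- latent draws and assembly (genes x samples, tumors first)
    Y <- matrix(baseline, nG, nS)
    Y[, isTumor] <- Y[, isTumor] + delta
    if (nM > 0 && any(!is.na(moduleOf))) {
        A <- .factorSqrt(config@interModuleCorr)
        Fm <- matrix(stats::rnorm(nS * nM), nS, nM) %*% A
        for (m in seq_len(nM)) {
            members <- which(moduleOf == modNames[m])
            if (length(members))
                Y[members, ] <- Y[members, ] + config@intraModuleLoading *
                    rep(Fm[, m], each = length(members))
        }
    }
    if (length(hubGene)) {
        # hub factors vary between subjects, not within a pair: they drive
        # cross-sample co-expression without perturbing paired contrasts
        Hp <- matrix(stats::rnorm(nP * length(hubGene)), nP,
            length(hubGene))
        H <- Hp[c(seq_len(nP), seq_len(nP)), , drop = FALSE]
        # a hub is a driver gene: its between-subject profile IS the
        # latent factor (it replaces the hub's independent subject
        # effect), leaving only residual noise between hub and factor;
        # partner loadings are calibrated against their idiosyncratic
        # variance (subject effect + residual noise) to hit the target
        # within-condition correlation
        hubSD <- config@noiseSD * config@hubCor /
            sqrt(1 - config@hubCor^2)
        partnerLoad <- sqrt(config@partnerCor^2 /
            (1 - config@partnerCor^2) *
            (config@subjectSD^2 + config@noiseSD^2))
        for (h in seq_along(hubGene)) {
            gi <- match(hubGene[h], genes)
            Y[gi, ] <- Y[gi, ] + hubSD * H[, h]
            pi <- match(hubPartners[[h]], genes)
            if (length(pi))
                Y[pi, ] <- Y[pi, ] + partnerLoad * rep(H[, h],
                    each = length(pi))
        }
    }
    if (config@subjectSD > 0) {
        U <- matrix(stats::rnorm(nG * nP, sd = config@subjectSD), nG, nP)
        if (length(hubGene))  # hub subject variation lives in its factor
            U[match(hubGene, genes), ] <- 0
        Y <- Y + U[, c(seq_len(nP), seq_len(nP))]
    }
    sdVec <- config@noiseSD *
        sqrt(ifelse(isTumor, config@tumorVarMultiplier,
            config@normalVarMultiplier))
    Y <- Y + matrix(stats::rnorm(nG * nS), nG, nS) *
        rep(sdVec, each = nG)
    fpkmMat <- 2^Y
    dimnames(fpkmMat) <- list(genes, samples)

    md <- data.frame(
        sample_id = samples,
        subject_id = c(subjects, subjects),
        condition = ifelse(isTumor, "tumor", "normal"),
        stage_numeric = c(stageNum, rep(NA_integer_, nP)),
        grade = c(grade, rep(NA_character_, nP)),
        stringsAsFactors = FALSE)
    cohort <- PairedCohort(fpkmMat, md, paired = TRUE)

    truth <- new("SyntheticTruth",
        de_genes = DataFrame(gene = genes[deIdx], fold_change = deFold,
            direction = deDir),
        module_of = stats::setNames(moduleOf[!is.na(moduleOf)],
            genes[!is.na(moduleOf)]),
        hub_genes = {
            hg <- DataFrame(gene = hubGene, direction = hubDir,
                n_partners = hubN)
            hg$partners <- hubPartners
            hg
        },
        factor_corr = config@interModuleCorr,
        seed = config@seed, version = "1.0")
    validObject(truth)
    list(cohort = cohort, truth = truth)
}

#' Write / read the planted truth of a synthetic cohort
#'
#' Lossless JSON round trip of a [SyntheticTruth-class]; reading a file
#' with an unknown schema version is an error.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path file path.
#' @return `writeTruth()` returns `path` invisibly; `readTruth()` the
#'   reconstructed object.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "SyntheticTruth"))
    hg <- truth@hub_genes
    payload <- list(
        version = truth@version,
        seed = truth@seed,
        de_genes = list(gene = as.character(truth@de_genes$gene),
            fold_change = as.numeric(truth@de_genes$fold_change),
            direction = as.character(truth@de_genes$direction)),
        module_of = as.list(truth@module_of),
        hub_genes = lapply(seq_len(nrow(hg)), function(i) list(
            gene = hg$gene[i], direction = hg$direction[i],
            n_partners = hg$n_partners[i],
            partners = as.character(hg$partners[[i]]))),
        factor_corr = unname(truth@factor_corr),
        factor_names = rownames(truth@factor_corr) %||% character())
    # I(17) significant digits so doubles survive the text round trip
    jsonlite::write_json(payload, path, auto_unbox = TRUE,
        digits = I(17), pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE,
        simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
    if (!identical(x$version, "1.0"))
        stop("unsupported truth-file version: ",
            if (is.null(x$version)) "<missing>" else x$version)
    hubs <- x$hub_genes
    hg <- DataFrame(
        gene = vapply(hubs, `[[`, "", "gene"),
        direction = vapply(hubs, `[[`, "", "direction"),
        n_partners = vapply(hubs, function(h) as.integer(h$n_partners), 0L))
    hg$partners <- lapply(hubs, function(h) as.character(h$partners))
    fc <- x$factor_corr
    if (is.null(fc) || !length(fc)) fc <- matrix(numeric(), 0L, 0L)
    fc <- as.matrix(fc)
    if (length(x$factor_names) && nrow(fc) == length(x$factor_names))
        dimnames(fc) <- list(as.character(x$factor_names),
            as.character(x$factor_names))
    new("SyntheticTruth",
        de_genes = DataFrame(gene = as.character(x$de_genes$gene),
            fold_change = as.numeric(x$de_genes$fold_change),
            direction = as.character(x$de_genes$direction)),
        module_of = unlist(lapply(x$module_of, as.character)) %||%
            stats::setNames(character(), character()),
        hub_genes = hg, factor_corr = fc,
        seed = as.integer(x$seed), version = x$version)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth (seed %d): %d DE genes, %d module genes in %d module(s), %d hub(s)\n",
        object@seed, nrow(object@de_genes), length(object@module_of),
        length(unique(object@module_of)), nrow(object@hub_genes)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d pairs, %d genes, fracDE=%.2f, folds [%g, %g], %d module(s), %d hub(s), seed %d\n",
        object@nPairs, object@nGenes, object@fracDE,
        object@foldChangeRange[1L], object@foldChangeRange[2L],
        object@nModules, nrow(object@hubSpec), object@seed))
})
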