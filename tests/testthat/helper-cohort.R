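# Small in-code fixtures shared across test files.

toyMetadata <- function(nPairs, stage = NULL) {
    w <- max(2L, nchar(nPairs))
    data.frame(
        sample_id = c(sprintf("T%0*d", w, 1:nPairs),
                      sprintf("N%0*d", w, 1:nPairs)),
        subject_id = rep(sprintf("S%0*d", w, 1:nPairs), 2),
        condition = rep(c("tumor", "normal"), each = nPairs),
        stage_numeric = c(stage %||% rep(NA_integer_, nPairs),
                          rep(NA_integer_, nPairs)),
        stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort from an explicit FPKM matrix laid out tumors-first
toyCohort <- function(fpkm, stage = NULL) {
    nPairs <- ncol(fpkm) / 2
    md <- toyMetadata(nPairs, stage = stage)
    colnames(fpkm) <- md$sample_id
    if (is.null(rownames(fpkm)))
        rownames(fpkm) <- sprintf("g%03d", seq_len(nrow(fpkm)))
    PairedCohort(fpkm, md)
}

# random lognormal cohort with an optional per-gene tumor log2 shift
randomCohort <- function(nGenes, nPairs, delta = 0, baseline = 5,
        subjectSD = 1, noiseSD = 0.5, seed = 1) {
    set.seed(seed)
    delta <- rep(delta, length.out = nGenes)
    subj <- matrix(rnorm(nGenes * nPairs, sd = subjectSD), nGenes)
    y <- cbind(subj + delta, subj) +
        matrix(rnorm(nGenes * 2 * nPairs, sd = noiseSD), nGenes) + baseline
    toyCohort(2^y)
}

# minimal DEResults covering the given genes, for network construction
toyDE <- function(genes, direction, log2_fc = NULL) {
    if (is.null(log2_fc))
        log2_fc <- ifelse(direction == "up", 2, -2)
    res <- S4Vectors::DataFrame(
        mean_T = 2^pmax(log2_fc, 0), mean_N = 2^pmax(-log2_fc, 0),
        fold_change = 2^log2_fc, log2_fc = log2_fc,
        p_value = rep(1e-6, length(genes)),
        q_value = rep(1e-5, length(genes)),
        direction = direction, row.names = genes)
    new("DEResults", res)
}

# the frozen hub-recovery study design (see the methods vignette)
hubRecoveryConfig <- function(seed) {
    simulationConfig(nPairs = 158, nGenes = 3000, fracDE = 0.25,
        foldChangeRange = c(4, 16), nModules = 0,
        baselineLog2MeanRange = c(6, 10),
        hubSpec = data.frame(direction = rep(c("up", "down"), each = 2),
            n_partners = rep(160L, 4), stringsAsFactors = FALSE),
        seed = seed)
}

# the frozen inter-module recovery design: module sizes mirror the
# reported proliferation (344) and lipid-catabolism (610) programs
moduleRecoveryConfig <- function(seed, rho) {
    simulationConfig(nPairs = 79, nGenes = 2000, fracDE = 0,
        nModules = 2, moduleSizes = c(344L, 610L),
        interModuleCorr = matrix(c(1, rho, rho, 1), 2),
        hubSpec = data.frame(), seed = seed)
}

runNetworkPipeline <- function(gen, samples = "tumors", threshold = 0.8) {
    de <- suppressMessages(runDE(gen$cohort))
    degs <- unlist(callDEGs(de), use.names = FALSE)
    cc <- correlationMatrix(gen$cohort, degs, samples = samples)
    buildNetwork(cc, de, threshold = threshold)
}
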