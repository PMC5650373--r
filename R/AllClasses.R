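#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Paired tumor/normal FPKM cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `"fpkm"`
#' assay (non-negative, finite, gene x sample) and per-sample metadata in
#' `colData`: `subject_id` (the pair key), `condition` (`"tumor"` or
#' `"normal"`), and optionally `stage_numeric` (TNM stage 1-4, tumors),
#' `stage_class` (`"low"` for stages 1-2, `"high"` for 3-4) and `grade`.
#' When the object is declared paired (`metadata(x)$paired`, the default),
#' validity requires every subject to contribute exactly one tumor and one
#' normal sample.
#'
#' @seealso [PairedCohort()], [fpkm()], [sampleCondition()]
#' @export
setClass("PairedCohort", contains = "SummarizedExperiment")

#' Per-gene differential expression results
#'
#' A [S4Vectors::DFrame] with one row per tested gene and columns
#' `mean_T`, `mean_N` (mean FPKM per condition), `fold_change`
#' (`(mean_T + eps) / (mean_N + eps)` on the linear FPKM scale),
#' `log2_fc`, `p_value` (paired-ANOVA condition p), `q_value`
#' (Benjamini-Hochberg adjusted) and `direction` (`"up"`, `"down"` or
#' `"ns"`). Thresholds and funnel counts live in `metadata()`.
#'
#' @seealso [runDE()], [callDEGs()]
#' @export
setClass("DEResults", contains = "DFrame")

#' Named gene-set collection
#'
#' Named list of character vectors of gene identifiers (unique within a
#' set), with an optional one-line description per set. Stands in for GO /
#' pathway categories supplied as GMT files.
#'
#' @slot sets named list of character vectors; names unique, sets non-empty.
#' @slot descriptions named character vector parallel to `sets`.
#' @seealso [readGMT()], [geneSets()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s) == 0L) return(TRUE)
    if (is.null(names(s)) || anyDuplicated(names(s)))
        return("set names must be present and unique")
    if (any(lengths(s) == 0L))
        return(paste0("empty gene set(s): ",
            paste(names(s)[lengths(s) == 0L], collapse = ", ")))
    if (any(vapply(s, anyDuplicated, 0L) > 0L))
        return("gene sets must not contain duplicated members")
    if (!identical(names(object@descriptions), names(s)))
        return("descriptions must be named parallel to sets")
    TRUE
})

#' Signed Pearson co-expression network
#'
#' Relevance network over differentially expressed genes: an edge joins
#' every unordered gene pair whose Pearson correlation of log2(FPKM + 1)
#' profiles exceeds the threshold in absolute value (strictly). Nodes
#' carry the DE direction, fold change and degree; genes left without any
#' edge are excluded at construction time.
#'
#' @slot nodes `DFrame` with columns `gene`, `direction`, `fold_change`,
#'   `log2_fc`, `degree`.
#' @slot edges `DFrame` with columns `from`, `to`, `cc`, `sign`
#'   (`"pos"`/`"neg"`).
#' @slot threshold numeric(1), the |cc| cut applied (edges satisfy
#'   `|cc| > threshold`).
#' @slot sampleSet character(1) describing the samples the correlations
#'   were computed over (`"all"`, `"tumors"` or `"normals"`).
#' @seealso [buildNetwork()], [selectHubs()], [hubNeighborhood()]
#' @export
setClass("CoexpressionNetwork",
    representation(nodes = "DFrame", edges = "DFrame",
        threshold = "numeric", sampleSet = "character"))

setValidity("CoexpressionNetwork", function(object) {
    nd <- object@nodes
    ed <- object@edges
    need_n <- c("gene", "direction", "fold_change", "log2_fc", "degree")
    need_e <- c("from", "to", "cc", "sign")
    if (!all(need_n %in% colnames(nd))) return("nodes lack required columns")
    if (!all(need_e %in% colnames(ed))) return("edges lack required columns")
    if (anyDuplicated(nd$gene)) return("duplicated node gene ids")
    if (nrow(ed)) {
        if (any(ed$from == ed$to)) return("self-edges are not allowed")
        if (!all(c(ed$from, ed$to) %in% nd$gene))
            return("edge endpoints must be listed nodes")
        if (any(abs(ed$cc) <= object@threshold))
            return("all edges must satisfy |cc| > threshold")
        if (!all(ed$sign == ifelse(ed$cc > 0, "pos", "neg")))
            return("edge sign class inconsistent with cc sign")
    }
    inc <- table(factor(c(ed$from, ed$to), levels = nd$gene))
    if (!all(nd$degree == as.integer(inc)))
        return("node degrees inconsistent with incident edge counts")
    TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' Records everything the generator planted, so recovery can be scored:
#' true differentially expressed genes (fold, direction), module
#' memberships, hub genes with their coupled partners, the realized
#' inter-module factor correlation matrix and the seed.
#'
#' @slot de_genes `DFrame` with columns `gene`, `fold_change` (true
#'   multiplicative tumor/normal effect), `direction`.
#' @slot module_of named character vector: gene -> module id.
#' @slot hub_genes `DFrame` with columns `gene`, `direction`,
#'   `n_partners`, plus a `partners` CharacterList-like list column.
#' @slot factor_corr numeric matrix of inter-module factor correlations.
#' @slot seed integer(1).
#' @slot version character(1), truth-file schema version.
#' @seealso [generateCohort()], [writeTruth()], [readTruth()]
#' @export
setClass("SyntheticTruth",
    representation(de_genes = "DFrame", module_of = "character",
        hub_genes = "DFrame", factor_corr = "matrix",
        seed = "integer", version = "character"))

setValidity("SyntheticTruth", function(object) {
    fc <- object@factor_corr
    if (length(fc) && !isSymmetric(unname(fc), tol = 1e-8))
        return("factor_corr must be symmetric")
    if (nrow(object@hub_genes) &&
        !all(object@hub_genes$gene %in% object@de_genes$gene))
        return("every planted hub must be a planted DE gene")
    TRUE
})

#' Synthetic paired-cohort simulation settings
#'
#' Parameters of the generative model for a paired tumor/normal FPKM
#' cohort. Defaults emulate the study design the package targets: 79
#' tumor/normal pairs; an expressed/low-abundance split with about 35%
#' of genes below mean FPKM 1; 10% of genes carrying true tumor effects
#' log-uniform between 2- and 250-fold; five correlated latent-factor
#' modules whose sign structure couples the two upregulated programs
#' together and anti-couples them with the three downregulated programs;
#' ten planted hub genes (five per direction); a 2:1 high:low stage
#' split among tumors.
#'
#' @slot nPairs integer, number of tumor/normal subject pairs.
#' @slot nGenes integer, number of genes.
#' @slot fracDE fraction of genes with true condition effects.
#' @slot foldChangeRange length-2 numeric, multiplicative effect-size
#'   envelope on the FPKM scale; effects are drawn log-uniformly.
#' @slot nModules integer, number of latent-factor modules.
#' @slot moduleSizes integer vector of module sizes (sum <= nGenes).
#' @slot interModuleCorr symmetric unit-diagonal positive-semidefinite
#'   matrix of latent-factor correlations.
#' @slot intraModuleLoading loading of member genes on their module
#'   factor (log2 units).
#' @slot hubSpec data.frame with columns `direction` and `n_partners`,
#'   one row per planted hub.
#' @slot hubCor,partnerCor target within-condition correlations of a
#'   hub gene and of its coupled partners with the hub's latent factor;
#'   loadings are calibrated against the subject + residual variance so
#'   these correlations are realized regardless of effect size.
#' @slot subjectSD between-subject SD on the log2 scale.
#' @slot noiseSD residual SD on the log2 scale.
#' @slot baselineLog2MeanRange range of expressed-gene log2 baselines.
#' @slot fracLowAbundance fraction of genes forced below mean FPKM 1.
#' @slot stageHighFraction fraction of tumors labelled high stage.
#' @slot tumorVarMultiplier,normalVarMultiplier per-condition residual
#'   variance multipliers (1 = homoskedastic).
#' @slot seed integer seed driving one global RNG stream.
#' @seealso [simulationConfig()], [generateCohort()]
#' @export
setClass("SimulationConfig",
    representation(nPairs = "integer", nGenes = "integer",
        fracDE = "numeric", foldChangeRange = "numeric",
        nModules = "integer", moduleSizes = "integer",
        interModuleCorr = "matrix", intraModuleLoading = "numeric",
        hubSpec = "data.frame", hubCor = "numeric",
        partnerCor = "numeric", subjectSD = "numeric",
        noiseSD = "numeric", baselineLog2MeanRange = "numeric",
        fracLowAbundance = "numeric", stageHighFraction = "numeric",
        tumorVarMultiplier = "numeric", normalVarMultiplier = "numeric",
        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nPairs < 2L) return("nPairs must be >= 2")
    if (object@nGenes < 1L) return("nGenes must be >= 1")
    for (f in c("fracDE", "fracLowAbundance", "stageHighFraction")) {
        v <- slot(object, f)
        if (v < 0 || v > 1) return(paste(f, "must lie in [0, 1]"))
    }
    fr <- object@foldChangeRange
    if (length(fr) != 2L || any(fr < 1) || fr[1] > fr[2])
        return("foldChangeRange must be [low, high] with 1 <= low <= high")
    R <- object@interModuleCorr
    if (length(R)) {
        if (nrow(R) != object@nModules || ncol(R) != object@nModules)
            return("interModuleCorr must be nModules x nModules")
        if (!isSymmetric(unname(R), tol = 1e-8))
            return("interModuleCorr must be symmetric")
        if (any(abs(diag(R) - 1) > 1e-8))
            return("interModuleCorr must have unit diagonal")
        if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <
            -1e-8)
            return("interModuleCorr must be positive semidefinite")
    }
    if (length(object@moduleSizes) != object@nModules)
        return("moduleSizes must have one entry per module")
    if (sum(object@moduleSizes) > object@nGenes)
        return("module sizes must sum to at most nGenes")
    if (nrow(object@hubSpec) &&
        !all(object@hubSpec$direction %in% c("up", "down")))
        return("hubSpec$direction must be 'up' or 'down'")
    for (f in c("hubCor", "partnerCor")) {
        v <- slot(object, f)
        if (v <= 0 || v >= 1) return(paste(f, "must lie in (0, 1)"))
    }
    TRUE
})
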