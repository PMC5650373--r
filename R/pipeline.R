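#' Pipeline configuration
#'
#' Assembles a validated configuration list for [runPipeline()]. Every
#' stage threshold defaults to the cascade's canonical value: mean FPKM
#' > 1 abundance filter, fold change > 2 with FDR <= 0.05 for the DEG
#' call, |cc| > 0.8 for the network, 5 hubs per direction, enrichment
#' FDR < 0.05. Configurations can also be loaded from YAML with
#' [readPipelineConfig()]; explicit arguments win over file values.
#'
#' @param outDir output directory (created if absent).
#' @param stages character vector of stages to run, in dependency order
#'   among `"simulate"`, `"de"`, `"cluster"`, `"enrich"`, `"network"`,
#'   `"hubs"`, `"modules"`.
#' @param simulate logical; generate the cohort instead of reading it.
#' @param simConfig a [SimulationConfig-class] (when simulating).
#' @param exprPath,metaPath input TSV paths (when not simulating).
#' @param gmtPath GMT collection for the enrichment stage; when
#'   simulating and unset, gene sets are derived from the planted truth.
#' @param modulesGmtPath GMT of module definitions for the modules
#'   stage; same simulated fallback.
#' @param minFPKM,fcThreshold,fdrThreshold,ccThreshold,kHubs,enrichFdr
#'   stage thresholds.
#' @param sampleSet correlation sample set (`"all"`, `"tumors"`,
#'   `"normals"`).
#' @param seed integer seed recorded in the manifest and forwarded to
#'   the simulator.
#' @return a named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir,
        stages = c("simulate", "de", "cluster", "enrich", "network",
            "hubs", "modules"),
        simulate = TRUE, simConfig = NULL, exprPath = NULL,
        metaPath = NULL, gmtPath = NULL, modulesGmtPath = NULL,
        minFPKM = 1, fcThreshold = 2, fdrThreshold = 0.05,
        ccThreshold = 0.8, kHubs = 5L, enrichFdr = 0.05,
        sampleSet = "all", seed = 1L) {
    known <- c("simulate", "de", "cluster", "enrich", "network", "hubs",
        "modules")
    bad <- setdiff(stages, known)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stopifnot(minFPKM >= 0, fcThreshold > 0, fdrThreshold >= 0,
        fdrThreshold <= 1, ccThreshold >= 0, ccThreshold < 1,
        kHubs >= 1)
    if (is.null(simConfig)) simConfig <- simulationConfig(seed = seed)
    cfg <- list(outDir = outDir, stages = stages, simulate = simulate,
        simConfig = simConfig, exprPath = exprPath, metaPath = metaPath,
        gmtPath = gmtPath, modulesGmtPath = modulesGmtPath,
        minFPKM = minFPKM, fcThreshold = fcThreshold,
        fdrThreshold = fdrThreshold, ccThreshold = ccThreshold,
        kHubs = as.integer(kHubs), enrichFdr = enrichFdr,
        sampleSet = sampleSet, seed = as.integer(seed))
    class(cfg) <- "pipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML file with any subset of the arguments above
#'   (`simConfig` given as a named list of [simulationConfig()]
#'   arguments).
#' @param ... overrides applied on top of the file values.
#' @export
readPipelineConfig <- function(path, ...) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$simConfig)) {
        sc <- y$simConfig
        if (!is.null(sc$hubSpec)) {
            sc$hubSpec <- if (!length(sc$hubSpec) ||
                !length(sc$hubSpec$direction)) data.frame()
                else as.data.frame(sc$hubSpec)
        }
        if (!is.null(sc$interModuleCorr))
            sc$interModuleCorr <- do.call(rbind, sc$interModuleCorr)
        y$simConfig <- do.call(simulationConfig, sc)
    }
    ov <- list(...)
    y[names(ov)] <- ov
    do.call(pipelineConfig, y)
}

.stageDeps <- list(simulate = character(), de = character(),
    cluster = "de", enrich = "de", network = "de", hubs = "network",
    modules = character())

.fmtNum <- function(x) sprintf("%.6f", x)

#' Run the full analysis cascade
#'
#' Executes the enabled stages in dependency order — simulate (or load)
#' the paired cohort, differential expression, clustering/PCA with
#' discordance reporting, enrichment, network construction, hub
#' ranking, module correlation — writing each stage's outputs as
#' fixed-precision text files under `config$outDir` together with a
#' reproducibility manifest (`manifest.json`: package version, seed,
#' config snapshot, input checksums, per-stage gene funnel counts). A
#' stage whose dependency is not enabled aborts with an error naming
#' the missing stage. Identical configurations (and seed) produce
#' byte-identical outputs.
#'
#' @param config a `pipelineConfig` list from [pipelineConfig()].
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    for (st in config$stages) {
        need <- setdiff(.stageDeps[[st]], config$stages)
        if (length(need))
            stop(sprintf("stage '%s' requires stage '%s' to be enabled",
                st, need[1L]))
    }
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(f) file.path(config$outDir, f)
    manifest <- list(
        package_version = as.character(utils::packageVersion("pairedCoex")),
        seed = config$seed,
        config = .configSnapshot(config),
        inputs = list(), funnel = list(), stages_run = config$stages)
    truth <- NULL; cohort <- NULL; de <- NULL; net <- NULL

    if ("simulate" %in% config$stages) {
        if (!isTRUE(config$simulate))
            stop("stage 'simulate' enabled but config$simulate is FALSE")
        gen <- generateCohort(config$simConfig)
        cohort <- gen$cohort; truth <- gen$truth
        writeExpressionTable(fpkm(cohort), outfile("expression.tsv"))
        writeSampleMetadata(as.data.frame(colData(cohort)),
            outfile("metadata.tsv"))
        writeTruth(truth, outfile("truth.json"))
    } else {
        if (is.null(config$exprPath) || is.null(config$metaPath))
            stop("exprPath and metaPath are required when not simulating")
        mat <- readExpressionTable(config$exprPath)
        md <- readSampleMetadata(config$metaPath)
        cohort <- PairedCohort(mat, md)
        manifest$inputs <- list(
            expression = unname(tools::md5sum(config$exprPath)),
            metadata = unname(tools::md5sum(config$metaPath)))
    }
    manifest$funnel$genes_input <- nrow(cohort)
    manifest$funnel$samples <- ncol(cohort)

    if ("de" %in% config$stages) {
        de <- runDE(cohort, minFPKM = config$minFPKM,
            fcThreshold = config$fcThreshold,
            fdrThreshold = config$fdrThreshold)
        writeDETable(de, outfile("de.tsv"))
        md <- S4Vectors::metadata(de)
        manifest$funnel$genes_abundant <- md$n_abundant
        manifest$funnel$degs_up <- md$n_up
        manifest$funnel$degs_down <- md$n_down
        manifest$funnel$degs_total <- md$n_up + md$n_down
    }

    if ("cluster" %in% config$stages) {
        degs <- unlist(callDEGs(de), use.names = FALSE)
        if (!length(degs)) {
            warning("no DEGs; clustering stage skipped")
        } else {
            hca <- hcaSamples(cohort, degs)
            utils::write.table(hca$assignment,
                outfile("cluster_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            ape::write.tree(ape::as.phylo(hca$hclust),
                outfile("dendrogram.nwk"))
            rep_ <- discordanceReport(hca, cohort, panelName = "degs")
            withRole <- function(df, role)
                data.frame(role = rep(role, nrow(df)), df,
                    stringsAsFactors = FALSE)
            disc <- rbind(
                withRole(rep_$tumors_clustering_with_normals,
                    "tumor_with_normals"),
                withRole(rep_$normals_clustering_with_tumors,
                    "normal_with_tumors"))
            utils::write.table(disc, outfile("discordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            pca <- pcaSamples(cohort, degs, nComponents = 2L)
            sc <- data.frame(sample_id = rownames(pca$scores),
                PC1 = .fmtNum(pca$scores[, 1L]),
                PC2 = .fmtNum(pca$scores[, 2L]))
            utils::write.table(sc, outfile("pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            manifest$funnel$cluster_concordant <-
                sum(hca$assignment$concordant)
        }
    }

    if ("enrich" %in% config$stages) {
        sets <- .resolveGeneSets(config$gmtPath, truth,
            "enrichment gene sets")
        enr <- enrichByDirection(de, sets, fdrThreshold = config$enrichFdr)
        .writeEnrichTable(enr$up, outfile("enrich_up.tsv"))
        .writeEnrichTable(enr$down, outfile("enrich_down.tsv"))
        manifest$funnel$enriched_up <- sum(enr$up$enriched)
        manifest$funnel$enriched_down <- sum(enr$down$enriched)
    }

    if ("network" %in% config$stages) {
        degs <- unlist(callDEGs(de), use.names = FALSE)
        if (length(degs) < 2L) {
            warning("fewer than 2 DEGs; network stage skipped")
        } else {
            cc <- correlationMatrix(cohort, degs,
                samples = config$sampleSet)
            net <- buildNetwork(cc, de, threshold = config$ccThreshold)
            writeNetwork(net, outfile("network_edges.tsv"),
                format = "tsv_edge_list",
                nodePath = outfile("network_nodes.tsv"))
            writeNetwork(net, outfile("network.sif"), format = "sif")
            writeNetwork(net, outfile("network.graphml"),
                format = "graphml")
            manifest$funnel$network_genes <- nrow(networkNodes(net))
            manifest$funnel$network_edges <- nrow(networkEdges(net))
        }
    }

    if ("hubs" %in% config$stages && !is.null(net)) {
        hubs <- selectHubs(net, kPerDirection = config$kHubs)
        out <- data.frame(gene = hubs$gene, direction = hubs$direction,
            degree = hubs$degree,
            fold_change = .fmtNum(hubs$fold_change),
            log2_fc = .fmtNum(hubs$log2_fc))
        utils::write.table(out, outfile("hubs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        if (nrow(hubs)) {
            nb <- hubNeighborhood(net, hubs)
            writeNetwork(nb, outfile("hub_neighborhood_edges.tsv"),
                format = "tsv_edge_list",
                nodePath = outfile("hub_neighborhood_nodes.tsv"))
            manifest$funnel$hub_neighborhood_genes <-
                nrow(networkNodes(nb))
        }
    }

    if ("modules" %in% config$stages) {
        mods <- .resolveGeneSets(config$modulesGmtPath, truth,
            "module definitions")
        mc <- moduleCorrelation(cohort, mods, samples = config$sampleSet,
            threshold = config$ccThreshold)
        out <- data.frame(module_a = mc$module_a, module_b = mc$module_b,
            eigengene_cc = .fmtNum(mc$eigengene_cc),
            mean_pairwise_cc = .fmtNum(mc$mean_pairwise_cc),
            classification = mc$classification)
        utils::write.table(out, outfile("module_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    jsonlite::write_json(manifest, outfile("manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

.configSnapshot <- function(config) {
    snap <- config[setdiff(names(config), "simConfig")]
    sc <- config$simConfig
    snap$simConfig <- list(nPairs = sc@nPairs, nGenes = sc@nGenes,
        fracDE = sc@fracDE, foldChangeRange = sc@foldChangeRange,
        nModules = sc@nModules, moduleSizes = sc@moduleSizes,
        intraModuleLoading = sc@intraModuleLoading,
        hubCor = sc@hubCor, partnerCor = sc@partnerCor,
        subjectSD = sc@subjectSD, noiseSD = sc@noiseSD,
        baselineLog2MeanRange = sc@baselineLog2MeanRange,
        fracLowAbundance = sc@fracLowAbundance,
        stageHighFraction = sc@stageHighFraction, seed = sc@seed)
    snap
}

.resolveGeneSets <- function(path, truth, what) {
    if (!is.null(path)) return(readGMT(path))
    if (is.null(truth))
        stop(what, " need a GMT file when the cohort is not simulated")
    sets <- list()
    if (length(truth@module_of))
        sets <- split(names(truth@module_of), truth@module_of)
    deg <- truth@de_genes
    if (nrow(deg)) {
        sets$planted_up <- deg$gene[deg$direction == "up"]
        sets$planted_down <- deg$gene[deg$direction == "down"]
    }
    sets <- sets[lengths(sets) > 0L]
    if (!length(sets)) stop("no ", what, " derivable from the truth")
    GeneSetCollection(sets)
}

.writeEnrichTable <- function(tab, path) {
    out <- data.frame(set_name = tab$set_name, overlap = tab$overlap,
        set_size = tab$set_size, query_size = tab$query_size,
        universe_size = tab$universe_size,
        p_value = sprintf("%.6e", tab$p_value),
        q_value = sprintf("%.6e", tab$q_value),
        enriched = tab$enriched)
    if (!nrow(tab)) out <- out[0L, , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
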