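test_that("identical seeds give bit-identical cohorts", {
    cfg <- simulationConfig(nPairs = 10, nGenes = 200, seed = 5,
        nModules = 2, moduleSizes = c(20L, 20L),
        interModuleCorr = matrix(c(1, .5, .5, 1), 2),
        hubSpec = data.frame(direction = "up", n_partners = 5L))
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(fpkm(a$cohort), fpkm(b$cohort))
    expect_identical(as.data.frame(colData(a$cohort)),
        as.data.frame(colData(b$cohort)))
    expect_identical(as.data.frame(a$truth@de_genes),
        as.data.frame(b$truth@de_genes))
    # different seed, different data
    c_ <- generateCohort(simulationConfig(nPairs = 10, nGenes = 200,
        nModules = 0, hubSpec = data.frame(), seed = 6))
    expect_false(identical(fpkm(a$cohort), fpkm(c_$cohort)))
})

test_that("cohort dimensions, pairing and stage split match the design", {
    gen <- generateCohort(simulationConfig(nPairs = 79, nGenes = 500,
        nModules = 0, hubSpec = data.frame(), seed = 2))
    co <- gen$cohort
    expect_equal(dim(co), c(500L, 158L))
    cond <- sampleCondition(co)
    expect_equal(sum(cond == "tumor"), 79)
    expect_equal(length(unique(subjectIds(co))), 79)
    # 53 of 79 tumors high stage (2:1 high:low)
    sc <- stageClass(co)[cond == "tumor"]
    expect_equal(sum(sc == "high"), 53)
    expect_equal(sum(sc == "low"), 26)
    # normals inherit the adjacent tumor's stage class
    adj <- adjacentTumorStage(co)
    expect_identical(unname(adj["N01"]), unname(stageClass(co)["T01"]))
})

test_that("null configuration is calibrated: ~5% rejections at p < 0.05", {
    gen <- generateCohort(simulationConfig(nPairs = 79, nGenes = 5000,
        fracDE = 0, nModules = 0, hubSpec = data.frame(),
        fracLowAbundance = 0, seed = 7))
    p <- pairedAnovaP(gen$cohort)
    expect_equal(mean(p < 0.05), 0.05, tolerance = 0.01 / 0.05)
    expect_gt(mean(p < 0.05), 0.04)
    expect_lt(mean(p < 0.05), 0.06)
})

test_that("low-abundance fraction is realized within 3 points", {
    gen <- generateCohort(simulationConfig(seed = 3))
    frac <- mean(rowMeans(fpkm(gen$cohort)) < 1)
    expect_lt(abs(frac - 0.35), 0.03)
})

test_that("planted log2 fold changes fill the configured envelope", {
    gen <- generateCohort(simulationConfig(nPairs = 10, nGenes = 4000,
        fracDE = 0.25, nModules = 0, hubSpec = data.frame(), seed = 9))
    lf <- log2(gen$truth@de_genes$fold_change)
    expect_gte(min(lf), 1)
    expect_lte(max(lf), log2(250))
    # log-uniform: mean |log2 fold| near the envelope midpoint
    expect_equal(mean(lf), (1 + log2(250)) / 2, tolerance = 0.05)
})

test_that("paired structure is real: within-pair correlation beats between-pair", {
    gen <- generateCohort(simulationConfig(nPairs = 20, nGenes = 800,
        fracDE = 0, nModules = 0, hubSpec = data.frame(), seed = 4))
    X <- log2fpkm(gen$cohort)
    Xc <- X - rowMeans(X)
    subj <- subjectIds(gen$cohort)
    cond <- sampleCondition(gen$cohort)
    tums <- names(cond)[cond == "tumor"]
    withinCor <- vapply(tums, function(t) {
        mate <- names(subj)[subj == subj[[t]] & cond == "normal"]
        cor(Xc[, t], Xc[, mate])
    }, 0)
    set.seed(1)
    betweenCor <- vapply(tums, function(t) {
        other <- sample(setdiff(names(subj)[cond == "normal"],
            names(subj)[subj == subj[[t]]]), 1)
        cor(Xc[, t], Xc[, other])
    }, 0)
    expect_gt(mean(withinCor), mean(betweenCor))
    expect_gt(mean(withinCor), 0.3)
    expect_lt(abs(mean(betweenCor)), 0.1)
})

test_that("anti-correlated module factors yield negative eigengene correlation", {
    hits <- vapply(1:20, function(s) {
        gen <- generateCohort(simulationConfig(nPairs = 79, nGenes = 400,
            fracDE = 0, nModules = 2, moduleSizes = c(40L, 40L),
            interModuleCorr = matrix(c(1, -0.9, -0.9, 1), 2),
            hubSpec = data.frame(), seed = s))
        mods <- GeneSetCollection(split(names(gen$truth@module_of),
            gen$truth@module_of))
        mc <- moduleCorrelation(gen$cohort, mods, threshold = 0.6)
        mc$eigengene_cc[mc$module_a == "M1" & mc$module_b == "M2"]
    }, 0)
    expect_true(all(hits < -0.6))
})

test_that("non-positive-semidefinite factor correlation is rejected upfront", {
    R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
    expect_error(simulationConfig(nPairs = 10, nGenes = 100, nModules = 3,
        moduleSizes = c(10L, 10L, 10L), interModuleCorr = R,
        hubSpec = data.frame()), "semidefinite")
})

test_that("truth files round-trip losslessly and reject foreign versions", {
    gen <- generateCohort(simulationConfig(nPairs = 8, nGenes = 300,
        fracDE = 0.2, nModules = 2, moduleSizes = c(15L, 15L),
        interModuleCorr = matrix(c(1, .4, .4, 1), 2),
        hubSpec = data.frame(direction = c("up", "down"),
            n_partners = c(6L, 4L)), seed = 11))
    f <- withr::local_tempfile(fileext = ".json")
    writeTruth(gen$truth, f)
    back <- readTruth(f)
    expect_identical(as.data.frame(back@de_genes)[1:3],
        as.data.frame(gen$truth@de_genes)[1:3])
    expect_identical(back@module_of, gen$truth@module_of)
    expect_identical(back@hub_genes$gene, gen$truth@hub_genes$gene)
    expect_identical(back@hub_genes$partners, gen$truth@hub_genes$partners)
    expect_identical(back@factor_corr, gen$truth@factor_corr)
    expect_identical(back@seed, gen$truth@seed)

    # empty hub list stays empty
    gen0 <- generateCohort(simulationConfig(nPairs = 5, nGenes = 50,
        fracDE = 0, nModules = 0, hubSpec = data.frame(), seed = 1))
    writeTruth(gen0$truth, f)
    expect_equal(nrow(readTruth(f)@hub_genes), 0)

    # version gate
    x <- jsonlite::read_json(f)
    x$version <- "9.9"
    jsonlite::write_json(x, f, auto_unbox = TRUE)
    expect_error(readTruth(f), "version")
})

test_that("every planted hub is a planted DE gene", {
    gen <- generateCohort(hubRecoveryConfig(1))
    expect_true(all(gen$truth@hub_genes$gene %in% gen$truth@de_genes$gene))
    expect_true(all(unlist(gen$truth@hub_genes$partners) %in%
        gen$truth@de_genes$gene))
    # partner sets disjoint within a direction
    for (d in c("up", "down")) {
        ps <- gen$truth@hub_genes$partners[
            gen$truth@hub_genes$direction == d]
        expect_false(anyDuplicated(unlist(ps)) > 0)
    }
})
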