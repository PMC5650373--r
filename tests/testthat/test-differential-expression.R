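test_that("abundance filter applies a strict mean-FPKM cut", {
    m <- rbind(kept = c(2, 2, 2, 2),
               boundary = c(1, 1, 1, 1),      # mean exactly 1: removed
               zero = c(0, 0, 0, 0),
               justover = c(1.004, 1, 1, 1))  # mean 1.001: kept
    co <- toyCohort(m)
    got <- filterByAbundance(co)
    expect_identical(rownames(got), c("kept", "justover"))
    expect_error(filterByAbundance(co, threshold = -1), "non-negative")
    # plain matrix input behaves identically
    expect_identical(rownames(filterByAbundance(fpkm(co))),
        c("kept", "justover"))
})

test_that("paired ANOVA equals the squared paired t-test", {
    co <- randomCohort(50, 10, delta = rep(c(0, 1), 25), seed = 3)
    p <- pairedAnovaP(co)
    X <- log2fpkm(co)
    oracle <- vapply(seq_len(nrow(X)), function(i)
        t.test(X[i, 1:10], X[i, 11:20], paired = TRUE)$p.value, 0)
    expect_equal(as.numeric(p), oracle, tolerance = 1e-8)
    # F = t^2 identity, explicitly
    tstat <- vapply(seq_len(nrow(X)), function(i)
        unname(t.test(X[i, 1:10], X[i, 11:20], paired = TRUE)$statistic), 0)
    Fstat <- qf(as.numeric(p), 1, 9, lower.tail = FALSE)
    expect_equal(Fstat, tstat^2, tolerance = 1e-8)
})

test_that("degenerate genes are flagged with p = 1, not errors", {
    set.seed(4)
    m <- matrix(5, 3, 8)           # every tumor equals its paired normal
    m[2, ] <- c(rep(8, 4), rep(2, 4))  # constant nonzero difference
    m[3, ] <- rexp(8) + 1
    co <- toyCohort(m)
    expect_message(p <- pairedAnovaP(co), "zero within-pair variance")
    expect_equal(unname(p[1:2]), c(1, 1))
    expect_true(attr(p, "zero_variance")[1])
    expect_false(attr(p, "zero_variance")[3])
})

test_that("null p-values are uniform (Kolmogorov-Smirnov at 1%)", {
    co <- randomCohort(200, 12, delta = 0, seed = 8)
    p <- pairedAnovaP(co)
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH q-values match the step-up definition", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFDR(0.04), 0.04)
    set.seed(99)
    for (i in 1:50) {
        p <- runif(sample(1:200, 1))^sample(1:3, 1)
        q <- bhFDR(p)
        expect_equal(q, bhStepUpOracle(p), tolerance = 1e-12)
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted order
    }
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhFDR(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("fold change uses the pseudocount ratio of condition means", {
    m <- rbind(a = c(10, 10, 5, 5),
               b = c(5, 5, 0, 0))
    co <- toyCohort(m)
    fc <- foldChange(co)
    expect_equal(fc["a", "fold_change"], (10 + 1e-3) / (5 + 1e-3))
    expect_equal(fc["a", "log2_fc"], log2(fc["a", "fold_change"]))
    # zero normal mean stays finite via the pseudocount
    expect_equal(fc["b", "fold_change"], 5.001 / 0.001)
    # per-pair geometric mean alternative
    fg <- foldChange(co, method = "per_pair_geomean")
    expect_equal(fg["a", "fold_change"], 2, tolerance = 1e-3)
})

test_that("a planted KLK6-scale effect is recovered within 25%", {
    est <- vapply(1:20, function(s) {
        gen <- generateCohort(simulationConfig(nPairs = 79, nGenes = 300,
            fracDE = 0.05, foldChangeRange = c(231, 231), nModules = 0,
            hubSpec = data.frame(), seed = s))
        de <- suppressMessages(runDE(gen$cohort))
        tt <- as.data.frame(gen$truth@de_genes)
        tt <- tt[tt$gene %in% rownames(de), ]
        fc <- de[tt$gene, "fold_change"]
        # a planted decrease of 231-fold is recovered as fold 1/231
        mean(ifelse(tt$direction == "up", fc, 1 / fc))
    }, 0)
    expect_lt(abs(mean(est) - 231) / 231, 0.25)
})

test_that("the DEG call applies strict fold and inclusive FDR criteria", {
    genes <- sprintf("g%d", 1:5)
    res <- S4Vectors::DataFrame(
        mean_T = c(4, 231, 0.3, 10, 1),
        mean_N = c(2, 1, 1, 5, 2),
        fold_change = c(2.0, 231, 0.3, 2.01, 0.499),
        log2_fc = log2(c(2.0, 231, 0.3, 2.01, 0.499)),
        p_value = c(1e-4, 1e-30, 0.1, 1e-4, 1e-4),
        q_value = c(0.01, 1e-28, 0.2, 0.05, 0.01),
        row.names = genes)
    res$direction <- ifelse(
        res$fold_change > 2 & res$q_value <= 0.05, "up",
        ifelse(1 / res$fold_change > 2 & res$q_value <= 0.05, "down", "ns"))
    de <- new("DEResults", res)
    degs <- callDEGs(de)
    expect_false("g1" %in% degs$up)      # fold exactly 2: strict
    expect_true("g2" %in% degs$up)       # 231-fold, tiny q
    expect_false("g3" %in% c(degs$up, degs$down))  # fails FDR
    expect_true("g4" %in% degs$up)       # q exactly 0.05: inclusive
    expect_true("g5" %in% degs$down)     # 1/fold > 2
    expect_length(intersect(degs$up, degs$down), 0)
})

test_that("swapping condition labels exactly swaps up and down sets", {
    gen <- generateCohort(simulationConfig(nPairs = 15, nGenes = 600,
        fracDE = 0.2, foldChangeRange = c(3, 30), nModules = 0,
        hubSpec = data.frame(), seed = 21))
    co <- gen$cohort
    de <- suppressMessages(runDE(co))
    md <- as.data.frame(colData(co))
    md$condition <- ifelse(md$condition == "tumor", "normal", "tumor")
    coSwap <- PairedCohort(fpkm(co), md)
    deSwap <- suppressMessages(runDE(coSwap))
    expect_setequal(callDEGs(de)$up, callDEGs(deSwap)$down)
    expect_setequal(callDEGs(de)$down, callDEGs(deSwap)$up)
    expect_equal(de$p_value, deSwap$p_value, tolerance = 1e-12)
})

test_that("planted 4-fold effects are detected with sensitivity over 0.9", {
    gen <- generateCohort(simulationConfig(foldChangeRange = c(4, 4),
        seed = 11))
    de <- suppressMessages(runDE(gen$cohort))
    called <- unlist(callDEGs(de), use.names = FALSE)
    sens <- mean(gen$truth@de_genes$gene %in% called)
    expect_gte(sens, 0.90)
})

test_that("volcano coordinates are deterministic and floor p = 0", {
    genes <- c("a", "b", "c")
    res <- S4Vectors::DataFrame(mean_T = 1:3, mean_N = 1:3,
        fold_change = c(4, 0.25, 1), log2_fc = c(2, -2, 0),
        p_value = c(0.01, 0.01, 0), q_value = c(0.02, 0.02, 0),
        direction = c("up", "down", "ns"), row.names = genes)
    v <- volcanoTable(new("DEResults", res))
    expect_equal(v$neg_log10_p[1], 2)
    expect_equal(v$log2_fc[1], -v$log2_fc[2])  # symmetric pair
    expect_true(is.finite(v$neg_log10_p[3]))
    expect_equal(v$direction[3], "ns")
})

test_that("DE tables survive a write/read round trip", {
    gen <- generateCohort(simulationConfig(nPairs = 6, nGenes = 80,
        nModules = 0, hubSpec = data.frame(), seed = 2))
    de <- suppressMessages(runDE(gen$cohort))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeDETable(de, f)
    back <- readDETable(f)
    expect_identical(rownames(back), rownames(de))
    expect_identical(back$direction, de$direction)
    expect_equal(back$fold_change, de$fold_change, tolerance = 1e-5)
})
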