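test_that("correlation matrix matches a two-pass oracle entrywise", {
    co <- randomCohort(50, 10, seed = 31)
    genes <- rownames(fpkm(co))
    cc <- correlationMatrix(co, genes)
    X <- log2fpkm(co)
    set.seed(1)
    for (i in sample(50, 8)) for (j in sample(50, 8)) {
        expect_equal(cc[i, j], pearsonOracle(X[i, ], X[j, ]),
            tolerance = 1e-12)
    }
    expect_equal(cc, t(cc), tolerance = 1e-12)
    expect_equal(unname(diag(cc)), rep(1, 50), tolerance = 1e-12)
})

test_that("exact duplicates and affine transforms hit the +-1 boundaries", {
    set.seed(32)
    base <- 2^runif(8, 2, 4)
    m <- rbind(a = base, twin = base,
               anti = 2^(8 - log2(base + 1) * 1.5) - 1)
    co <- toyCohort(m)
    cc <- correlationMatrix(co, rownames(m))
    expect_equal(cc["a", "twin"], 1, tolerance = 1e-12)
    expect_equal(cc["a", "anti"], -1, tolerance = 1e-12)
})

test_that("constant genes are dropped and tiny sample sets rejected", {
    m <- rbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
    co <- toyCohort(m)
    expect_message(cc <- correlationMatrix(co, rownames(m)), "flat")
    expect_equal(rownames(cc), "a")
    m2 <- m[, 1:2]
    expect_error(correlationMatrix(toyCohort(m2), "a"), "3 samples")
})

test_that("network construction equals the all-pairs double loop", {
    set.seed(33)
    n <- 100
    genes <- sprintf("g%03d", 1:n)
    # random correlation-like symmetric matrix with heavy tails
    L <- matrix(rnorm(n * 12), n)
    cc <- cor(t(L))
    dimnames(cc) <- list(genes, genes)
    de <- toyDE(genes, rep(c("up", "down"), 50))
    for (thr in c(0.3, 0.5, 0.8)) {
        net <- buildNetwork(cc, de, threshold = thr)
        oracle <- edgeListOracle(cc, thr)
        ed <- as.data.frame(networkEdges(net))
        if (is.null(oracle)) {
            expect_equal(nrow(ed), 0)
        } else {
            key <- function(d) sort(paste(d$from, d$to))
            expect_identical(key(ed), key(oracle))
            o <- order(ed$from, ed$to)
            oo <- order(oracle$from, oracle$to)
            expect_equal(ed$cc[o], oracle$cc[oo], tolerance = 1e-15)
        }
    }
})

test_that("the |cc| threshold is strict and signs classify edges", {
    genes <- c("a", "b", "c", "d")
    cc <- diag(4); dimnames(cc) <- list(genes, genes)
    cc["a", "b"] <- cc["b", "a"] <- 0.8       # exactly at threshold: no edge
    cc["a", "c"] <- cc["c", "a"] <- -0.95
    cc["b", "d"] <- cc["d", "b"] <- 0.80001
    de <- toyDE(genes, c("up", "up", "down", "down"))
    net <- buildNetwork(cc, de, threshold = 0.8)
    ed <- as.data.frame(networkEdges(net))
    expect_equal(nrow(ed), 2)
    expect_false(any(ed$from == "a" & ed$to == "b"))
    expect_equal(ed$sign[ed$to == "c"], "neg")
    expect_equal(ed$sign[ed$to == "d"], "pos")
    # isolated genes excluded from the node set
    expect_setequal(networkNodes(net)$gene, c("a", "b", "c", "d"))

    cc2 <- diag(2); dimnames(cc2) <- list(c("a", "b"), c("a", "b"))
    net2 <- buildNetwork(cc2, de, threshold = 0.8)
    expect_equal(nrow(networkNodes(net2)), 0)

    expect_error(buildNetwork(cc, de, threshold = 1), "\\[0, 1\\)")
    expect_error(buildNetwork(cc, toyDE(genes[1:3],
        c("up", "up", "down"))), "absent")
})

test_that("degree bookkeeping and threshold monotonicity hold", {
    set.seed(34)
    n <- 60
    genes <- sprintf("g%02d", 1:n)
    cc <- cor(t(matrix(rnorm(n * 8), n)))
    dimnames(cc) <- list(genes, genes)
    de <- toyDE(genes, rep(c("up", "down"), n / 2))
    prev <- Inf
    for (thr in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
        net <- buildNetwork(cc, de, threshold = thr)
        nEdges <- nrow(networkEdges(net))
        expect_equal(sum(networkNodes(net)$degree), 2 * nEdges)
        expect_true(all(networkNodes(net)$degree > 0))
        expect_lte(nEdges, prev)
        prev <- nEdges
    }
})

test_that("network is invariant to sample order; negative slopes flip signs", {
    gen <- generateCohort(simulationConfig(nPairs = 12, nGenes = 150,
        fracDE = 0.3, foldChangeRange = c(4, 16), nModules = 0,
        hubSpec = data.frame(), seed = 35))
    co <- gen$cohort
    de <- suppressMessages(runDE(co))
    degs <- unlist(callDEGs(de), use.names = FALSE)
    cc <- correlationMatrix(co, degs)
    net <- buildNetwork(cc, de, 0.6)

    set.seed(36)
    perm <- sample(ncol(co))
    coPerm <- PairedCohort(fpkm(co)[, perm],
        as.data.frame(colData(co))[perm, ])
    ccPerm <- correlationMatrix(coPerm, degs)
    netPerm <- buildNetwork(ccPerm, de, 0.6)
    key <- function(x) {
        ed <- as.data.frame(networkEdges(x))
        sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
    }
    expect_identical(key(net), key(netPerm))

    # flipping one gene on the log2(FPKM+1) scale flips its edge signs
    flip <- degs[1]
    X <- log2fpkm(co)
    X2 <- X
    X2[flip, ] <- max(X[flip, ]) + min(X[flip, ]) - X[flip, ]
    co2 <- PairedCohort(pmax(2^X2 - 1, 0), as.data.frame(colData(co)))
    cc2 <- correlationMatrix(co2, degs)
    expect_equal(cc2[flip, setdiff(degs, flip)],
        -cc[flip, setdiff(degs, flip)], tolerance = 1e-10)
})

starNetwork <- function(hubNames, degrees, folds) {
    from <- character(); to <- character()
    leaves <- character()
    for (i in seq_along(hubNames)) {
        ls <- sprintf("zz_%s_%03d", hubNames[i], seq_len(degrees[i]))
        from <- c(from, rep(hubNames[i], degrees[i]))
        to <- c(to, ls)
        leaves <- c(leaves, ls)
    }
    genes <- c(hubNames, leaves)
    nd <- S4Vectors::DataFrame(gene = genes, direction = "up",
        fold_change = c(folds, rep(2.5, length(leaves))),
        log2_fc = log2(c(folds, rep(2.5, length(leaves)))),
        degree = c(as.integer(degrees), rep(1L, length(leaves))))
    ed <- S4Vectors::DataFrame(from = from, to = to,
        cc = rep(0.9, length(from)), sign = rep("pos", length(from)))
    new("CoexpressionNetwork", nodes = nd, edges = ed,
        threshold = 0.8, sampleSet = "all")
}

test_that("hub ranking reproduces the documented ordering and tie-breaks", {
    net <- starNetwork(
        c("MTHFD1L", "BUB1", "TRIP13", "MAD2L1", "PPAT", "XTRA"),
        c(176, 150, 145, 109, 106, 90),
        c(5.51, 3.15, 4.09, 3.08, 3.06, 2.5))
    hubs <- selectHubs(net, 5)
    expect_equal(hubs$gene,
        c("MTHFD1L", "BUB1", "TRIP13", "MAD2L1", "PPAT"))
    expect_true(all(diff(hubs$degree) <= 0))

    # tie at the k-th rank: larger |log2_fc| wins, then gene id
    net2 <- starNetwork(c("a", "b", "c"), c(10, 10, 10), c(4, 8, 8))
    hubs2 <- selectHubs(net2, 2)
    expect_equal(hubs2$gene, c("b", "c"))

    emptyNet <- new("CoexpressionNetwork",
        nodes = networkNodes(net)[0, ],
        edges = networkEdges(net)[0, ], threshold = 0.8,
        sampleSet = "all")
    expect_warning(h0 <- selectHubs(emptyNet), "empty")
    expect_equal(nrow(h0), 0)
})

test_that("hub neighborhoods are induced subgraphs", {
    genes <- c("hub", "p1", "p2", "p3", "lone1", "lone2")
    cc <- diag(6); dimnames(cc) <- list(genes, genes)
    link <- function(a, b, v) cc[a, b] <<- cc[b, a] <<- v
    link("hub", "p1", 0.9); link("hub", "p2", 0.85)
    link("hub", "p3", -0.88); link("p1", "p2", 0.82)
    link("lone1", "lone2", 0.99)
    de <- toyDE(genes, rep("up", 6))
    net <- buildNetwork(cc, de, 0.8)
    nb <- hubNeighborhood(net, "hub")
    expect_setequal(networkNodes(nb)$gene, c("hub", "p1", "p2", "p3"))
    # induced edges include the p1-p2 edge not incident to the hub
    expect_equal(nrow(networkEdges(nb)), 4)
    expect_equal(sum(networkNodes(nb)$degree), 8)
    expect_error(hubNeighborhood(net, "nothere"), "nothere")
})

test_that("module self-correlation is 1 and guards fire", {
    gen <- generateCohort(simulationConfig(nPairs = 10, nGenes = 200,
        fracDE = 0, nModules = 2, moduleSizes = c(10L, 10L),
        interModuleCorr = diag(2), hubSpec = data.frame(), seed = 37))
    mods <- GeneSetCollection(split(names(gen$truth@module_of),
        gen$truth@module_of))
    mc <- moduleCorrelation(gen$cohort, mods)
    self <- mc[mc$module_a == mc$module_b, ]
    expect_equal(self$eigengene_cc, c(1, 1), tolerance = 1e-12)
    expect_true(all(self$classification == "positive"))

    tiny <- GeneSetCollection(list(ok = geneSets(mods)[[1]],
        small = geneSets(mods)[[2]][1:2]))
    expect_error(moduleCorrelation(gen$cohort, tiny), "small")
    overlap <- GeneSetCollection(list(a = geneSets(mods)[[1]],
        b = geneSets(mods)[[1]][c(1, 2, 3)]))
    expect_error(moduleCorrelation(gen$cohort, overlap), "overlap")
})

test_that("planted inter-module correlations are classified correctly", {
    cls <- vapply(1:5, function(s) {
        gen <- generateCohort(moduleRecoveryConfig(s, -0.9))
        mods <- GeneSetCollection(split(names(gen$truth@module_of),
            gen$truth@module_of))
        mc <- moduleCorrelation(gen$cohort, mods)
        mc$classification[mc$module_a == "M1" & mc$module_b == "M2"]
    }, "")
    expect_true(all(cls == "negative"))
    cls0 <- vapply(1:5, function(s) {
        gen <- generateCohort(moduleRecoveryConfig(s, 0))
        mods <- GeneSetCollection(split(names(gen$truth@module_of),
            gen$truth@module_of))
        mc <- moduleCorrelation(gen$cohort, mods)
        mc$classification[mc$module_a == "M1" & mc$module_b == "M2"]
    }, "")
    expect_true(all(cls0 == "none"))
})

test_that("planted hubs top the degree ranking and keep their partners", {
    gen <- generateCohort(hubRecoveryConfig(101))
    net <- runNetworkPipeline(gen)
    hubs <- selectHubs(net, 5)
    planted <- as.data.frame(gen$truth@hub_genes)
    expect_true(all(planted$gene %in% hubs$gene))
    nb <- hubNeighborhood(net, planted$gene)
    nbGenes <- networkNodes(nb)$gene
    for (i in seq_len(nrow(planted))) {
        partners <- gen$truth@hub_genes$partners[[i]]
        edges <- as.data.frame(networkEdges(net))
        touching <- c(edges$to[edges$from == planted$gene[i]],
                      edges$from[edges$to == planted$gene[i]])
        expect_gte(mean(partners %in% touching), 0.8)
        expect_true(all(intersect(partners, touching) %in% nbGenes))
    }
})
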