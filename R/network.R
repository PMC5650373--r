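.selectSamples <- function(cohort, samples = c("all", "tumors", "normals")) {
    samples <- match.arg(samples)
    cond <- sampleCondition(cohort)
    keep <- switch(samples, all = names(cond),
        tumors = names(cond)[cond == "tumor"],
        normals = names(cond)[cond == "normal"])
    list(ids = keep, label = samples)
}

#' Pearson correlation matrix over a gene set
#'
#' Exact sample Pearson correlation of `log2(FPKM + 1)` gene profiles
#' over the chosen sample set (all samples by default; the
#' tumor/normal pooled view is what drives the strong contrast-induced
#' correlations the network thresholds on). Constant genes are dropped
#' with a message listing them; fewer than 3 samples is an error.
#'
#' @param cohort a [PairedCohort-class].
#' @param genes character vector of genes to correlate.
#' @param samples `"all"`, `"tumors"` or `"normals"`.
#' @return symmetric correlation matrix with a `"sampleSet"` attribute.
#' @export
correlationMatrix <- function(cohort, genes,
        samples = c("all", "tumors", "normals")) {
    stopifnot(is(cohort, "PairedCohort"))
    sel <- .selectSamples(cohort, samples)
    if (length(sel$ids) < 3L)
        stop("need at least 3 samples to estimate correlations")
    X <- log2fpkm(cohort)
    missing <- setdiff(genes, rownames(X))
    if (length(missing))
        stop("gene(s) absent from the matrix: ",
            paste(utils::head(missing, 10L), collapse = ", "))
    X <- X[genes, sel$ids, drop = FALSE]
    s <- apply(X, 1L, stats::sd)
    const <- s <= .Machine$double.eps * 100
    if (any(const)) {
        message("dropping constant gene(s): ",
            paste(utils::head(rownames(X)[const], 10L), collapse = ", "))
        X <- X[!const, , drop = FALSE]
    }
    cc <- stats::cor(t(X))
    attr(cc, "sampleSet") <- sel$label
    cc
}

#' Build a signed co-expression network
#'
#' Thresholded relevance network: an edge joins every unordered pair of
#' genes whose Pearson correlation exceeds `threshold` in absolute value
#' (strictly). Genes left without any edge are excluded from the node
#' set. Every gene must carry an up/down call in `de` (the network is
#' defined over differentially expressed genes).
#'
#' @param cc correlation matrix from [correlationMatrix()].
#' @param de a [DEResults-class] covering all `cc` genes with direction
#'   `"up"` or `"down"`.
#' @param threshold |cc| cut in `[0, 1)` (strict `>`).
#' @return a [CoexpressionNetwork-class].
#' @examples
#' # see vignette; networks are usually built from runDE() output
#' @export
buildNetwork <- function(cc, de, threshold = 0.8) {
    stopifnot(is(de, "DEResults"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold >= 1)
        stop("'threshold' must lie in [0, 1)")
    genes <- rownames(cc)
    missing <- setdiff(genes, rownames(de))
    if (length(missing))
        stop("correlation genes absent from the DE table: ",
            paste(utils::head(missing, 10L), collapse = ", "))
    dirs <- stats::setNames(de[genes, "direction"], genes)
    notCalled <- genes[!dirs %in% c("up", "down")]
    if (length(notCalled))
        stop("network genes must be called up or down: ",
            paste(utils::head(notCalled, 10L), collapse = ", "))
    hit <- which(abs(cc) > threshold & upper.tri(cc), arr.ind = TRUE)
    ed <- DataFrame(
        from = genes[hit[, 1L]], to = genes[hit[, 2L]],
        cc = cc[hit], sign = ifelse(cc[hit] > 0, "pos", "neg"))
    deg <- table(factor(c(ed$from, ed$to), levels = genes))
    keep <- genes[deg > 0L]
    nd <- DataFrame(gene = keep,
        direction = unname(dirs[keep]),
        fold_change = de[keep, "fold_change"],
        log2_fc = de[keep, "log2_fc"],
        degree = as.integer(deg[keep]))
    new("CoexpressionNetwork", nodes = nd, edges = ed,
        threshold = threshold,
        sampleSet = attr(cc, "sampleSet") %||% "all")
}

#' Network accessors
#'
#' @param x a [CoexpressionNetwork-class].
#' @return `networkNodes()` / `networkEdges()`: the node / edge
#'   `DFrame`; `networkThreshold()`: the |cc| cut; `nodeDegrees()`: an
#'   integer vector named by gene.
#' @name networkNodes
#' @aliases networkNodes,CoexpressionNetwork-method
#'   networkEdges,CoexpressionNetwork-method
#'   networkThreshold,CoexpressionNetwork-method
#'   nodeDegrees,CoexpressionNetwork-method
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname networkNodes
#' @export
setMethod("networkThreshold", "CoexpressionNetwork", function(x)
    x@threshold)

#' @rdname networkNodes
#' @export
setMethod("nodeDegrees", "CoexpressionNetwork", function(x)
    stats::setNames(as.integer(x@nodes$degree), x@nodes$gene))

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf(
        "CoexpressionNetwork: %d node(s), %d edge(s) at |cc| > %g over '%s' samples\n",
        nrow(object@nodes), nrow(object@edges), object@threshold,
        object@sampleSet))
    if (nrow(object@edges))
        cat(sprintf("  %d positive / %d negative edge(s)\n",
            sum(object@edges$sign == "pos"),
            sum(object@edges$sign == "neg")))
})

#' Rank hub genes by degree
#'
#' The genes with the greatest number of correlated partners, ranked
#' separately among up- and down-regulated nodes. Ties are broken by
#' degree (descending), then |log2 fold change| (descending), then gene
#' id (ascending). When a direction holds fewer than `kPerDirection`
#' nodes, all of them are returned with a warning.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param kPerDirection hubs to report per direction.
#' @return data.frame with columns `gene`, `direction`, `degree`,
#'   `fold_change`, `log2_fc`, ordered within direction.
#' @export
selectHubs <- function(network, kPerDirection = 5L) {
    stopifnot(is(network, "CoexpressionNetwork"))
    nd <- as.data.frame(networkNodes(network))
    if (!nrow(nd)) {
        warning("empty network; no hubs to report")
        return(data.frame(gene = character(), direction = character(),
            degree = integer(), fold_change = numeric(),
            log2_fc = numeric(), stringsAsFactors = FALSE))
    }
    pick <- function(d) {
        sub <- nd[nd$direction == d, , drop = FALSE]
        if (!nrow(sub)) return(sub)
        o <- order(-sub$degree, -abs(sub$log2_fc), sub$gene)
        sub <- sub[o, , drop = FALSE]
        if (nrow(sub) < kPerDirection)
            warning(sprintf(
                "only %d '%s' node(s) available (%d requested)",
                nrow(sub), d, kPerDirection))
        utils::head(sub, kPerDirection)
    }
    out <- rbind(pick("up"), pick("down"))
    rownames(out) <- NULL
    out[, c("gene", "direction", "degree", "fold_change", "log2_fc")]
}

#' Hub neighborhood subnetwork
#'
#' Induced subgraph on the hubs and their direct neighbors: the node
#' set is the hubs plus every gene sharing an edge with a hub, the edge
#' set is every network edge with both endpoints inside that node set.
#' Degrees are recomputed within the subnetwork.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param hubs hub table from [selectHubs()] (or a character vector of
#'   hub genes); all hubs must be network nodes.
#' @return a [CoexpressionNetwork-class].
#' @export
hubNeighborhood <- function(network, hubs) {
    stopifnot(is(network, "CoexpressionNetwork"))
    hubGenes <- if (is.character(hubs)) hubs else hubs$gene
    nd <- networkNodes(network)
    ed <- networkEdges(network)
    missing <- setdiff(hubGenes, nd$gene)
    if (length(missing))
        stop("hub(s) not in the network: ",
            paste(missing, collapse = ", "))
    touch <- ed$from %in% hubGenes | ed$to %in% hubGenes
    keepGenes <- union(hubGenes, union(ed$from[touch], ed$to[touch]))
    keepEdges <- ed[ed$from %in% keepGenes & ed$to %in% keepGenes, ,
        drop = FALSE]
    deg <- table(factor(c(keepEdges$from, keepEdges$to),
        levels = keepGenes))
    sub_nd <- nd[match(keepGenes, nd$gene), , drop = FALSE]
    sub_nd$degree <- as.integer(deg[keepGenes])
    new("CoexpressionNetwork", nodes = sub_nd, edges = keepEdges,
        threshold = network@threshold, sampleSet = network@sampleSet)
}

#' Inter-module correlation classification
#'
#' Summarises each module by its eigengene — the first
#' principal-component score series of the module's per-gene
#' standardized `log2(FPKM + 1)`, sign-fixed to correlate positively
#' with the module's mean profile — then reports, for every module pair
#' (including self-pairs), the eigengene correlation and the mean
#' pairwise gene-gene correlation, classifying the pair `positive` when
#' the eigengene cc exceeds `threshold`, `negative` below
#' `-threshold`, and `none` otherwise.
#'
#' @param cohort a [PairedCohort-class].
#' @param modules a [GeneSetCollection-class]; modules must be disjoint
#'   and hold at least 3 genes each.
#' @param samples `"all"`, `"tumors"` or `"normals"`.
#' @param threshold classification cut on the eigengene cc.
#' @return data.frame with columns `module_a`, `module_b`,
#'   `eigengene_cc`, `mean_pairwise_cc`, `classification`.
#' @export
moduleCorrelation <- function(cohort, modules,
        samples = c("all", "tumors", "normals"), threshold = 0.8) {
    stopifnot(is(cohort, "PairedCohort"), is(modules, "GeneSetCollection"))
    sl <- geneSets(modules)
    small <- names(sl)[lengths(sl) < 3L]
    if (length(small))
        stop("module(s) smaller than 3 genes: ",
            paste(small, collapse = ", "))
    allG <- unlist(sl, use.names = FALSE)
    if (anyDuplicated(allG))
        stop("modules must not overlap")
    sel <- .selectSamples(cohort, samples)
    X <- log2fpkm(cohort)
    missing <- setdiff(allG, rownames(X))
    if (length(missing))
        stop("module gene(s) absent from the matrix: ",
            paste(utils::head(missing, 10L), collapse = ", "))
    X <- X[, sel$ids, drop = FALSE]
    eigengene <- function(genes) {
        M <- X[genes, , drop = FALSE]
        M <- M - rowMeans(M)
        s <- sqrt(rowSums(M^2) / (ncol(M) - 1L))
        keep <- s > .Machine$double.eps * 100
        M <- M[keep, , drop = FALSE] / s[keep]
        pc <- stats::prcomp(t(M), center = FALSE, scale. = FALSE)
        e <- pc$x[, 1L]
        if (stats::cor(e, colMeans(M)) < 0) e <- -e
        e
    }
    eg <- lapply(sl, eigengene)
    nm <- names(sl)
    pairs <- expand.grid(a = seq_along(nm), b = seq_along(nm))
    pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
    res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        a <- pairs$a[i]; b <- pairs$b[i]
        ecc <- stats::cor(eg[[a]], eg[[b]])
        mcc <- if (a == b) {
            C <- stats::cor(t(X[sl[[a]], , drop = FALSE]))
            mean(C[upper.tri(C)])
        } else {
            mean(stats::cor(t(X[sl[[a]], , drop = FALSE]),
                t(X[sl[[b]], , drop = FALSE])))
        }
        data.frame(module_a = nm[a], module_b = nm[b],
            eigengene_cc = ecc, mean_pairwise_cc = mcc,
            classification = if (ecc > threshold) "positive"
                else if (ecc < -threshold) "negative" else "none",
            stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    res
}
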