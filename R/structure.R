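.panelMatrix <- function(cohort, genePanel, standardize = TRUE) {
    X <- log2fpkm(cohort)
    missing <- setdiff(genePanel, rownames(X))
    if (length(missing))
        stop("panel gene(s) absent from the matrix: ",
            paste(utils::head(missing, 10L), collapse = ", "),
            if (length(missing) > 10L) ", ...")
    X <- X[genePanel, , drop = FALSE]
    Xc <- X - rowMeans(X)
    if (!standardize) return(Xc)
    s <- sqrt(rowSums(Xc^2) / (ncol(Xc) - 1L))
    const <- s <= .Machine$double.eps * 100
    if (any(const)) {
        # constant genes carry no clustering information; drop, don't 0/0
        Xc <- Xc[!const, , drop = FALSE]
        s <- s[!const]
        if (!nrow(Xc)) return(Xc)
    }
    Xc / s
}

#' Hierarchical clustering of samples over a gene panel
#'
#' Agglomerative clustering of samples on per-gene standardized
#' `log2(FPKM + 1)` (z-scores), Euclidean distance and average linkage
#' by default, cut at k = 2. Each cluster is labelled with its majority
#' condition (ties broken toward the condition of the earliest sample in
#' input order); each sample is flagged concordant when its own
#' condition matches its cluster's majority. A degenerate cut (all
#' merge heights zero, or both clusters sharing one majority label) is
#' flagged rather than interpreted.
#'
#' @param cohort a [PairedCohort-class] with >= 2 samples.
#' @param genePanel character vector of genes (must all be present).
#' @param distance distance measure passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with elements `hclust` (the tree), `assignment`
#'   (data.frame: `sample_id`, `cluster`, `majority_condition`,
#'   `concordant`) and `degenerate` (logical).
#' @export
hcaSamples <- function(cohort, genePanel, distance = "euclidean",
        linkage = "average") {
    stopifnot(is(cohort, "PairedCohort"))
    if (ncol(cohort) < 2L) stop("need at least 2 samples")
    Z <- .panelMatrix(cohort, genePanel)
    cond <- sampleCondition(cohort)
    if (!nrow(Z)) {
        # every panel gene constant across samples: nothing to cluster on
        warning("all panel genes are constant; degenerate single cluster")
        tab <- table(cond)
        maj <- names(tab)[which.max(tab)]
        assignment <- data.frame(sample_id = colnames(cohort),
            cluster = 1L, majority_condition = maj,
            concordant = unname(cond) == maj, stringsAsFactors = FALSE)
        return(list(hclust = NULL, assignment = assignment,
            degenerate = TRUE))
    }
    d <- stats::dist(t(Z), method = distance)
    hc <- stats::hclust(d, method = linkage)
    cl <- stats::cutree(hc, k = 2L)
    majority <- vapply(1:2, function(k) {
        members <- names(cl)[cl == k]
        tab <- table(cond[members])
        top <- names(tab)[tab == max(tab)]
        if (length(top) == 1L) top else unname(cond[members[1L]])
    }, "")
    assignment <- data.frame(sample_id = names(cl),
        cluster = unname(cl),
        majority_condition = majority[cl],
        concordant = unname(cond[names(cl)]) == majority[cl],
        stringsAsFactors = FALSE)
    degenerate <- max(hc$height) <= .Machine$double.eps * 100 ||
        majority[1L] == majority[2L] || length(unique(cl)) < 2L
    list(hclust = hc, assignment = assignment, degenerate = degenerate)
}

#' Principal component analysis of samples over a gene panel
#'
#' PCA of samples on per-gene centered (optionally standardized)
#' `log2(FPKM + 1)`. Each component's sign is fixed so that its
#' largest-magnitude gene loading is positive, making scores
#' reproducible across linear-algebra backends.
#'
#' @param cohort a [PairedCohort-class].
#' @param genePanel character vector of genes.
#' @param nComponents number of leading components (must not exceed
#'   `min(#genes, #samples)`).
#' @param scale standardize genes to unit variance (default `TRUE`).
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components) and `varExplained` (fractions, non-increasing).
#' @export
pcaSamples <- function(cohort, genePanel, nComponents = 2L, scale = TRUE) {
    stopifnot(is(cohort, "PairedCohort"))
    Z <- .panelMatrix(cohort, genePanel, standardize = scale)
    if (!nrow(Z)) stop("no usable panel genes")
    if (nComponents > min(nrow(Z), ncol(Z)))
        stop(sprintf("nComponents (%d) exceeds min(genes, samples) = %d",
            nComponents, min(nrow(Z), ncol(Z))))
    pc <- stats::prcomp(t(Z), center = TRUE, scale. = FALSE)
    k <- nComponents
    scores <- pc$x[, seq_len(k), drop = FALSE]
    loadings <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    varExplained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    list(scores = scores, loadings = loadings,
        varExplained = varExplained)
}

#' Per-condition dispersion in principal-component space
#'
#' Mean Euclidean distance of each condition's samples to the condition
#' centroid in score space — a scalar heterogeneity measure allowing
#' tumor-versus-normal spread comparisons.
#'
#' @param pca result of [pcaSamples()].
#' @param cohort the [PairedCohort-class] the scores came from.
#' @return named numeric vector, one dispersion per condition.
#' @export
groupDispersion <- function(pca, cohort) {
    stopifnot(is(cohort, "PairedCohort"))
    cond <- sampleCondition(cohort)[rownames(pca$scores)]
    vapply(split(rownames(pca$scores), cond), function(ids) {
        if (length(ids) < 2L)
            stop("each condition needs >= 2 samples for a dispersion")
        S <- pca$scores[ids, , drop = FALSE]
        ctr <- colMeans(S)
        mean(sqrt(rowSums((S - rep(ctr, each = nrow(S)))^2)))
    }, 0)
}

#' Histology-versus-cluster discordance report
#'
#' From a two-group cut, lists every sample whose condition disagrees
#' with its cluster's majority: tumors clustering with the normals
#' (annotated with their own stage class) and normals clustering with
#' the tumors (annotated with the stage class of their adjacent tumor).
#' A degenerate cut is propagated as a flag with empty lists rather than
#' fabricated discordance.
#'
#' @param hca result of [hcaSamples()].
#' @param cohort the [PairedCohort-class] clustered.
#' @param panelName label recorded in the report.
#' @return list with `panel`, `degenerate`,
#'   `tumors_clustering_with_normals` and
#'   `normals_clustering_with_tumors` (each a data.frame `sample_id`,
#'   `stage_class`).
#' @export
discordanceReport <- function(hca, cohort, panelName = "panel") {
    stopifnot(is(cohort, "PairedCohort"))
    empty <- data.frame(sample_id = character(),
        stage_class = character(), stringsAsFactors = FALSE)
    if (isTRUE(hca$degenerate))
        return(list(panel = panelName, degenerate = TRUE,
            tumors_clustering_with_normals = empty,
            normals_clustering_with_tumors = empty))
    a <- hca$assignment
    cond <- sampleCondition(cohort)
    own <- stageClass(cohort)
    adj <- adjacentTumorStage(cohort)
    disc <- a[!a$concordant, , drop = FALSE]
    tum <- disc$sample_id[cond[disc$sample_id] == "tumor"]
    nor <- disc$sample_id[cond[disc$sample_id] == "normal"]
    list(panel = panelName, degenerate = FALSE,
        tumors_clustering_with_normals = data.frame(
            sample_id = tum, stage_class = unname(own[tum]),
            stringsAsFactors = FALSE),
        normals_clustering_with_tumors = data.frame(
            sample_id = nor, stage_class = unname(adj[nor]),
            stringsAsFactors = FALSE))
}
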