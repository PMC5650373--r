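#' Filter genes by mean abundance
#'
#' Retains genes whose mean FPKM across all samples is strictly greater
#' than `threshold` (default 1), the conventional reliability cut for
#' FPKM quantitation. Gene order is preserved.
#'
#' @param x a [PairedCohort-class] or a numeric gene x sample matrix.
#' @param threshold non-negative mean-FPKM cut (strict `>`).
#' @return an object of the same class as `x`, genes subset.
#' @export
filterByAbundance <- function(x, threshold = 1) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        stop("'threshold' must be a single non-negative number")
    m <- if (is(x, "PairedCohort")) fpkm(x) else x
    if (!nrow(m)) stop("expression matrix is empty")
    keep <- rowMeans(m) > threshold
    x[keep, , drop = FALSE]
}

#' Per-gene paired ANOVA p-values
#'
#' For every gene, fits the two-factor blocked model (condition +
#' subject) on `log2(FPKM + 1)` and returns the F-test p-value for the
#' condition effect. With two conditions this F statistic equals the
#' squared paired-t statistic, so the test is computed as a vectorised
#' paired t-test on within-pair differences. A gene whose within-pair
#' differences have zero variance gets `p = 1` and is flagged (attribute
#' `"zero_variance"`) rather than raising an error. An unpaired one-way
#' option (`paired = FALSE`, equal-variance two-sample F) is provided
#' for sensitivity analysis.
#'
#' @param cohort a [PairedCohort-class] with complete pairing and at
#'   least 2 pairs.
#' @param paired logical; blocked (paired) model or one-way.
#' @return named numeric vector of p-values (attribute `zero_variance`:
#'   logical vector of flagged genes).
#' @export
pairedAnovaP <- function(cohort, paired = TRUE) {
    stopifnot(is(cohort, "PairedCohort"))
    X <- log2fpkm(cohort)
    cond <- sampleCondition(cohort)
    if (paired) {
        subj <- subjectIds(cohort)
        tumorCols <- names(cond)[cond == "tumor"]
        normalCols <- names(cond)[cond == "normal"]
        normalBySubj <- stats::setNames(normalCols, subj[normalCols])
        mates <- normalBySubj[subj[tumorCols]]
        if (anyNA(mates)) stop("pairing is incomplete")
        n <- length(tumorCols)
        if (n < 2L) stop("paired ANOVA needs at least 2 pairs")
        D <- X[, tumorCols, drop = FALSE] - X[, mates, drop = FALSE]
        m <- rowMeans(D)
        s2 <- rowSums((D - m)^2) / (n - 1L)
        zero <- s2 <= .Machine$double.eps * 100
        Fstat <- ifelse(zero, NA_real_, n * m^2 / s2)
        p <- ifelse(zero, 1, stats::pf(Fstat, 1, n - 1L,
            lower.tail = FALSE))
        if (any(zero))
            message(sum(zero),
                " gene(s) with zero within-pair variance; p set to 1")
        attr(p, "zero_variance") <- unname(zero)
        names(p) <- rownames(X)
        p
    } else {
        tI <- cond == "tumor"; nI <- cond == "normal"
        n1 <- sum(tI); n2 <- sum(nI)
        if (n1 < 2L || n2 < 2L)
            stop("one-way ANOVA needs >= 2 samples per condition")
        m1 <- rowMeans(X[, tI, drop = FALSE])
        m2 <- rowMeans(X[, nI, drop = FALSE])
        v1 <- rowSums((X[, tI, drop = FALSE] - m1)^2)
        v2 <- rowSums((X[, nI, drop = FALSE] - m2)^2)
        s2 <- (v1 + v2) / (n1 + n2 - 2L)
        zero <- s2 <= .Machine$double.eps * 100
        Fstat <- ifelse(zero, NA_real_,
            (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2)))
        p <- ifelse(zero, 1, stats::pf(Fstat, 1, n1 + n2 - 2L,
            lower.tail = FALSE))
        if (any(zero))
            message(sum(zero),
                " gene(s) with zero residual variance; p set to 1")
        attr(p, "zero_variance") <- unname(zero)
        names(p) <- rownames(X)
        p
    }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (p_(j) m / j)`, capped at 1
#' and mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")` after validating the input).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values in input order.
#' @export
bhFDR <- function(p) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must be finite numbers in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Linear tumor/normal fold change
#'
#' `(mean_T + eps) / (mean_N + eps)` per gene on the linear FPKM scale
#' (the reporting convention for ratios like a 231-fold increase), with
#' pseudocount `eps` guarding against zero normal means. By request the
#' geometric mean of per-pair ratios is computed instead.
#'
#' @param cohort a [PairedCohort-class] with both conditions present.
#' @param eps pseudocount on the FPKM scale.
#' @param method `"ratio_of_means"` (default) or `"per_pair_geomean"`.
#' @return data.frame with columns `mean_T`, `mean_N`, `fold_change`,
#'   `log2_fc`, rownames = gene ids.
#' @export
foldChange <- function(cohort, eps = 1e-3,
        method = c("ratio_of_means", "per_pair_geomean")) {
    stopifnot(is(cohort, "PairedCohort"))
    method <- match.arg(method)
    m <- fpkm(cohort)
    cond <- sampleCondition(cohort)
    if (!all(c("tumor", "normal") %in% cond))
        stop("both conditions must be present")
    meanT <- rowMeans(m[, cond == "tumor", drop = FALSE])
    meanN <- rowMeans(m[, cond == "normal", drop = FALSE])
    if (method == "ratio_of_means") {
        fc <- (meanT + eps) / (meanN + eps)
    } else {
        subj <- subjectIds(cohort)
        tumorCols <- names(cond)[cond == "tumor"]
        normalBySubj <- stats::setNames(names(cond)[cond == "normal"],
            subj[cond == "normal"])
        mates <- normalBySubj[subj[tumorCols]]
        lr <- log2(m[, tumorCols, drop = FALSE] + eps) -
            log2(m[, mates, drop = FALSE] + eps)
        fc <- 2^rowMeans(lr)
    }
    data.frame(mean_T = meanT, mean_N = meanN, fold_change = fc,
        log2_fc = log2(fc), row.names = rownames(m))
}

#' Run the differential-expression cascade
#'
#' Abundance filter (mean FPKM strictly > `minFPKM`), paired ANOVA on
#' `log2(FPKM + 1)`, Benjamini-Hochberg correction, linear fold change,
#' and the two-criterion call: `up` requires `fold_change >
#' fcThreshold` (strict) and `q <= fdrThreshold` (inclusive); `down`
#' requires `1/fold_change > fcThreshold` and the same FDR cut.
#'
#' @param cohort a [PairedCohort-class].
#' @param minFPKM abundance filter threshold.
#' @param fcThreshold linear fold-change criterion (strict `>`).
#' @param fdrThreshold FDR criterion (inclusive `<=`).
#' @param eps fold-change pseudocount.
#' @param paired use the blocked (paired) test; see [pairedAnovaP()].
#' @param foldMethod see [foldChange()].
#' @return a [DEResults-class]; `metadata()` carries the thresholds and
#'   the gene funnel (`n_input`, `n_abundant`, `n_up`, `n_down`).
#' @examples
#' gen <- generateCohort(simulationConfig(nPairs = 8, nGenes = 100,
#'     nModules = 0, hubSpec = data.frame(), seed = 3))
#' de <- runDE(gen$cohort)
#' head(as.data.frame(de))
#' @export
runDE <- function(cohort, minFPKM = 1, fcThreshold = 2,
        fdrThreshold = 0.05, eps = 1e-3, paired = TRUE,
        foldMethod = c("ratio_of_means", "per_pair_geomean")) {
    stopifnot(is(cohort, "PairedCohort"))
    foldMethod <- match.arg(foldMethod)
    n_input <- nrow(cohort)
    filtered <- filterByAbundance(cohort, minFPKM)
    p <- pairedAnovaP(filtered, paired = paired)
    q <- bhFDR(as.numeric(p))
    fcTab <- foldChange(filtered, eps = eps, method = foldMethod)
    up <- fcTab$fold_change > fcThreshold & q <= fdrThreshold
    down <- (1 / fcTab$fold_change) > fcThreshold & q <= fdrThreshold
    direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
    res <- DataFrame(mean_T = fcTab$mean_T, mean_N = fcTab$mean_N,
        fold_change = fcTab$fold_change, log2_fc = fcTab$log2_fc,
        p_value = as.numeric(p), q_value = q, direction = direction,
        row.names = rownames(filtered))
    out <- new("DEResults", res)
    S4Vectors::metadata(out) <- list(minFPKM = minFPKM,
        fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
        eps = eps, paired = paired, foldMethod = foldMethod,
        n_input = n_input, n_abundant = nrow(filtered),
        n_up = sum(up), n_down = sum(down))
    out
}

#' Partition called genes into up/down sets
#'
#' @param de a [DEResults-class].
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
callDEGs <- function(de) {
    stopifnot(is(de, "DEResults"))
    list(up = rownames(de)[de$direction == "up"],
         down = rownames(de)[de$direction == "down"])
}

#' Volcano-plot coordinates
#'
#' Deterministic `(log2 fold change, -log10 p)` coordinates per gene;
#' `p = 0` is floored at the smallest positive double before the log so
#' coordinates stay finite. Non-significant genes carry direction
#' `"ns"` for plotting layers.
#'
#' @param de a [DEResults-class].
#' @return data.frame with columns `gene`, `log2_fc`, `neg_log10_p`,
#'   `direction`.
#' @export
volcanoTable <- function(de) {
    stopifnot(is(de, "DEResults"))
    p <- pmax(de$p_value, .Machine$double.xmin)
    data.frame(gene = rownames(de), log2_fc = de$log2_fc,
        neg_log10_p = -log10(p), direction = de$direction)
}

setMethod("show", "DEResults", function(object) {
    md <- S4Vectors::metadata(object)
    cat(sprintf(
        "DEResults: %d gene(s); %d up / %d down at fold > %s, FDR <= %s\n",
        nrow(object), sum(object$direction == "up"),
        sum(object$direction == "down"), md$fcThreshold %||% "?",
        md$fdrThreshold %||% "?"))
    callNextMethod()
})

#' Write / read a differential-expression results table
#'
#' TSV with columns `gene`, `mean_T`, `mean_N`, `fold_change`,
#' `log2_fc`, `p_value`, `q_value`, `direction`; numerics are formatted
#' with 6 significant-decimal fixed notation except p/q which keep full
#' precision in scientific notation.
#'
#' @param de a [DEResults-class].
#' @param path file path.
#' @export
writeDETable <- function(de, path) {
    stopifnot(is(de, "DEResults"))
    out <- data.frame(gene = rownames(de),
        mean_T = sprintf("%.6f", de$mean_T),
        mean_N = sprintf("%.6f", de$mean_N),
        fold_change = sprintf("%.6f", de$fold_change),
        log2_fc = sprintf("%.6f", de$log2_fc),
        p_value = sprintf("%.6e", de$p_value),
        q_value = sprintf("%.6e", de$q_value),
        direction = de$direction)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE)
    res <- DataFrame(tab[, setdiff(colnames(tab), "gene")],
        row.names = tab$gene)
    new("DEResults", res)
}
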