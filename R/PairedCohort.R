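#' Construct a paired tumor/normal FPKM cohort
#'
#' Bundles a validated FPKM matrix with per-sample metadata into a
#' [PairedCohort-class] (a `SummarizedExperiment`). Validation is total:
#' either every invariant holds (unique ids, finite non-negative values,
#' condition levels, stage consistency, pairing completeness when
#' `paired = TRUE`) or construction fails with a located error.
#'
#' @param fpkm numeric matrix of non-negative FPKM values, genes as rows
#'   (rownames = gene ids), samples as columns (colnames = sample ids).
#' @param metadata `data.frame` or `DataFrame` with one row per sample;
#'   required columns `sample_id`, `subject_id`, `condition`
#'   (`"tumor"`/`"normal"`); optional `stage_numeric` (1-4),
#'   `stage_class` (`"low"`/`"high"`), `grade`
#'   (`"well"`/`"moderate"`/`"poor"`). Rows are matched to matrix columns
#'   by `sample_id`.
#' @param paired logical; when `TRUE` (default) every subject must have
#'   exactly one tumor and one normal sample.
#' @return A `PairedCohort` object.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'     dimnames = list(paste0("g", 1:3), c("T1", "N1", "T2", "N2")))
#' md <- data.frame(sample_id = colnames(m),
#'     subject_id = c("S1", "S1", "S2", "S2"),
#'     condition = c("tumor", "normal", "tumor", "normal"))
#' PairedCohort(m, md)
#' @export
PairedCohort <- function(fpkm, metadata, paired = TRUE) {
    if (!is.matrix(fpkm) || !is.numeric(fpkm))
        stop("'fpkm' must be a numeric matrix")
    if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
        stop("'fpkm' must carry gene rownames and sample colnames")
    .checkUniqueIds(rownames(fpkm), "gene")
    .checkUniqueIds(colnames(fpkm), "sample")
    .checkFiniteNonNegative(fpkm)
    md <- .validateMetadata(as.data.frame(metadata), paired = paired)
    if (!setequal(md$sample_id, colnames(fpkm)))
        stop("metadata sample_id set must match the matrix sample columns")
    md <- md[match(colnames(fpkm), md$sample_id), , drop = FALSE]
    cd <- DataFrame(md, row.names = md$sample_id)
    se <- SummarizedExperiment(assays = SimpleList(fpkm = fpkm),
        colData = cd)
    obj <- new("PairedCohort", se)
    S4Vectors::metadata(obj)$paired <- isTRUE(paired)
    validObject(obj)
    obj
}

setValidity("PairedCohort", function(object) {
    if (!"fpkm" %in% assayNames(object))
        return("a 'fpkm' assay is required")
    m <- assay(object, "fpkm")
    if (any(!is.finite(m))) return("FPKM values must be finite")
    if (any(m < 0)) return("FPKM values must be non-negative")
    if (anyDuplicated(rownames(object))) return("duplicate gene ids")
    if (anyDuplicated(colnames(object))) return("duplicate sample ids")
    cd <- colData(object)
    need <- c("sample_id", "subject_id", "condition")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain:", paste(need, collapse = ", ")))
    if (!all(cd$condition %in% c("tumor", "normal")))
        return("condition must be 'tumor' or 'normal'")
    if (isTRUE(S4Vectors::metadata(object)$paired)) {
        bad <- .pairingProblems(as.data.frame(cd))
        if (length(bad))
            return(paste0("incomplete tumor/normal pairing for subject(s): ",
                paste(bad, collapse = ", ")))
    }
    TRUE
})

.checkUniqueIds <- function(ids, what) {
    d <- unique(ids[duplicated(ids)])
    if (length(d))
        stop(sprintf("duplicate %s id(s): %s", what,
            paste(d, collapse = ", ")))
    invisible(TRUE)
}

.checkFiniteNonNegative <- function(m) {
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad)) {
        i <- bad[1L, ]
        stop(sprintf(
            "non-finite or negative expression value at gene '%s', sample '%s'",
            rownames(m)[i[1L]], colnames(m)[i[2L]]))
    }
    invisible(TRUE)
}

.pairingProblems <- function(md) {
    split_cond <- split(md$condition, md$subject_id)
    names(split_cond)[!vapply(split_cond, function(x)
        sum(x == "tumor") == 1L && sum(x == "normal") == 1L, TRUE)]
}

.validateMetadata <- function(md, paired = TRUE) {
    need <- c("sample_id", "subject_id", "condition")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks required column(s): ",
            paste(miss, collapse = ", "))
    md$sample_id <- as.character(md$sample_id)
    md$subject_id <- as.character(md$subject_id)
    md$condition <- as.character(md$condition)
    .checkUniqueIds(md$sample_id, "sample")
    bad <- setdiff(unique(md$condition), c("tumor", "normal"))
    if (length(bad))
        stop("unknown condition level(s): ", paste(bad, collapse = ", "))
    if ("stage_numeric" %in% colnames(md)) {
        sn <- md$stage_numeric
        ok <- is.na(sn) | (sn %in% 1:4)
        if (!all(ok))
            stop("stage_numeric must be in 1..4 or NA (offending sample(s): ",
                paste(md$sample_id[!ok], collapse = ", "), ")")
        derived <- ifelse(is.na(sn), NA_character_,
            ifelse(sn <= 2, "low", "high"))
        if ("stage_class" %in% colnames(md)) {
            sc <- as.character(md$stage_class)
            conflict <- !is.na(derived) & !is.na(sc) & sc != derived
            if (any(conflict))
                stop("stage_class inconsistent with stage_numeric for: ",
                    paste(md$sample_id[conflict], collapse = ", "))
            md$stage_class <- ifelse(is.na(sc), derived, sc)
        } else md$stage_class <- derived
    }
    if ("stage_class" %in% colnames(md)) {
        sc <- md$stage_class
        bad <- !is.na(sc) & !sc %in% c("low", "high")
        if (any(bad))
            stop("stage_class must be 'low' or 'high' (offending sample(s): ",
                paste(md$sample_id[bad], collapse = ", "), ")")
    }
    if ("grade" %in% colnames(md)) {
        g <- md$grade
        bad <- !is.na(g) & !g %in% c("well", "moderate", "poor")
        if (any(bad))
            stop("grade must be well/moderate/poor (offending sample(s): ",
                paste(md$sample_id[bad], collapse = ", "), ")")
    }
    if (isTRUE(paired)) {
        bad <- .pairingProblems(md)
        if (length(bad))
            stop("incomplete tumor/normal pairing for subject(s): ",
                paste(bad, collapse = ", "))
    }
    md
}

#' Assay and metadata accessors for a paired cohort
#'
#' `fpkm()` returns the FPKM matrix; `log2fpkm()` returns
#' `log2(FPKM + 1)`, the scale every statistical stage (paired ANOVA,
#' clustering, PCA, Pearson correlation) operates on.
#'
#' @param x a [PairedCohort-class].
#' @return a numeric gene x sample matrix.
#' @name fpkm
#' @aliases fpkm,PairedCohort-method log2fpkm,PairedCohort-method
#' @export
setMethod("fpkm", "PairedCohort", function(x) assay(x, "fpkm"))

#' @rdname fpkm
#' @export
setMethod("log2fpkm", "PairedCohort", function(x) log2(assay(x, "fpkm") + 1))

#' Per-sample design accessors
#'
#' `sampleCondition()` returns the tumor/normal label per sample,
#' `subjectIds()` the pair key, `stageClass()` the low/high stage class
#' (NA where unrecorded, e.g. normal samples).
#'
#' @param x a [PairedCohort-class].
#' @return a character vector named by sample id.
#' @name sampleCondition
#' @aliases sampleCondition,PairedCohort-method subjectIds,PairedCohort-method
#'   stageClass,PairedCohort-method
#' @export
setMethod("sampleCondition", "PairedCohort", function(x)
    stats::setNames(colData(x)$condition, colnames(x)))

#' @rdname sampleCondition
#' @export
setMethod("subjectIds", "PairedCohort", function(x)
    stats::setNames(colData(x)$subject_id, colnames(x)))

#' @rdname sampleCondition
#' @export
setMethod("stageClass", "PairedCohort", function(x) {
    cd <- colData(x)
    sc <- if ("stage_class" %in% colnames(cd)) as.character(cd$stage_class)
        else rep(NA_character_, ncol(x))
    stats::setNames(sc, colnames(x))
})

#' Stage class of the tumor adjacent to each sample
#'
#' For every sample, the stage class recorded for the tumor of the same
#' subject — for a normal sample this is the stage of its adjacent tumor,
#' the annotation used when reporting normals that cluster with tumors.
#'
#' @param x a [PairedCohort-class].
#' @return character vector named by sample id.
#' @export
adjacentTumorStage <- function(x) {
    stopifnot(is(x, "PairedCohort"))
    cd <- as.data.frame(colData(x))
    sc <- stageClass(x)
    tum <- cd$condition == "tumor"
    bySubject <- stats::setNames(sc[tum], cd$subject_id[tum])
    stats::setNames(unname(bySubject[cd$subject_id]), colnames(x))
}

setMethod("show", "PairedCohort", function(object) {
    cd <- colData(object)
    n_t <- sum(cd$condition == "tumor")
    n_n <- sum(cd$condition == "normal")
    cat(sprintf("PairedCohort: %d genes x %d samples (%d tumor / %d normal, %d subjects)\n",
        nrow(object), ncol(object), n_t, n_n,
        length(unique(cd$subject_id))))
    callNextMethod()
})
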