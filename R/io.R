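#' Read a gene x sample expression table
#'
#' Reads a TSV (default) or CSV matrix with one header row of sample ids
#' and gene ids in the first column, validating as it goes: duplicate
#' gene or sample ids, non-numeric cells, blank cells and negative
#' values are hard errors naming the offending coordinates. Input
#' ordering of genes and samples is preserved.
#'
#' @param path file path.
#' @param dialect `"tsv"` (canonical) or `"csv"`.
#' @return numeric matrix, genes as rows, samples as columns.
#' @seealso [writeExpressionTable()], [PairedCohort()]
#' @export
readExpressionTable <- function(path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "tsv") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
        check.names = FALSE, stringsAsFactors = FALSE, quote = "",
        comment.char = "", colClasses = "character")
    if (ncol(tab) < 2L)
        stop("expression table needs a gene-id column plus >= 1 sample")
    genes <- tab[[1L]]
    samples <- colnames(tab)[-1L]
    .checkUniqueIds(genes, "gene")
    .checkUniqueIds(samples, "sample")
    vals <- matrix(NA_real_, nrow(tab), length(samples),
        dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        raw <- tab[[j + 1L]]
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(num) | !nzchar(trimws(raw)))
        if (length(bad))
            stop(sprintf(
                "non-numeric or blank expression cell at gene '%s', sample '%s'",
                genes[bad[1L]], samples[j]))
        vals[, j] <- num
    }
    .checkFiniteNonNegative(vals)
    vals
}

#' Write a gene x sample expression table
#'
#' Values are written with 17 significant digits so that
#' `readExpressionTable(writeExpressionTable(x))` is bit-identical.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(mat, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "tsv") "\t" else ","
    out <- cbind(gene = rownames(mat),
        formatC(mat, format = "g", digits = 17))
    utils::write.table(out, path, sep = sep, quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read and validate a sample metadata table
#'
#' TSV with required columns `sample_id`, `subject_id`, `condition`
#' (tumor/normal) and optional `stage_numeric`, `stage_class`, `grade`.
#' `stage_class` is derived from `stage_numeric` (stages 1-2 low, 3-4
#' high) when absent and checked for consistency when present. Under
#' `paired = TRUE` a subject with two tumors or a missing normal is a
#' hard error naming the subject.
#'
#' @param path file path.
#' @param paired logical; enforce one tumor + one normal per subject.
#' @return a `data.frame`, one row per sample.
#' @export
readSampleMetadata <- function(path, paired = TRUE) {
    md <- utils::read.table(path, header = TRUE, sep = "\t",
        check.names = FALSE, stringsAsFactors = FALSE, quote = "",
        comment.char = "")
    .validateMetadata(md, paired = paired)
}

#' @rdname readSampleMetadata
#' @param md metadata `data.frame`.
#' @export
writeSampleMetadata <- function(md, path) {
    utils::write.table(as.data.frame(md), path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a set
#' are deduplicated with a warning; a line without any member is an
#' error reporting the line number.
#'
#' @param path file path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list(); descs <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        members <- if (length(f) > 2L) f[-(1:2)] else character()
        members <- members[nzchar(members)]
        if (!length(members) || !nzchar(f[1L]))
            stop(sprintf("GMT line %d: set '%s' has no members", i,
                if (length(f)) f[1L] else ""))
        if (anyDuplicated(members)) {
            warning(sprintf("GMT set '%s': %d duplicate member(s) removed",
                f[1L], sum(duplicated(members))))
            members <- unique(members)
        }
        sets[[f[1L]]] <- members
        descs[f[1L]] <- f[2L]
    }
    if (anyDuplicated(names(sets)))
        stop("duplicate set names in GMT file")
    GeneSetCollection(sets, descs)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' Write a gene-set collection as GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "GeneSetCollection"))
    lines <- vapply(names(geneSets(x)), function(nm)
        paste(c(nm, setDescriptions(x)[[nm]], geneSets(x)[[nm]]),
            collapse = "\t"), "")
    # an empty description field must still occupy its column
    writeLines(lines, path)
    invisible(path)
}

#' Gene-set collection accessors
#'
#' @param x a [GeneSetCollection-class].
#' @return `geneSets()`: the named list of member vectors;
#'   `setDescriptions()`: the named description vector.
#' @name geneSets
#' @aliases geneSets,GeneSetCollection-method
#'   setDescriptions,GeneSetCollection-method
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname geneSets
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
    if (length(object@sets)) {
        n <- utils::head(names(object@sets), 5L)
        for (nm in n)
            cat(sprintf("  %s (%d genes)\n", nm, length(object@sets[[nm]])))
        if (length(object@sets) > 5L) cat("  ...\n")
    }
})

#' Export a co-expression network to standard graph formats
#'
#' `tsv_edge_list` writes `source`, `target`, `cc` (6 decimals), `sign`;
#' `sif` writes Cytoscape simple-interaction lines with `pos`/`neg`
#' interaction labels; `graphml` writes a GraphML document (via igraph)
#' carrying node `direction`/`degree` and edge `cc`/`sign` attributes.
#' An optional node table (gene, direction, fold change, degree) can be
#' written alongside.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path output file path.
#' @param format one of `"tsv_edge_list"`, `"sif"`, `"graphml"`.
#' @param nodePath optional path for a TSV node table.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path,
        format = c("tsv_edge_list", "sif", "graphml"), nodePath = NULL) {
    stopifnot(is(network, "CoexpressionNetwork"))
    format <- tryCatch(match.arg(format), error = function(e)
        stop("unknown network format; supported: tsv_edge_list, sif, graphml"))
    ed <- as.data.frame(networkEdges(network))
    nd <- as.data.frame(networkNodes(network))
    if (format == "tsv_edge_list") {
        out <- data.frame(source = ed$from, target = ed$to,
            cc = sprintf("%.6f", ed$cc), sign = ed$sign)
        if (!nrow(ed)) out <- out[0L, , drop = FALSE]
        utils::write.table(out, path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = TRUE)
    } else if (format == "sif") {
        lines <- if (nrow(ed))
            sprintf("%s\t%s\t%s", ed$from, ed$sign, ed$to) else character()
        writeLines(lines, path)
    } else {
        g <- asIgraph(network)
        igraph::write_graph(g, path, format = "graphml")
    }
    if (!is.null(nodePath)) {
        out <- data.frame(gene = nd$gene, direction = nd$direction,
            fold_change = sprintf("%.6f", nd$fold_change),
            log2_fc = sprintf("%.6f", nd$log2_fc), degree = nd$degree)
        utils::write.table(out, nodePath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = TRUE)
    }
    invisible(path)
}

#' Convert a co-expression network to an igraph object
#'
#' @param network a [CoexpressionNetwork-class].
#' @return an undirected `igraph` graph with node attributes `direction`
#'   and `degree` and edge attributes `cc` and `sign`.
#' @export
asIgraph <- function(network) {
    stopifnot(is(network, "CoexpressionNetwork"))
    nd <- as.data.frame(networkNodes(network))
    ed <- as.data.frame(networkEdges(network))
    igraph::graph_from_data_frame(
        d = ed[, c("from", "to", "cc", "sign")],
        directed = FALSE,
        vertices = data.frame(name = nd$gene, direction = nd$direction,
            degree = nd$degree))
}
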