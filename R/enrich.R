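#' Hypergeometric over-representation of a gene set collection
#'
#' One-sided over-representation test for each set: with universe size
#' `N`, set size in the universe `K`, query size `n` and overlap `k`,
#' the p-value is the hypergeometric upper tail `P[X >= k]`. BH
#' correction is applied across all tested sets; a set is enriched when
#' `q < fdrThreshold` (strict). Sets are intersected with the universe
#' first; sets with empty intersection are dropped with a message. The
#' query must be a subset of the universe.
#'
#' @param query character vector of genes of interest (e.g. one DEG
#'   direction).
#' @param universe character vector defining the background (typically
#'   the abundance-filtered genes).
#' @param sets a [GeneSetCollection-class].
#' @param fdrThreshold enrichment call cut on q (strict `<`).
#' @return data.frame with one row per tested set, columns `set_name`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `q_value`, `enriched`, sorted by q, then p, then name.
#' @export
enrichGeneSets <- function(query, universe, sets, fdrThreshold = 0.05) {
    stopifnot(is(sets, "GeneSetCollection"))
    query <- unique(as.character(query))
    universe <- unique(as.character(universe))
    off <- setdiff(query, universe)
    if (length(off))
        stop("query gene(s) outside the universe: ",
            paste(utils::head(off, 10L), collapse = ", "),
            if (length(off) > 10L) ", ...")
    sl <- lapply(geneSets(sets), intersect, universe)
    dropped <- sum(lengths(sl) == 0L)
    if (dropped)
        message(dropped, " set(s) with empty universe intersection dropped")
    sl <- sl[lengths(sl) > 0L]
    N <- length(universe); n <- length(query)
    rows <- lapply(names(sl), function(nm) {
        K <- length(sl[[nm]])
        k <- length(intersect(sl[[nm]], query))
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(set_name = nm, overlap = k, set_size = K,
            query_size = n, universe_size = N, p_value = p,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(set_name = character(), overlap = integer(),
            set_size = integer(), query_size = integer(),
            universe_size = integer(), p_value = numeric(),
            stringsAsFactors = FALSE)
    out$q_value <- if (nrow(out)) bhFDR(out$p_value) else numeric()
    out$enriched <- out$q_value < fdrThreshold
    out[order(out$q_value, out$p_value, out$set_name), , drop = FALSE]
}

#' Direction-split enrichment of DE results
#'
#' Runs [enrichGeneSets()] separately on the up- and down-regulated
#' gene sets against the abundance-filtered universe (all tested genes
#' in `de`). An empty DEG direction yields an empty table with a
#' warning.
#'
#' @param de a [DEResults-class].
#' @param sets a [GeneSetCollection-class].
#' @param universe background genes; defaults to all genes tested in
#'   `de`.
#' @param fdrThreshold see [enrichGeneSets()].
#' @return list with enrichment tables `up` and `down`.
#' @export
enrichByDirection <- function(de, sets, universe = rownames(de),
        fdrThreshold = 0.05) {
    stopifnot(is(de, "DEResults"))
    degs <- callDEGs(de)
    run <- function(q, label) {
        if (!length(q)) {
            warning("no ", label, "-regulated genes; empty table returned")
            out <- suppressMessages(
                enrichGeneSets(character(), universe, sets, fdrThreshold))
            return(out[0L, , drop = FALSE])
        }
        enrichGeneSets(q, universe, sets, fdrThreshold)
    }
    list(up = run(degs$up, "up"), down = run(degs$down, "down"))
}
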