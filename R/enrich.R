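# Generic gene-set over-representation: hypergeometric upper tail per set
# with BH correction. Used for per-cluster GO enrichment and for module
# annotation; works on any term -> genes collection (GO slims, pathways).

#' Gene-set over-representation analysis
#'
#' Per set: upper-tail hypergeometric P(X >= k) with population
#' N = |universe|, K = |set genes in the universe|, draws n = |query| and
#' k = |query in set|; BH-FDR across sets.
#'
#' @param query character vector of genes (must be within the universe).
#' @param universe character vector of background genes.
#' @param sets named list, set id -> genes.
#' @return data.frame with columns \code{set}, \code{set_size},
#'   \code{overlap}, \code{p}, \code{fdr}, ordered by p; zero rows for an
#'   empty query.
#' @export
genesetEnrichment <- function(query, universe, sets) {
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query genes must be a subset of the universe")
    if (!length(query))
        return(data.frame(set = character(0), set_size = integer(0),
                          overlap = integer(0), p = numeric(0),
                          fdr = numeric(0)))
    N <- length(universe); n <- length(query)
    rows <- lapply(names(sets), function(s) {
        sg <- intersect(sets[[s]], universe)
        K <- length(sg)
        k <- length(intersect(query, sg))
        p <- if (K == 0) 1 else hyperUpperTail(k, K = K, N = N, n = n)
        data.frame(set = s, set_size = K, overlap = k, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhFdr(out$p)
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}
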