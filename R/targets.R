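# Assignment of high-efficacy, inversely regulated target genes to DE
# miRNAs, hypergeometric enrichment against the DE gene list, and the
# permutation enrichment-score calibration.

#' Assign functional target genes to DE miRNAs
#'
#' Predictions are filtered to context score <= \code{context_max} and to
#' genes present on the mRNA platform (the universe). The functional target
#' set of a miRNA is its predicted targets that are differentially
#' expressed with direction opposite to the miRNA's (down targets for up
#' miRNAs and vice versa); set \code{direction_aware = FALSE} to keep any
#' DE predicted target.
#'
#' @param de_mirnas filtered miRNA DE table (\code{\link{filterDE}}).
#' @param de_genes filtered mRNA DE table.
#' @param preds prediction table (\code{\link{readTargetPredictions}}).
#' @param universe character vector of genes on the mRNA platform.
#' @param context_max maximum retained context score.
#' @param direction_aware logical; inverse-direction rule (default TRUE).
#' @return list with elements \code{functional} (miRNA -> DE targets),
#'   \code{predicted} (miRNA -> platform-restricted predicted targets) and
#'   \code{universe}.
#' @export
assignTargets <- function(de_mirnas, de_genes, preds, universe,
                          context_max = -0.1, direction_aware = TRUE) {
    n0 <- nrow(preds)
    preds <- preds[preds$context_score <= context_max &
                   preds$gene %in% universe, , drop = FALSE]
    logFilter("predictions: context+platform", n0, nrow(preds))
    mirnas <- de_mirnas$feature
    dir_mirna <- stats::setNames(de_mirnas$direction, de_mirnas$feature)
    dir_gene <- stats::setNames(de_genes$direction, de_genes$feature)
    predicted <- lapply(stats::setNames(mirnas, mirnas), function(m)
        sort(unique(preds$gene[preds$mirna == m])))
    functional <- lapply(stats::setNames(mirnas, mirnas), function(m) {
        tg <- intersect(predicted[[m]], de_genes$feature)
        if (direction_aware)
            tg <- tg[dir_gene[tg] != dir_mirna[[m]]]
        sort(tg)
    })
    list(functional = functional, predicted = predicted,
         universe = sort(unique(universe)))
}

#' Hypergeometric enrichment of miRNA targets among DE genes
#'
#' Per miRNA: upper-tail P(X >= k) with population N = |universe|,
#' K = |DE genes|, draws n = |predicted targets|, successes
#' k = |functional targets|; BH-FDR across miRNAs and the enrichment score
#' ES = -log10 p.
#'
#' @param target_map result of \code{\link{assignTargets}}.
#' @param de_genes character vector of DE gene ids (subset of the universe).
#' @return data.frame with columns \code{mirna}, \code{n_predicted},
#'   \code{n_de_targets}, \code{p}, \code{fdr}, \code{es}.
#' @export
hypergeomEnrichment <- function(target_map, de_genes) {
    universe <- target_map$universe
    if (!all(de_genes %in% universe))
        stop("DE genes must be a subset of the universe")
    N <- length(universe); K <- length(unique(de_genes))
    mirnas <- names(target_map$predicted)
    res <- lapply(mirnas, function(m) {
        n <- length(target_map$predicted[[m]])
        k <- length(target_map$functional[[m]])
        p <- if (n == 0) 1 else hyperUpperTail(k, K = K, N = N, n = n)
        data.frame(mirna = m, n_predicted = n, n_de_targets = k, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$fdr <- bhFdr(out$p)
    out$es <- -log10(out$p)
    rownames(out) <- NULL
    out
}

#' Permutation calibration of enrichment scores
#'
#' For each of B permutations, draws |DE genes| genes uniformly without
#' replacement from the universe, recomputes each miRNA's overlap with its
#' predicted targets and the corresponding enrichment score, and reports
#' the permutation p-value (1 + #\{ES_b >= ES_obs\}) / (B + 1).
#'
#' @param target_map result of \code{\link{assignTargets}}.
#' @param enrichment result of \code{\link{hypergeomEnrichment}}.
#' @param n_de number of genes drawn per permutation (the DE gene count).
#' @param B number of permutations.
#' @param seed integer seed.
#' @return \code{enrichment} with an added \code{perm_p} column.
#' @export
permutationES <- function(target_map, enrichment, n_de, B = 1000, seed = 1) {
    if (B < 1) stop("B must be >= 1")
    universe <- target_map$universe
    N <- length(universe)
    if (n_de > N) stop("n_de exceeds the universe size")
    mirnas <- enrichment$mirna
    pred_idx <- lapply(target_map$predicted[mirnas], function(g)
        match(g, universe))
    # ES_b >= ES_obs iff k_b >= k_obs at fixed (N, K, n): count overlaps
    exceed <- integer(length(mirnas))
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    k_obs <- enrichment$n_de_targets
    for (b in seq_len(B)) {
        draw <- logical(N)
        draw[sample.int(N, n_de)] <- TRUE
        k_b <- vapply(pred_idx, function(ix) sum(draw[ix]), integer(1))
        exceed <- exceed + (k_b >= k_obs)
    }
    enrichment$perm_p <- (1 + exceed) / (B + 1)
    enrichment
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Retain miRNAs with significantly enriched targets
#'
#' Keeps miRNAs with enrichment FDR strictly below \code{fdr_max}; the
#' permutation p-value is reported alongside, not used as a second filter.
#'
#' @param enrichment result of \code{\link{hypergeomEnrichment}} (optionally
#'   with \code{perm_p}).
#' @param fdr_max FDR threshold (strict \code{<}).
#' @return character vector of retained miRNA ids.
#' @export
selectMirnas <- function(enrichment, fdr_max = 0.05) {
    keep <- enrichment$mirna[enrichment$fdr < fdr_max]
    logFilter("miRNA enrichment filter", nrow(enrichment), length(keep),
              sprintf("(FDR<%g)", fdr_max))
    if (!length(keep))
        warning("no miRNA passes the enrichment filter; ",
                "motif stages will be skipped")
    keep
}
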