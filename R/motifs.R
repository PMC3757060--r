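# TF target mapping via promoter/TFBS containment, 3-node and 4-node FFL
# candidate tests with pair-specific hypergeometric nulls, BH per
# (cluster x motif-type) family, and coexpression evaluation by KS test
# against a permutation reference.

#' Map TF target genes and TF-regulated miRNAs
#'
#' A feature is a target of a TF when at least one of the TF's binding
#' sites lies completely inside the feature's promoter, the symmetric
#' window of \code{halfwidth} nucleotides around the TSS (0-based
#' half-open: a TFBS [s, e) hits iff tss - w <= s and e <= tss + w). Only
#' TFs present in the expression matrix with a group-mean log2 intensity
#' >= \code{tf_expr_min} in at least one group are retained; absent TFs
#' are dropped with a log entry.
#'
#' @param tfbs TFBS table (\code{\link{readTFBS}}).
#' @param tss TSS table (\code{\link{readTSS}}).
#' @param expr mRNA \code{\link{expressionMatrix}} (TF rows included).
#' @param halfwidth promoter half-width in nucleotides.
#' @param tf_expr_min expression threshold (log2).
#' @return list with \code{gene_targets} (tf -> genes), \code{mirna_targets}
#'   (tf -> miRNAs) and \code{expressed_tfs}.
#' @export
mapTfTargets <- function(tfbs, tss, expr, halfwidth = 2000,
                         tf_expr_min = 8) {
    if (halfwidth <= 0) stop("halfwidth must be positive")
    tfs <- unique(tfbs$tf)
    hi <- expr$groups == "high"; lo <- expr$groups == "low"
    present <- tfs[tfs %in% rownames(expr$values)]
    if (length(present) < length(tfs))
        logFilter("TFs present on platform", length(tfs), length(present))
    expressed <- present[vapply(present, function(f) {
        max(mean(expr$values[f, hi]), mean(expr$values[f, lo])) >= tf_expr_min
    }, logical(1))]
    logFilter("TFs expressed", length(present), length(expressed),
              sprintf("(log2>=%g in >=1 group)", tf_expr_min))

    gene_targets <- stats::setNames(vector("list", length(expressed)),
                                    expressed)
    mirna_targets <- gene_targets
    for (f in expressed) {
        gene_targets[[f]] <- character(0)
        mirna_targets[[f]] <- character(0)
    }
    sites <- tfbs[tfbs$tf %in% expressed, , drop = FALSE]
    for (chr in unique(tss$chrom)) {
        anno <- tss[tss$chrom == chr, , drop = FALSE]
        st <- sites[sites$chrom == chr, , drop = FALSE]
        if (!nrow(anno) || !nrow(st)) next
        # 0-based half-open [tss-w, tss+w) -> 1-based closed IRanges
        prom <- IRanges::IRanges(start = anno$tss - halfwidth + 1,
                                 end = anno$tss + halfwidth)
        bs <- IRanges::IRanges(start = st$start + 1, end = st$end)
        ov <- IRanges::findOverlaps(bs, prom, type = "within")
        if (!length(ov)) next
        hit_tf <- st$tf[S4Vectors_from(ov)]
        hit_feat <- anno$feature[S4Vectors_to(ov)]
        hit_kind <- anno$kind[S4Vectors_to(ov)]
        for (ix in seq_along(hit_tf)) {
            f <- hit_tf[ix]
            if (hit_kind[ix] == "gene")
                gene_targets[[f]] <- c(gene_targets[[f]], hit_feat[ix])
            else
                mirna_targets[[f]] <- c(mirna_targets[[f]], hit_feat[ix])
        }
    }
    list(gene_targets = lapply(gene_targets, function(x) sort(unique(x))),
         mirna_targets = lapply(mirna_targets, function(x) sort(unique(x))),
         expressed_tfs = expressed)
}

# small wrappers to avoid importing S4Vectors wholesale
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

#' 3-node FFL hypergeometric test for one miRNA-TF pair
#'
#' Tests whether the pair shares more differentially expressed common
#' targets than expected among the miRNA's computationally predicted
#' targets: population N = predicted targets of the miRNA, successes
#' K = predicted targets bound by the TF, draws n = functional (DE)
#' targets, observed k = functional targets bound by the TF. With
#' \code{universe} supplied, the population is that gene set instead
#' (global-null sensitivity variant).
#'
#' @param predicted character vector, the miRNA's predicted targets.
#' @param functional character vector, the miRNA's functional DE targets
#'   (subset of \code{predicted}).
#' @param tf_targets character vector, genes bound by the TF.
#' @param universe optional global universe overriding the predicted-target
#'   null.
#' @return list with \code{p} and the counts \code{N}, \code{K}, \code{n},
#'   \code{k} and the common targets.
#' @export
ffl3Test <- function(predicted, functional, tf_targets, universe = NULL) {
    pop <- if (is.null(universe)) predicted else unique(universe)
    if (!all(functional %in% pop))
        stop("functional targets must lie in the null population")
    N <- length(pop)
    K <- length(intersect(pop, tf_targets))
    n <- length(functional)
    common <- intersect(functional, tf_targets)
    k <- length(common)
    p <- if (K == 0 || N == 0) 1 else hyperUpperTail(k, K = K, N = N, n = n)
    list(p = p, N = N, K = K, n = n, k = k, common = sort(common))
}

#' First-neighbor gene sets around miRNA functional targets
#'
#' For each miRNA, the union of its functional targets and their direct
#' PPI neighbors. Targets absent from the PPI contribute only themselves.
#'
#' @param functional named list, miRNA -> functional targets.
#' @param ppi PPI edge table (\code{\link{readPPI}}).
#' @return named list, miRNA -> first-neighbor gene set.
#' @export
neighborNetwork <- function(functional, ppi) {
    adj <- split(c(ppi$b, ppi$a), c(ppi$a, ppi$b))
    lapply(functional, function(tg) {
        nb <- unique(unlist(adj[tg], use.names = FALSE))
        sort(unique(c(tg, nb)))
    })
}

#' 4-node FFL hypergeometric test for one miRNA-TF pair
#'
#' Tests whether the TF binds differentially expressed secondary-target
#' candidates more often than expected within the miRNA's first-neighbor
#' protein-interaction network: population N = first neighbors,
#' K = neighbors bound by the TF, draws n = DE neighbors, observed k = DE
#' neighbors bound by the TF.
#'
#' @param neighbors the miRNA's first-neighbor gene set.
#' @param tf_targets genes bound by the TF.
#' @param de_genes differentially expressed genes.
#' @return list with \code{p}, counts and the co-regulated secondaries.
#' @export
ffl4Test <- function(neighbors, tf_targets, de_genes) {
    N <- length(neighbors)
    K <- length(intersect(neighbors, tf_targets))
    nb_de <- intersect(neighbors, de_genes)
    n <- length(nb_de)
    sec <- intersect(nb_de, tf_targets)
    k <- length(sec)
    p <- if (N == 0 || K == 0) 1 else hyperUpperTail(k, K = K, N = N, n = n)
    list(p = p, N = N, K = K, n = n, k = k, secondaries = sort(sec))
}

#' Enumerate and test all miRNA-TF pairs per cluster and motif type
#'
#' Runs \code{\link{ffl3Test}} and \code{\link{ffl4Test}} for every
#' (retained miRNA, expressed TF) pair within each functional cluster,
#' adjusts p-values by BH within each (cluster x motif-type) family, and
#' materializes FFL records for pairs below the FDR threshold (strict
#' \code{<}).
#'
#' @param mirnas retained miRNA ids.
#' @param target_map result of \code{\link{assignTargets}}.
#' @param tf_map result of \code{\link{mapTfTargets}}.
#' @param ppi PPI edge table.
#' @param de_genes DE gene ids (secondary-target candidates; direction
#'   unconstrained).
#' @param clusters named integer/character vector, functional target gene ->
#'   cluster label; tests are run per cluster.
#' @param ffl_fdr FDR threshold for pair significance.
#' @return list with \code{pairs} (one row per tested pair: cluster, motif,
#'   mirna, tf, counts, p, fdr, significant) and \code{records} (one row per
#'   motif instance of a significant pair: motif, cluster, mirna, tf,
#'   primary, secondary).
#' @export
fflDiscovery <- function(mirnas, target_map, tf_map, ppi, de_genes,
                         clusters, ffl_fdr = 0.2) {
    tfs <- tf_map$expressed_tfs
    if (!length(mirnas) || !length(tfs))
        return(list(pairs = emptyPairs(), records = emptyRecords()))
    adj <- split(c(ppi$b, ppi$a), c(ppi$a, ppi$b))
    pair_rows <- list(); rec_ctx <- list()
    for (cl in sort(unique(as.character(clusters)))) {
        cl_genes <- names(clusters)[as.character(clusters) == cl]
        func_cl <- lapply(target_map$functional[mirnas], intersect,
                          x = cl_genes)
        nb_cl <- neighborNetwork(func_cl, ppi)
        for (m in mirnas) for (f in tfs) {
            t3 <- ffl3Test(target_map$predicted[[m]], func_cl[[m]],
                           tf_map$gene_targets[[f]])
            pair_rows[[length(pair_rows) + 1]] <- data.frame(
                cluster = cl, motif = "ffl3", mirna = m, tf = f,
                N = t3$N, K = t3$K, n = t3$n, k = t3$k, p = t3$p,
                stringsAsFactors = FALSE)
            rec_ctx[[paste(cl, "ffl3", m, f)]] <- t3$common
            t4 <- ffl4Test(nb_cl[[m]], tf_map$gene_targets[[f]], de_genes)
            pair_rows[[length(pair_rows) + 1]] <- data.frame(
                cluster = cl, motif = "ffl4", mirna = m, tf = f,
                N = t4$N, K = t4$K, n = t4$n, k = t4$k, p = t4$p,
                stringsAsFactors = FALSE)
            rec_ctx[[paste(cl, "ffl4", m, f)]] <- t4$secondaries
        }
    }
    pairs <- do.call(rbind, pair_rows)
    pairs$fdr <- NA_real_
    for (cl in unique(pairs$cluster)) for (mt in c("ffl3", "ffl4")) {
        ix <- pairs$cluster == cl & pairs$motif == mt
        pairs$fdr[ix] <- bhFdr(pairs$p[ix])
    }
    pairs$significant <- pairs$fdr < ffl_fdr
    recs <- list()
    sig <- pairs[pairs$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
        cl <- sig$cluster[i]; mt <- sig$motif[i]
        m <- sig$mirna[i]; f <- sig$tf[i]
        cl_genes <- names(clusters)[as.character(clusters) == cl]
        func <- intersect(target_map$functional[[m]], cl_genes)
        if (mt == "ffl3") {
            for (g in rec_ctx[[paste(cl, mt, m, f)]])
                recs[[length(recs) + 1]] <- data.frame(
                    motif = "ffl3", cluster = cl, mirna = m, tf = f,
                    primary = g, secondary = NA_character_,
                    p = sig$p[i], fdr = sig$fdr[i],
                    stringsAsFactors = FALSE)
        } else {
            for (s in rec_ctx[[paste(cl, mt, m, f)]]) {
                prim <- intersect(func, adj[[s]])
                # a DE functional target bound by the TF can itself be the
                # interacting secondary's partner; require a PPI link
                for (g in prim)
                    recs[[length(recs) + 1]] <- data.frame(
                        motif = "ffl4", cluster = cl, mirna = m, tf = f,
                        primary = g, secondary = s,
                        p = sig$p[i], fdr = sig$fdr[i],
                        stringsAsFactors = FALSE)
            }
        }
    }
    records <- if (length(recs)) do.call(rbind, recs) else emptyRecords()
    list(pairs = pairs, records = records)
}

# n distinct unordered index pairs from M items (rejection sampling)
samplePairs <- function(M, n) {
    n <- min(n, M * (M - 1) / 2)
    keys <- integer(0)
    while (length(keys) < n) {
        a <- sample.int(M, n, replace = TRUE)
        b <- sample.int(M, n, replace = TRUE)
        lo <- pmin(a, b); hi <- pmax(a, b)
        ok <- lo < hi
        keys <- unique(c(keys, (lo[ok] - 1) * M + hi[ok]))
    }
    keys <- keys[seq_len(n)]
    cbind((keys - 1) %/% M + 1, (keys - 1) %% M + 1)
}

emptyPairs <- function() data.frame(
    cluster = character(0), motif = character(0), mirna = character(0),
    tf = character(0), N = integer(0), K = integer(0), n = integer(0),
    k = integer(0), p = numeric(0), fdr = numeric(0),
    significant = logical(0), stringsAsFactors = FALSE)

emptyRecords <- function() data.frame(
    motif = character(0), cluster = character(0), mirna = character(0),
    tf = character(0), primary = character(0), secondary = character(0),
    p = numeric(0), fdr = numeric(0), stringsAsFactors = FALSE)

#' Re-verify FFL records against the raw inputs
#'
#' Structural validation of every emitted motif instance: a 3-node record
#' needs its primary among the miRNA's functional targets and bound by the
#' TF; a 4-node record needs the primary among the miRNA's functional
#' targets, the secondary bound by the TF and differentially expressed,
#' and a PPI edge between primary and secondary.
#'
#' @param records FFL record table (\code{\link{fflDiscovery}}).
#' @param target_map result of \code{\link{assignTargets}}.
#' @param tf_map result of \code{\link{mapTfTargets}}.
#' @param ppi PPI edge table.
#' @param de_genes DE gene ids.
#' @return logical vector, one entry per record, TRUE when the record
#'   satisfies its structural invariant.
#' @export
verifyFFLRecords <- function(records, target_map, tf_map, ppi, de_genes) {
    ppi_keys <- c(paste(ppi$a, ppi$b), paste(ppi$b, ppi$a))
    vapply(seq_len(nrow(records)), function(i) {
        m <- records$mirna[i]; f <- records$tf[i]
        g <- records$primary[i]; s <- records$secondary[i]
        func <- target_map$functional[[m]]
        bound <- tf_map$gene_targets[[f]]
        if (is.null(func) || is.null(bound)) return(FALSE)
        if (records$motif[i] == "ffl3") {
            g %in% func && g %in% bound
        } else {
            g %in% func && s %in% bound && s %in% de_genes &&
                paste(g, s) %in% ppi_keys
        }
    }, logical(1))
}

#' Coexpression of co-regulated genes versus random gene pairs
#'
#' For each (cluster, motif-type) family, pools the Pearson correlations
#' (across samples) of every unordered gene pair co-regulated by the same
#' significant miRNA-TF pair, draws \code{B} equally sized sets of random
#' gene pairs from the expression matrix as the reference, and applies a
#' one-sided two-sample KS test of the observed correlations being
#' stochastically greater. Genes with zero variance across samples are
#' skipped (logged).
#'
#' @param records FFL records (\code{\link{fflDiscovery}}).
#' @param expr mRNA \code{\link{expressionMatrix}}.
#' @param B number of random draws.
#' @param seed integer seed.
#' @return data.frame with one row per (cluster, motif): number of pairs,
#'   mean observed and reference correlation, KS statistic and p-value.
#' @export
coexpressionEval <- function(records, expr, B = 1000, seed = 1) {
    vals <- expr$values
    usable <- rownames(vals)[apply(vals, 1, stats::var) > 0]
    if (length(usable) < nrow(vals))
        logFilter("coexpression: non-constant genes", nrow(vals),
                  length(usable))
    old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
    set.seed(seed)
    # all pairwise correlations once; indexed below
    C <- stats::cor(t(vals[usable, , drop = FALSE]))
    out <- list()
    for (cl in unique(records$cluster)) for (mt in unique(records$motif)) {
        sub <- records[records$cluster == cl & records$motif == mt, ,
                       drop = FALSE]
        if (!nrow(sub)) next
        pair_sets <- split(
            ifelse(is.na(sub$secondary), sub$primary,
                   paste(sub$primary, sub$secondary, sep = "\r")),
            paste(sub$mirna, sub$tf))
        gp <- list()
        for (ps in pair_sets) {
            genes <- unique(unlist(strsplit(ps, "\r", fixed = TRUE)))
            genes <- intersect(genes, usable)
            if (length(genes) >= 2) {
                cmb <- utils::combn(sort(genes), 2)
                gp[[length(gp) + 1]] <- cmb
            }
        }
        if (!length(gp)) next
        pairs_mat <- unique(t(do.call(cbind, gp)))
        obs <- C[cbind(pairs_mat[, 1], pairs_mat[, 2])]
        n_pairs <- length(obs)
        # pairs distinct within each draw; draws independent
        ref <- numeric(0)
        for (b in seq_len(B)) {
            pm <- samplePairs(length(usable), n_pairs)
            ref <- c(ref, C[cbind(pm[, 1], pm[, 2])])
        }
        ks <- suppressWarnings(
            stats::ks.test(obs, ref, alternative = "less"))
        out[[length(out) + 1]] <- data.frame(
            cluster = cl, motif = mt, n_pairs = n_pairs,
            mean_obs = mean(obs), mean_ref = mean(ref),
            ks_stat = unname(ks$statistic), p = ks$p.value,
            stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else data.frame(
        cluster = character(0), motif = character(0), n_pairs = integer(0),
        mean_obs = numeric(0), mean_ref = numeric(0), ks_stat = numeric(0),
        p = numeric(0))
}
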