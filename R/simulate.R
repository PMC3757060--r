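# Synthetic input bundles with planted ground truth. The generator emulates
# the study design the pipeline expects: a 4-vs-3 two-group panel, planted
# up/down DE miRNAs whose functional targets carry inverse group effects,
# planted 3-node FFLs (TF binding sites placed fully inside the common
# target's promoter) and 4-node FFLs (a PPI edge primary-secondary plus a
# TFBS in the secondary's promoter), decoy binding sites straddling
# promoter boundaries to exercise the complete-containment rule, and a
# two-branch GO toy ontology that gives target genes a metabolic-like (A)
# or signaling-like (B) functional identity.

resample <- function(x, size, replace = FALSE) x[sample.int(length(x), size,
                                                            replace = replace)]

# binary tree of `depth` levels under one branch term; returns parent list
branchTerms <- function(prefix, depth) {
    parents <- list()
    parents[[prefix]] <- character(0)   # filled by caller with the root
    level <- prefix
    for (dd in seq_len(depth - 1)) {
        nxt <- character(0)
        for (p in level) for (s in 1:2) {
            id <- paste0(p, ".", s)
            parents[[id]] <- p
            nxt <- c(nxt, id)
        }
        level <- nxt
    }
    parents
}

makeToyDag <- function(depth) {
    root <- "BP:root"
    parents <- stats::setNames(list(character(0)), root)
    for (br in c("BP:A", "BP:B")) {
        sub <- branchTerms(br, depth)
        sub[[br]] <- root
        parents <- c(parents, sub)
    }
    new("GODag", parents = parents, namespace = "biological_process",
        root = root)
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return list with \code{bundle} (all in-memory inputs: mirna_expr,
#'   mrna_expr, predictions, tfbs, tss, ppi, annotation, dag) and
#'   \code{truth} (planted DE miRNAs and genes, functional pairs, FFL
#'   triples/quads, branch labels).
#' @export
simulateBundle <- function(params = simulationParams()) {
    p <- params
    old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
    set.seed(p@seed)

    mirnas <- sprintf("mir%03d", seq_len(p@n_mirnas))
    genes <- sprintf("g%03d", seq_len(p@n_genes))
    tfs <- sprintf("TF%02d", seq_len(p@n_tfs))
    samples <- c(sprintf("H%d", seq_len(p@n_samples_high)),
                 sprintf("L%d", seq_len(p@n_samples_low)))
    groups <- stats::setNames(rep(c("high", "low"),
                                  c(p@n_samples_high, p@n_samples_low)),
                              samples)

    n_down <- p@n_de_mirnas_down; n_up <- p@n_de_mirnas_up
    de_mirnas <- mirnas[seq_len(n_down + n_up)]
    mirna_lfc <- stats::setNames(
        c(-(p@de_lfc_mean + p@de_lfc_sd * stats::rnorm(n_down)),
          p@de_lfc_mean + p@de_lfc_sd * stats::rnorm(n_up)),
        de_mirnas)

    # planted DE gene pools; inverse regulation pairs down-miRNAs with the
    # up pool and vice versa
    n_func <- round(p@fraction_functional_targets * p@targets_per_mirna)
    n_pool <- max(round(0.12 * p@n_genes), n_func)
    if (2 * n_pool > p@n_genes)
        stop("infeasible: DE gene pools exceed the gene count")
    up_pool <- genes[seq_len(n_pool)]
    down_pool <- genes[n_pool + seq_len(n_pool)]
    null_genes <- genes[-seq_len(2 * n_pool)]
    gene_lfc <- stats::setNames(
        c(p@de_lfc_mean + p@de_lfc_sd * stats::rnorm(n_pool),
          -(p@de_lfc_mean + p@de_lfc_sd * stats::rnorm(n_pool))),
        c(up_pool, down_pool))

    # expression: baseline + half-effect split between groups + noise
    buildExpr <- function(ids, lfc_map, baseline) {
        eff <- stats::setNames(rep(0, length(ids)), ids)
        known <- intersect(ids, names(lfc_map))
        eff[known] <- lfc_map[known]
        base <- stats::setNames(rep(baseline, length(ids)), ids)
        vals <- outer(eff, ifelse(groups == "high", 0.5, -0.5)) + base +
            matrix(stats::rnorm(length(ids) * length(samples),
                                sd = p@noise_sd),
                   length(ids), length(samples))
        dimnames(vals) <- list(ids, samples)
        vals
    }
    mirna_vals <- buildExpr(mirnas, mirna_lfc, p@baseline_mean)
    gene_vals <- buildExpr(genes, gene_lfc, p@baseline_mean)
    # TFs ride on the mRNA platform; the last TF is left unexpressed to
    # exercise the expression filter
    expressed_tfs <- tfs[-length(tfs)]
    tf_base <- stats::setNames(rep(9, length(tfs)), tfs)
    tf_base[tfs[length(tfs)]] <- 6
    tf_vals <- matrix(stats::rnorm(length(tfs) * length(samples),
                                   sd = p@noise_sd),
                      length(tfs), length(samples),
                      dimnames = list(tfs, samples)) + tf_base
    mrna_vals <- rbind(gene_vals, tf_vals)
    mirna_expr <- expressionMatrix(mirna_vals, groups)
    mrna_expr <- expressionMatrix(mrna_vals, groups)

    # predictions: planted miRNAs draw functional targets from the
    # opposite-direction pool; padding targets come from null genes; a few
    # weak-scored rows per miRNA exercise the context-score filter
    pred_rows <- list()
    functional <- list()
    for (m in mirnas) {
        if (m %in% de_mirnas) {
            pool <- if (mirna_lfc[[m]] < 0) up_pool else down_pool
            fx <- resample(pool, n_func)
            functional[[m]] <- fx
            pad <- resample(null_genes,
                            min(p@targets_per_mirna - n_func,
                                length(null_genes)))
            tg <- c(fx, pad)
        } else {
            tg <- resample(genes, p@targets_per_mirna)
        }
        pred_rows[[m]] <- data.frame(
            mirna = m, gene = tg,
            context_score = round(stats::runif(length(tg), -0.6, -0.15), 3),
            stringsAsFactors = FALSE)
        weak <- resample(genes, 3)
        pred_rows[[paste0(m, ".weak")]] <- data.frame(
            mirna = m, gene = weak,
            context_score = round(stats::runif(3, -0.09, -0.01), 3),
            stringsAsFactors = FALSE)
    }
    predictions <- do.call(rbind, pred_rows)
    rownames(predictions) <- NULL

    # genome layout: promoters are disjoint 10 kb-spaced windows
    w <- 2000
    gene_tss <- stats::setNames(10000 * seq_along(genes) + 5000, genes)
    mirna_tss <- stats::setNames(10000 * seq_along(mirnas) + 5000, mirnas)
    tss <- rbind(
        data.frame(feature = genes, kind = "gene", chrom = "chr1",
                   tss = unname(gene_tss),
                   strand = rep_len(c("+", "-"), length(genes)),
                   stringsAsFactors = FALSE),
        data.frame(feature = mirnas, kind = "mirna", chrom = "chr2",
                   tss = unname(mirna_tss),
                   strand = rep_len(c("+", "-"), length(mirnas)),
                   stringsAsFactors = FALSE))

    n_pairs <- p@n_planted_ffl3 + p@n_planted_ffl4
    if (n_pairs > length(expressed_tfs))
        stop("infeasible: more planted FFL pairs than expressed TFs")
    if (p@n_planted_ffl3 > 0 && p@n_planted_ffl3 > length(de_mirnas))
        stop("infeasible: more planted 3-node FFLs than DE miRNAs")

    tfbs_rows <- list()
    siteIn <- function(tf, chrom, tsspos)
        data.frame(tf = tf, chrom = chrom, start = tsspos - 50,
                   end = tsspos - 40, stringsAsFactors = FALSE)
    # planted pairs alternate between down- and up-regulated miRNAs so
    # both functional branches receive motifs
    down_m <- de_mirnas[seq_len(n_down)]
    up_m <- de_mirnas[n_down + seq_len(n_up)]
    de_inter <- character(0)
    for (i in seq_len(max(n_down, n_up))) {
        if (i <= n_down) de_inter <- c(de_inter, down_m[i])
        if (i <= n_up) de_inter <- c(de_inter, up_m[i])
    }
    ffl3_pairs <- list(); ffl3_triples <- list()
    for (i in seq_len(p@n_planted_ffl3)) {
        m <- de_inter[((i - 1) %% length(de_inter)) + 1]
        f <- expressed_tfs[i]
        bound <- resample(functional[[m]], max(1, round(0.85 * n_func)))
        for (g in bound)
            tfbs_rows[[length(tfbs_rows) + 1]] <-
                siteIn(f, "chr1", gene_tss[[g]])
        tfbs_rows[[length(tfbs_rows) + 1]] <- siteIn(f, "chr2", mirna_tss[[m]])
        ffl3_pairs[[i]] <- data.frame(mirna = m, tf = f,
                                      stringsAsFactors = FALSE)
        ffl3_triples[[i]] <- data.frame(mirna = m, tf = f, target = bound,
                                        stringsAsFactors = FALSE)
    }

    ppi_rows <- list()
    ffl4_pairs <- list(); ffl4_quads <- list()
    n_sec <- 15
    for (j in seq_len(p@n_planted_ffl4)) {
        m <- de_inter[((p@n_planted_ffl3 + j - 1) %% length(de_inter)) + 1]
        f <- expressed_tfs[p@n_planted_ffl3 + j]
        # secondaries share the primaries' direction (coherent inverse
        # regulation by the pair), drawn outside the miRNA's own targets
        cand <- setdiff(if (mirna_lfc[[m]] < 0) up_pool else down_pool,
                        functional[[m]])
        secs <- resample(cand, min(n_sec, length(cand)))
        prims <- resample(functional[[m]], length(secs), replace = TRUE)
        for (ix in seq_along(secs)) {
            s <- secs[ix]; g <- prims[ix]
            tfbs_rows[[length(tfbs_rows) + 1]] <-
                siteIn(f, "chr1", gene_tss[[s]])
            ppi_rows[[length(ppi_rows) + 1]] <-
                data.frame(a = g, b = s, stringsAsFactors = FALSE)
            ffl4_quads[[length(ffl4_quads) + 1]] <- data.frame(
                mirna = m, tf = f, primary = g, secondary = s,
                stringsAsFactors = FALSE)
        }
        tfbs_rows[[length(tfbs_rows) + 1]] <- siteIn(f, "chr2", mirna_tss[[m]])
        ffl4_pairs[[j]] <- data.frame(mirna = m, tf = f,
                                      stringsAsFactors = FALSE)
    }

    # background binding inside random promoters + boundary decoys that
    # only partially overlap (must never count as targets)
    for (f in expressed_tfs) {
        hit <- genes[stats::runif(length(genes)) < 0.02]
        for (g in hit)
            tfbs_rows[[length(tfbs_rows) + 1]] <-
                siteIn(f, "chr1", gene_tss[[g]])
        for (g in resample(genes, 2))
            tfbs_rows[[length(tfbs_rows) + 1]] <- data.frame(
                tf = f, chrom = "chr1", start = gene_tss[[g]] + w - 5,
                end = gene_tss[[g]] + w + 5, stringsAsFactors = FALSE)
    }
    # the unexpressed TF binds promoters too; it must be filtered out
    for (g in resample(genes, 5))
        tfbs_rows[[length(tfbs_rows) + 1]] <-
            siteIn(tfs[length(tfs)], "chr1", gene_tss[[g]])
    tfbs <- unique(do.call(rbind, tfbs_rows))
    rownames(tfbs) <- NULL

    # background PPI
    n_bg <- stats::rbinom(1, choose(p@n_genes, 2),
                          p@ppi_background_edge_prob)
    if (n_bg > 0) {
        pm <- samplePairs(p@n_genes, n_bg)
        ppi_rows[[length(ppi_rows) + 1]] <- data.frame(
            a = genes[pm[, 1]], b = genes[pm[, 2]], stringsAsFactors = FALSE)
    }
    ppi <- suppressMessages(normalizePPI(do.call(rbind, ppi_rows)))

    # GO: two branches; up-pool genes are branch A ("metabolic-like"),
    # down-pool branch B ("signaling-like"), flipped with the noise rate;
    # a third of the null genes get random annotations for corpus realism
    dag <- makeToyDag(p@go_depth)
    termsOf <- function(br) {
        all_t <- dagTerms(dag)
        all_t[startsWith(all_t, paste0("BP:", br, "."))]
    }
    tA <- termsOf("A"); tB <- termsOf("B")
    annotation <- list(); branch <- character(0)
    for (g in c(up_pool, down_pool)) {
        br_true <- if (g %in% up_pool) "A" else "B"
        br_obs <- if (stats::runif(1) < p@go_annotation_noise)
            setdiff(c("A", "B"), br_true) else br_true
        pool_t <- if (br_obs == "A") tA else tB
        annotation[[g]] <- resample(pool_t, min(sample(2:3, 1),
                                                length(pool_t)))
        branch[g] <- br_true
    }
    # null genes carry coherent annotations too (a random single branch):
    # non-DE genes still belong to one functional class each
    for (g in resample(null_genes, round(length(null_genes) / 3))) {
        pool_t <- if (stats::runif(1) < 0.5) tA else tB
        annotation[[g]] <- resample(pool_t, min(sample(2:3, 1),
                                                length(pool_t)))
    }

    bundle <- list(mirna_expr = mirna_expr, mrna_expr = mrna_expr,
                   predictions = predictions, tfbs = tfbs, tss = tss,
                   ppi = ppi, annotation = annotation, dag = dag)
    truth <- list(
        de_mirnas = data.frame(mirna = de_mirnas,
                               log2fc = unname(mirna_lfc),
                               stringsAsFactors = FALSE),
        de_genes = data.frame(gene = names(gene_lfc),
                              log2fc = unname(gene_lfc),
                              stringsAsFactors = FALSE),
        functional_pairs = do.call(rbind, lapply(names(functional),
            function(m) if (length(functional[[m]]))
                data.frame(mirna = m, gene = functional[[m]],
                           stringsAsFactors = FALSE))),
        ffl3_pairs = if (length(ffl3_pairs)) do.call(rbind, ffl3_pairs)
                     else NULL,
        ffl3_triples = if (length(ffl3_triples))
                           do.call(rbind, ffl3_triples) else NULL,
        ffl4_pairs = if (length(ffl4_pairs)) do.call(rbind, ffl4_pairs)
                     else NULL,
        ffl4_quads = if (length(ffl4_quads)) do.call(rbind, ffl4_quads)
                     else NULL,
        branch = data.frame(gene = names(branch), branch = unname(branch),
                            stringsAsFactors = FALSE)
    )
    list(bundle = bundle, truth = truth)
}

#' Generate a null bundle (no planted effects)
#'
#' Identical structure to \code{\link{simulateBundle}} with every planted
#' effect size set to zero: expression carries pure noise, so every
#' downstream test operates under its null.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return as \code{\link{simulateBundle}}.
#' @export
nullBundle <- function(params = simulationParams()) {
    p <- params
    methods::slot(p, "de_lfc_mean") <- 0
    methods::slot(p, "de_lfc_sd") <- 0
    simulateBundle(p)
}

#' Write a bundle to disk in the pipeline's file formats
#'
#' @param sim result of \code{\link{simulateBundle}}.
#' @param dir output directory (created if needed).
#' @return named list of file paths accepted by \code{\link{loadInputs}}.
#' @export
writeBundle <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    b <- sim$bundle
    paths <- list(
        mirna_expr = file.path(dir, "mirna_expr.tsv"),
        mirna_groups = file.path(dir, "mirna_groups.tsv"),
        mrna_expr = file.path(dir, "mrna_expr.tsv"),
        mrna_groups = file.path(dir, "mrna_groups.tsv"),
        predictions = file.path(dir, "predictions.tsv"),
        tfbs = file.path(dir, "tfbs.tsv"),
        tss = file.path(dir, "tss.tsv"),
        ppi = file.path(dir, "ppi.tsv"),
        gaf = file.path(dir, "annotation.gaf.tsv"),
        obo = file.path(dir, "go.obo")
    )
    writeExpression(b$mirna_expr, paths$mirna_expr, paths$mirna_groups)
    writeExpression(b$mrna_expr, paths$mrna_expr, paths$mrna_groups)
    wt <- function(df, f) utils::write.table(df, f, sep = "\t",
                                             quote = FALSE, row.names = FALSE)
    wt(b$predictions, paths$predictions)
    wt(b$tfbs, paths$tfbs)
    wt(b$tss, paths$tss)
    wt(data.frame(gene1 = b$ppi$a, gene2 = b$ppi$b), paths$ppi)
    gaf <- data.frame(gene = rep(names(b$annotation),
                                 lengths(b$annotation)),
                      term = unlist(b$annotation, use.names = FALSE),
                      namespace = "biological_process")
    wt(gaf, paths$gaf)
    writeOBO(b$dag, paths$obo)
    jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths
}

#' Derive propagated term -> gene sets from an annotation
#'
#' @param annotation named list, gene -> terms.
#' @param dag a \linkS4class{GODag}.
#' @return named list, term -> genes (annotations propagated to ancestors).
#' @export
annotationToSets <- function(annotation, dag) {
    sets <- list()
    for (g in names(annotation)) {
        prop <- unique(unlist(lapply(annotation[[g]], ancestorsWithSelf,
                                     dag = dag)))
        for (t in prop) sets[[t]] <- c(sets[[t]], g)
    }
    lapply(sets, unique)
}
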