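# End-to-end orchestration: differential expression -> target assignment
# and enrichment -> GO similarity clustering -> FFL motif testing ->
# network construction and module analysis. Every stage's table can be
# serialized to an output directory, and the whole run is deterministic
# given the configuration seed.

#' Run the full co-regulatory FFL pipeline
#'
#' @param bundle input bundle: either the \code{bundle} element of
#'   \code{\link{simulateBundle}} or the result of \code{\link{loadInputs}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param outdir optional directory; when given, every stage table is
#'   written as TSV and the per-cluster networks as GraphML.
#' @return list with elements \code{de_mirna}, \code{de_mrna} (full DE
#'   tables), \code{de_mirna_sig}, \code{de_mrna_sig} (filtered),
#'   \code{target_map}, \code{enrichment}, \code{retained_mirnas},
#'   \code{clustering} (model-selection result), \code{clusters} (gene ->
#'   label), \code{cluster_enrichment}, \code{tf_map}, \code{ffl} (pair
#'   tests + records), \code{coexpression}, \code{networks} (per cluster:
#'   network, hubs, modules, module annotation).
#' @export
runPipeline <- function(bundle, config = pipelineConfig(), outdir = NULL) {
    methods::validObject(config)
    if (!is.null(outdir))
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(obj, name) {
        if (!is.null(outdir) && is.data.frame(obj))
            utils::write.table(obj, file.path(outdir, paste0(name, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        obj
    }
    res <- list()

    # -- stage 1: differential expression ------------------------------
    mirna_kept <- varianceFilter(bundle$mirna_expr,
                                 config@variance_keep_fraction)
    res$de_mirna <- emit(moderatedT(mirna_kept), "de_mirna")
    res$de_mirna_sig <- emit(
        filterDE(res$de_mirna, "fdr", config@mirna_fdr,
                 config@mirna_abs_lfc), "de_mirna_sig")
    res$de_mrna <- emit(moderatedT(bundle$mrna_expr), "de_mrna")
    res$de_mrna_sig <- emit(
        filterDE(res$de_mrna, "raw", config@mrna_p, config@mrna_abs_lfc),
        "de_mrna_sig")

    # -- stage 2: target assignment and enrichment ---------------------
    universe <- rownames(bundle$mrna_expr$values)
    res$target_map <- assignTargets(
        res$de_mirna_sig, res$de_mrna_sig, bundle$predictions, universe,
        context_max = config@context_score_max,
        direction_aware = config@direction_aware)
    res$enrichment <- hypergeomEnrichment(res$target_map,
                                          res$de_mrna_sig$feature)
    res$enrichment <- emit(
        permutationES(res$target_map, res$enrichment,
                      n_de = length(unique(res$de_mrna_sig$feature)),
                      B = config@n_permutations,
                      seed = subSeed(config@seed, 1)), "enrichment")
    res$retained_mirnas <- selectMirnas(res$enrichment, config@mirna_fdr)

    # -- stage 3: GO similarity clustering of functional targets -------
    func_genes <- sort(unique(unlist(
        res$target_map$functional[res$retained_mirnas])))
    annotated <- func_genes[func_genes %in% names(bundle$annotation) &
                            lengths(bundle$annotation[func_genes]) > 0]
    logFilter("targets with GO annotation", length(func_genes),
              length(annotated), "(unannotated excluded)")
    if (length(annotated) >= 4) {
        simm <- geneSimilarityMatrix(annotated, bundle$annotation,
                                     bundle$dag)
        res$clustering <- selectParameters(simm$dis,
                                           r_grid = config@fuzziness_grid,
                                           k_grid = config@k_grid,
                                           seed = subSeed(config@seed, 2))
        emit(res$clustering$diagnostics, "cluster_diagnostics")
        labs <- hardLabels(res$clustering$clustering)
        res$clusters <- stats::setNames(paste0("C", labs), names(labs))
        sets <- annotationToSets(bundle$annotation, bundle$dag)
        res$cluster_enrichment <- do.call(rbind, lapply(
            sort(unique(res$clusters)), function(cl) {
                q <- names(res$clusters)[res$clusters == cl]
                enr <- genesetEnrichment(q, annotated, sets)
                if (nrow(enr)) cbind(cluster = cl, enr) else NULL
            }))
        emit(res$cluster_enrichment, "cluster_enrichment")
    } else {
        warning("too few annotated functional targets to cluster; ",
                "treating all as one cluster")
        res$clustering <- NULL
        res$clusters <- stats::setNames(rep("C1", length(annotated)),
                                        annotated)
        res$cluster_enrichment <- NULL
    }

    # -- stage 4: FFL motif discovery ----------------------------------
    res$tf_map <- mapTfTargets(bundle$tfbs, bundle$tss, bundle$mrna_expr,
                               halfwidth = config@promoter_halfwidth,
                               tf_expr_min = config@tf_expression_log2)
    if (length(res$retained_mirnas) && length(res$clusters)) {
        res$ffl <- fflDiscovery(res$retained_mirnas, res$target_map,
                                res$tf_map, bundle$ppi,
                                de_genes = res$de_mrna_sig$feature,
                                clusters = res$clusters,
                                ffl_fdr = config@ffl_fdr)
        emit(res$ffl$pairs, "ffl_pairs")
        emit(res$ffl$records, "ffl_records")
        res$coexpression <- emit(
            coexpressionEval(res$ffl$records, bundle$mrna_expr,
                             B = config@n_permutations,
                             seed = subSeed(config@seed, 3)),
            "coexpression")
    } else {
        warning("no retained miRNAs or clustered targets; ",
                "skipping motif discovery")
        res$ffl <- list(pairs = emptyPairs(), records = emptyRecords())
        res$coexpression <- NULL
    }

    # -- stage 5: networks ---------------------------------------------
    lfc_map <- c(stats::setNames(res$de_mirna$log2fc, res$de_mirna$feature),
                 stats::setNames(res$de_mrna$log2fc, res$de_mrna$feature))
    de_feats <- c(res$de_mirna_sig$feature, res$de_mrna_sig$feature)
    res$networks <- list()
    for (cl in sort(unique(res$ffl$records$cluster))) {
        recs <- res$ffl$records[res$ffl$records$cluster == cl, ,
                                drop = FALSE]
        net <- mergeMotifs(recs, lfc = lfc_map[names(lfc_map) %in%
                                               de_feats],
                           tf_map = res$tf_map, cluster_id = cl)
        hubs <- callHubs(net,
                         fraction_mirna = config@hub_fraction_mirna,
                         fraction_tf = config@hub_fraction_tf,
                         fraction_target = config@hub_fraction_target)
        mods <- walktrapModules(net)
        sets <- annotationToSets(bundle$annotation, bundle$dag)
        mod_anno <- annotateModules(net, mods, sets,
                                    enrich_fdr = config@enrich_fdr)
        res$networks[[cl]] <- list(network = net, hubs = hubs,
                                   modules = mods,
                                   module_annotation = mod_anno)
        emit(hubs, paste0("network_", cl, "_nodes"))
        emit(mod_anno, paste0("network_", cl, "_modules"))
        if (!is.null(outdir))
            writeNetwork(net, file.path(outdir,
                                        paste0("network_", cl, ".graphml")),
                         format = "graphml")
    }
    res
}
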