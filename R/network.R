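# Merging significant FFL motifs into typed co-regulatory networks and the
# downstream structural analyses: centralities, hub calling, random-walk
# community detection and per-module functional annotation.

#' Merge FFL records into a co-regulatory network
#'
#' Takes the motif instances of one functional cluster and forms the union
#' graph. Node types: \code{mirna}, \code{tf}, \code{primary_target},
#' \code{secondary_target} (a gene that is primary in one motif and
#' secondary in another is typed primary — the regulatory role dominates).
#' Edge kinds: \code{mirna_target} (miRNA-primary), \code{tf_target}
#' (TF-common/secondary target, and TF-miRNA when the TF has a binding
#' site in the miRNA's promoter), \code{ppi} (primary-secondary). Parallel
#' edges between a node pair collapse to a single edge with kind priority
#' mirna_target > tf_target > ppi.
#'
#' @param records FFL record table for one cluster
#'   (\code{\link{fflDiscovery}}).
#' @param lfc named numeric vector, feature -> log2FC (features missing
#'   from it get 0 and \code{de = FALSE}).
#' @param tf_map optional \code{\link{mapTfTargets}} result used to add
#'   TF-miRNA regulatory edges.
#' @param cluster_id cluster label.
#' @return a \linkS4class{CoRegNetwork}.
#' @export
mergeMotifs <- function(records, lfc = numeric(0), tf_map = NULL,
                        cluster_id = "C1") {
    edges <- list()
    addEdge <- function(a, b, kind)
        edges[[length(edges) + 1]] <<- data.frame(a = a, b = b, kind = kind,
                                                  stringsAsFactors = FALSE)
    types <- character(0)
    setType <- function(id, type) {
        prio <- c(mirna = 1, tf = 2, primary_target = 3,
                  secondary_target = 4)
        cur <- types[id]
        if (is.na(cur) || prio[[type]] < prio[[cur]]) types[id] <<- type
    }
    for (i in seq_len(nrow(records))) {
        m <- records$mirna[i]; f <- records$tf[i]
        g <- records$primary[i]; s <- records$secondary[i]
        setType(m, "mirna"); setType(f, "tf")
        setType(g, "primary_target")
        addEdge(m, g, "mirna_target")
        if (records$motif[i] == "ffl3") {
            addEdge(f, g, "tf_target")
        } else {
            setType(s, "secondary_target")
            addEdge(f, s, "tf_target")
            addEdge(g, s, "ppi")
        }
        if (!is.null(tf_map) && m %in% tf_map$mirna_targets[[f]])
            addEdge(f, m, "tf_target")
    }
    if (!length(edges)) {
        g <- igraph::make_empty_graph(0, directed = FALSE)
        return(new("CoRegNetwork", graph = g, cluster_id = cluster_id))
    }
    ed <- do.call(rbind, edges)
    swap <- ed$a > ed$b
    tmp <- ed$a[swap]; ed$a[swap] <- ed$b[swap]; ed$b[swap] <- tmp
    kind_prio <- c(mirna_target = 1, tf_target = 2, ppi = 3)
    ed <- ed[order(ed$a, ed$b, kind_prio[ed$kind]), , drop = FALSE]
    ed <- ed[!duplicated(ed[, c("a", "b")]), , drop = FALSE]
    nodes <- sort(unique(c(ed$a, ed$b)))
    lfc_full <- stats::setNames(rep(0, length(nodes)), nodes)
    known <- intersect(nodes, names(lfc))
    lfc_full[known] <- lfc[known]
    g <- igraph::graph_from_data_frame(
        ed, directed = FALSE,
        vertices = data.frame(name = nodes,
                              type = unname(types[nodes]),
                              log2fc = unname(lfc_full),
                              de = nodes %in% known,
                              stringsAsFactors = FALSE))
    new("CoRegNetwork", graph = g, cluster_id = cluster_id)
}

#' Node centralities of a co-regulatory network
#'
#' Degree (undirected neighbor count, edge kinds pooled) and betweenness
#' (exact shortest-path count through each node, unnormalized, undirected).
#'
#' @param net a \linkS4class{CoRegNetwork}.
#' @return data.frame with columns \code{node}, \code{type}, \code{degree},
#'   \code{betweenness}.
#' @export
centralities <- function(net) {
    g <- networkGraph(net)
    if (!igraph::gorder(g))
        return(data.frame(node = character(0), type = character(0),
                          degree = numeric(0), betweenness = numeric(0)))
    data.frame(node = igraph::V(g)$name,
               type = igraph::V(g)$type,
               degree = unname(igraph::degree(g)),
               betweenness = unname(igraph::betweenness(
                   g, directed = FALSE, normalized = FALSE)),
               stringsAsFactors = FALSE)
}

#' Call network hubs per node type
#'
#' Ranks nodes within their type by degree (descending; ties broken by
#' betweenness, then id) and flags the top \code{ceil(fraction * count)}
#' as hubs. Primary and secondary targets are pooled as "target" and share
#' \code{fraction_target}.
#'
#' @param net a \linkS4class{CoRegNetwork}.
#' @param fraction_mirna,fraction_tf,fraction_target top-degree fractions.
#' @return the \code{\link{centralities}} table with added \code{hub_type}
#'   and logical \code{hub} columns.
#' @export
callHubs <- function(net, fraction_mirna = 0.25, fraction_tf = 0.25,
                     fraction_target = 0.05) {
    stopifnot(fraction_mirna > 0, fraction_mirna <= 1,
              fraction_tf > 0, fraction_tf <= 1,
              fraction_target > 0, fraction_target <= 1)
    cent <- centralities(net)
    cent$hub_type <- ifelse(cent$type %in% c("mirna", "tf"), cent$type,
                            "target")
    fr <- c(mirna = fraction_mirna, tf = fraction_tf,
            target = fraction_target)
    cent$hub <- FALSE
    for (ht in unique(cent$hub_type)) {
        ix <- which(cent$hub_type == ht)
        n_hub <- ceiling(fr[[ht]] * length(ix))
        o <- ix[order(-cent$degree[ix], -cent$betweenness[ix],
                      cent$node[ix])]
        cent$hub[o[seq_len(n_hub)]] <- TRUE
    }
    cent
}

#' Random-walk community detection (walktrap)
#'
#' Pons-Latapy agglomerative community detection from t-step random-walk
#' distances with the partition cut at maximum modularity; disconnected
#' components are handled independently by the algorithm.
#'
#' @param net a \linkS4class{CoRegNetwork}.
#' @param steps random-walk length (default 4).
#' @return list with \code{membership} (named node -> module id),
#'   \code{modularity} of the cut, and \code{summary} (per module: id,
#'   nodes, edges, member miRNAs and TFs).
#' @export
walktrapModules <- function(net, steps = 4) {
    g <- networkGraph(net)
    if (!igraph::gorder(g)) stop("cannot partition an empty network")
    if (igraph::gorder(g) == 1) {
        mem <- stats::setNames(1L, igraph::V(g)$name)
    } else {
        wt <- igraph::cluster_walktrap(g, steps = steps)
        mem <- stats::setNames(as.integer(igraph::membership(wt)),
                               igraph::V(g)$name)
    }
    mods <- sort(unique(mem))
    smry <- do.call(rbind, lapply(mods, function(mm) {
        nd <- names(mem)[mem == mm]
        sub <- igraph::induced_subgraph(g, nd)
        tp <- igraph::V(sub)$type
        data.frame(module = mm, n_nodes = length(nd),
                   n_edges = igraph::gsize(sub),
                   mirnas = paste(sort(igraph::V(sub)$name[tp == "mirna"]),
                                  collapse = ","),
                   tfs = paste(sort(igraph::V(sub)$name[tp == "tf"]),
                               collapse = ","),
                   stringsAsFactors = FALSE)
    }))
    modul <- if (igraph::gorder(g) > 1 && igraph::gsize(g) > 0)
        igraph::modularity(g, mem) else 0
    list(membership = mem, modularity = modul, summary = smry)
}

#' Annotate network modules with their top enriched gene set
#'
#' Per module, runs \code{\link{genesetEnrichment}} of the module's gene
#' nodes (all non-miRNA nodes) against the network-wide gene universe;
#' the label is the top term, or \code{"-"} when nothing passes
#' \code{enrich_fdr}.
#'
#' @param net a \linkS4class{CoRegNetwork}.
#' @param modules result of \code{\link{walktrapModules}}.
#' @param sets named list, term -> genes.
#' @param enrich_fdr FDR threshold for a label to be assigned.
#' @return the module summary table with added \code{label} and \code{p}
#'   columns.
#' @export
annotateModules <- function(net, modules, sets, enrich_fdr = 0.05) {
    g <- networkGraph(net)
    tp <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
    universe <- names(tp)[tp != "mirna"]
    smry <- modules$summary
    smry$label <- "-"
    smry$p <- NA_real_
    for (i in seq_len(nrow(smry))) {
        nd <- names(modules$membership)[modules$membership ==
                                        smry$module[i]]
        genes <- intersect(nd, universe)
        if (!length(genes)) next
        enr <- genesetEnrichment(genes, universe, sets)
        enr <- enr[enr$fdr < enrich_fdr, , drop = FALSE]
        if (nrow(enr)) {
            smry$label[i] <- enr$set[1]
            smry$p[i] <- enr$p[1]
        }
    }
    smry
}
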