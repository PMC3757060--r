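#' @import methods
NULL

#' Pipeline configuration
#'
#' Holds every tunable threshold of the co-regulatory FFL pipeline. Defaults
#' correspond to the published proliferation study design: miRNA differential
#' expression at FDR < 0.05 with |log2FC| >= 1 after keeping the 75% most
#' variable probes; mRNA differential expression at raw p < 0.05 with
#' |log2FC| >= 0.7; TargetScan-like context score <= -0.1; TFs expressed at
#' log2 intensity >= 8 in at least one group; promoter windows of +/-2000 nt
#' around the TSS; FFL pair significance at FDR < 0.2; 1,000 permutations;
#' hub fractions of 25% (miRNAs, TFs) and 5% (targets); FANNY fuzziness grid
#' 1.1-1.5 and cluster-number grid 2-15.
#'
#' @slot mirna_fdr FDR cutoff (strict \code{<}) for DE miRNAs.
#' @slot mirna_abs_lfc minimum |log2FC| (inclusive) for DE miRNAs.
#' @slot mrna_p raw p cutoff (strict \code{<}) for DE mRNAs.
#' @slot mrna_abs_lfc minimum |log2FC| (inclusive) for DE mRNAs.
#' @slot context_score_max maximum (most positive) context score retained.
#' @slot variance_keep_fraction fraction of most-variable miRNA probes kept.
#' @slot tf_expression_log2 minimum group-mean log2 intensity for a TF to
#'   count as expressed.
#' @slot promoter_halfwidth promoter half-width in nucleotides around a TSS.
#' @slot ffl_fdr FDR cutoff (strict \code{<}) for miRNA-TF pair tests.
#' @slot enrich_fdr FDR cutoff for GO/gene-set over-representation.
#' @slot n_permutations permutation count for enrichment-score calibration
#'   and coexpression reference distributions.
#' @slot hub_fraction_mirna,hub_fraction_tf,hub_fraction_target per-type
#'   top-degree fractions called as hubs.
#' @slot fuzziness_grid candidate FANNY fuzziness exponents.
#' @slot k_grid candidate cluster numbers.
#' @slot direction_aware logical; whether enrichment counts only
#'   inverse-direction DE targets (default) or all DE targets.
#' @slot seed integer random seed used by stochastic stages.
#'
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    mirna_fdr = "numeric",
    mirna_abs_lfc = "numeric",
    mrna_p = "numeric",
    mrna_abs_lfc = "numeric",
    context_score_max = "numeric",
    variance_keep_fraction = "numeric",
    tf_expression_log2 = "numeric",
    promoter_halfwidth = "numeric",
    ffl_fdr = "numeric",
    enrich_fdr = "numeric",
    n_permutations = "numeric",
    hub_fraction_mirna = "numeric",
    hub_fraction_tf = "numeric",
    hub_fraction_target = "numeric",
    fuzziness_grid = "numeric",
    k_grid = "numeric",
    direction_aware = "logical",
    seed = "numeric"
))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    fr <- c(variance_keep_fraction = object@variance_keep_fraction,
            hub_fraction_mirna = object@hub_fraction_mirna,
            hub_fraction_tf = object@hub_fraction_tf,
            hub_fraction_target = object@hub_fraction_target)
    bad <- fr[!(fr > 0 & fr <= 1)]
    if (length(bad))
        msg <- c(msg, paste0("fractions must be in (0,1]: ",
                             paste(names(bad), collapse = ", ")))
    if (object@n_permutations < 1)
        msg <- c(msg, "n_permutations must be >= 1")
    if (!length(object@fuzziness_grid) || !length(object@k_grid))
        msg <- c(msg, "fuzziness_grid and k_grid must be non-empty")
    if (any(object@fuzziness_grid <= 1))
        msg <- c(msg, "fuzziness exponents must be > 1")
    if (any(object@k_grid < 2))
        msg <- c(msg, "cluster numbers must be >= 2")
    if (object@promoter_halfwidth <= 0)
        msg <- c(msg, "promoter_halfwidth must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' @param ... named overrides of any \linkS4class{PipelineConfig} slot.
#' @return a validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(seed = 7, n_permutations = 200)
#' @export
pipelineConfig <- function(...) {
    defaults <- list(
        mirna_fdr = 0.05, mirna_abs_lfc = 1.0,
        mrna_p = 0.05, mrna_abs_lfc = 0.7,
        context_score_max = -0.1,
        variance_keep_fraction = 0.75,
        tf_expression_log2 = 8.0,
        promoter_halfwidth = 2000,
        ffl_fdr = 0.2, enrich_fdr = 0.05,
        n_permutations = 1000,
        hub_fraction_mirna = 0.25, hub_fraction_tf = 0.25,
        hub_fraction_target = 0.05,
        fuzziness_grid = seq(1.1, 1.5, by = 0.1),
        k_grid = 2:15,
        direction_aware = TRUE,
        seed = 1
    )
    ov <- list(...)
    unknown <- setdiff(names(ov), names(defaults))
    if (length(unknown))
        stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
    defaults[names(ov)] <- ov
    do.call(new, c(list("PipelineConfig"), defaults))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  DE miRNA: FDR <", object@mirna_fdr, "& |log2FC| >=",
        object@mirna_abs_lfc, "(top", object@variance_keep_fraction * 100,
        "% variable probes)\n")
    cat("  DE mRNA : p <", object@mrna_p, "& |log2FC| >=",
        object@mrna_abs_lfc, "\n")
    cat("  targets : context score <=", object@context_score_max, "\n")
    cat("  TF      : expressed log2 >=", object@tf_expression_log2,
        "; promoter +/-", object@promoter_halfwidth, "nt\n")
    cat("  FFL     : FDR <", object@ffl_fdr, ";",
        object@n_permutations, "permutations; seed", object@seed, "\n")
})

#' Parameters of the synthetic-data generator
#'
#' Describes a planted-ground-truth study: a two-group design (defaults
#' mirror a 4 high / 3 low proliferation cell-line panel), differentially
#' expressed miRNAs split between up and down with Gaussian log2 effects,
#' inversely regulated functional targets, planted 3-node and 4-node FFLs,
#' a background PPI, and a two-branch GO toy ontology giving targets a
#' "metabolic-like" or "signaling-like" functional identity.
#'
#' @slot n_samples_high,n_samples_low group sizes.
#' @slot n_mirnas,n_genes,n_tfs feature counts (TFs are additional rows of
#'   the mRNA matrix).
#' @slot n_de_mirnas_up,n_de_mirnas_down planted DE miRNA counts.
#' @slot de_lfc_mean,de_lfc_sd planted |log2FC| distribution.
#' @slot baseline_mean,noise_sd baseline log2 intensity and i.i.d. Gaussian
#'   noise SD (log2 units).
#' @slot targets_per_mirna predicted targets per miRNA.
#' @slot fraction_functional_targets fraction of a DE miRNA's predicted
#'   targets given a planted inverse group effect.
#' @slot n_planted_ffl3,n_planted_ffl4 planted (miRNA, TF) FFL pairs.
#' @slot ppi_background_edge_prob background PPI edge probability.
#' @slot go_depth depth of each of the two GO branches.
#' @slot go_annotation_noise probability a functional target is annotated
#'   into the wrong branch.
#' @slot seed integer seed.
#'
#' @exportClass SimulationParams
setClass("SimulationParams", representation(
    n_samples_high = "numeric", n_samples_low = "numeric",
    n_mirnas = "numeric", n_genes = "numeric", n_tfs = "numeric",
    n_de_mirnas_up = "numeric", n_de_mirnas_down = "numeric",
    de_lfc_mean = "numeric", de_lfc_sd = "numeric",
    baseline_mean = "numeric", noise_sd = "numeric",
    targets_per_mirna = "numeric",
    fraction_functional_targets = "numeric",
    n_planted_ffl3 = "numeric", n_planted_ffl4 = "numeric",
    ppi_background_edge_prob = "numeric",
    go_depth = "numeric", go_annotation_noise = "numeric",
    seed = "numeric"
))

setValidity("SimulationParams", function(object) {
    msg <- character()
    cnt <- c(object@n_samples_high, object@n_samples_low, object@n_mirnas,
             object@n_genes, object@n_tfs, object@targets_per_mirna,
             object@go_depth)
    if (any(cnt < 1)) msg <- c(msg, "counts must be positive")
    if (object@n_de_mirnas_up + object@n_de_mirnas_down > object@n_mirnas)
        msg <- c(msg, "planted DE miRNAs exceed n_mirnas")
    fr <- c(object@fraction_functional_targets, object@go_annotation_noise,
            object@ppi_background_edge_prob)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0,1]")
    if (object@noise_sd < 0 || object@de_lfc_sd < 0)
        msg <- c(msg, "standard deviations must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param ... named overrides of any \linkS4class{SimulationParams} slot.
#' @return a validated \linkS4class{SimulationParams}.
#' @examples
#' sp <- simulationParams(seed = 11, n_genes = 100)
#' @export
simulationParams <- function(...) {
    defaults <- list(
        n_samples_high = 4, n_samples_low = 3,
        n_mirnas = 60, n_genes = 250, n_tfs = 12,
        n_de_mirnas_up = 8, n_de_mirnas_down = 9,
        de_lfc_mean = 2, de_lfc_sd = 0.25,
        baseline_mean = 9, noise_sd = 0.5,
        targets_per_mirna = 30,
        fraction_functional_targets = 0.5,
        n_planted_ffl3 = 6, n_planted_ffl4 = 5,
        ppi_background_edge_prob = 0.01,
        go_depth = 3, go_annotation_noise = 0.05,
        seed = 1
    )
    ov <- list(...)
    unknown <- setdiff(names(ov), names(defaults))
    if (length(unknown))
        stop("unknown simulation fields: ", paste(unknown, collapse = ", "))
    defaults[names(ov)] <- ov
    do.call(new, c(list("SimulationParams"), defaults))
}

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@n_samples_high, "high +",
        object@n_samples_low, "low samples;",
        object@n_mirnas, "miRNAs,", object@n_genes, "genes,",
        object@n_tfs, "TFs\n")
    cat("  planted:", object@n_de_mirnas_up, "up +",
        object@n_de_mirnas_down, "down DE miRNAs (|lfc| ~ N(",
        object@de_lfc_mean, ",", object@de_lfc_sd, ")), noise sd",
        object@noise_sd, "\n")
    cat("  planted FFL pairs:", object@n_planted_ffl3, "3-node,",
        object@n_planted_ffl4, "4-node; seed", object@seed, "\n")
})

#' Gene Ontology DAG (is_a subset)
#'
#' A minimal directed acyclic graph over ontology terms: each term maps to
#' its set of \code{is_a} parents within one namespace with a single root.
#'
#' @slot parents named list, term id -> character vector of parent ids
#'   (empty for the root).
#' @slot namespace single namespace tag (for example
#'   \code{"biological_process"}).
#' @slot root the root term id.
#'
#' @exportClass GODag
setClass("GODag", representation(
    parents = "list", namespace = "character", root = "character"
))

setValidity("GODag", function(object) {
    msg <- character()
    ids <- names(object@parents)
    if (!(object@root %in% ids)) msg <- c(msg, "root not among terms")
    else if (length(object@parents[[object@root]]))
        msg <- c(msg, "root must have no parents")
    all_par <- unique(unlist(object@parents))
    if (length(all_par) && !all(all_par %in% ids))
        msg <- c(msg, "parent ids missing from term set")
    # acyclicity + root reachability by iterative ancestor closure
    if (!length(msg)) {
        for (id in ids) {
            seen <- character(); frontier <- id
            repeat {
                nxt <- setdiff(unique(unlist(object@parents[frontier])), seen)
                if (!length(nxt)) break
                if (id %in% nxt) { msg <- c(msg, "cycle detected"); break }
                seen <- c(seen, nxt); frontier <- nxt
            }
            if (length(msg)) break
            if (id != object@root && !(object@root %in% seen)) {
                msg <- c(msg, paste0("term ", id, " does not reach the root"))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GODag", function(object) {
    cat("GODag:", length(object@parents), "terms, namespace",
        object@namespace, ", root", object@root, "\n")
})

#' Fuzzy clustering result
#'
#' Result of FANNY fuzzy clustering on a dissimilarity matrix: the
#' membership matrix, the fuzziness exponent, the Dunn partition coefficient
#' (raw and normalized) measuring crispness, the Dunn separation index of
#' the induced hard partition, and per-item hard labels and membership
#' strengths.
#'
#' @slot membership items x k matrix, rows summing to 1.
#' @slot fuzziness the exponent r (> 1).
#' @slot k cluster count.
#' @slot dunn_coeff,dunn_coeff_norm Dunn partition coefficient Fc and its
#'   normalization Fc' = (k Fc - 1)/(k - 1).
#' @slot dunn_index min between-cluster separation / max within diameter.
#' @slot labels per-item hard labels (argmax membership).
#' @slot strength per-item maximum membership.
#' @slot objective final value of the FANNY objective.
#'
#' @exportClass FuzzyClustering
setClass("FuzzyClustering", representation(
    membership = "matrix", fuzziness = "numeric", k = "numeric",
    dunn_coeff = "numeric", dunn_coeff_norm = "numeric",
    dunn_index = "numeric", labels = "integer", strength = "numeric",
    objective = "numeric"
))

setValidity("FuzzyClustering", function(object) {
    U <- object@membership
    msg <- character()
    if (any(U < -1e-9 | U > 1 + 1e-9))
        msg <- c(msg, "memberships must lie in [0,1]")
    if (any(abs(rowSums(U) - 1) > 1e-6))
        msg <- c(msg, "membership rows must sum to 1")
    if (ncol(U) != object@k) msg <- c(msg, "k does not match membership")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FuzzyClustering", function(object) {
    cat("FuzzyClustering: n =", nrow(object@membership),
        ", k =", object@k, ", r =", object@fuzziness, "\n")
    cat("  Dunn coefficient", round(object@dunn_coeff, 3),
        "(normalized", paste0(round(object@dunn_coeff_norm, 3), ")"),
        "; Dunn index", round(object@dunn_index, 3), "\n")
    print(table(cluster = object@labels))
})

#' Typed miRNA-TF co-regulatory network
#'
#' An undirected typed graph produced by merging significant FFL motifs.
#' Nodes carry a type (\code{mirna}, \code{tf}, \code{primary_target},
#' \code{secondary_target}), a log2 fold change and a DE flag; edges carry a
#' kind (\code{mirna_target}, \code{tf_target}, \code{ppi}).
#'
#' @slot graph an \code{igraph} object holding the attributed graph.
#' @slot cluster_id label of the functional cluster the network derives from.
#'
#' @exportClass CoRegNetwork
setClass("CoRegNetwork", representation(
    graph = "ANY", cluster_id = "character"
))

setValidity("CoRegNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
    msg <- character()
    if (igraph::gorder(g) > 0) {
        tp <- igraph::V(g)$type
        if (is.null(tp) || any(!tp %in%
                c("mirna", "tf", "primary_target", "secondary_target")))
            msg <- c(msg, "all nodes need a valid 'type' attribute")
    }
    if (igraph::gsize(g) > 0) {
        kd <- igraph::E(g)$kind
        if (is.null(kd) || any(!kd %in% c("mirna_target", "tf_target", "ppi")))
            msg <- c(msg, "all edges need a valid 'kind' attribute")
        if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
            msg <- c(msg, "graph must be simple")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CoRegNetwork", function(object) {
    g <- object@graph
    cat("CoRegNetwork [", object@cluster_id, "]: ",
        igraph::gorder(g), " nodes, ", igraph::gsize(g), " edges\n", sep = "")
    if (igraph::gorder(g) > 0)
        print(table(type = igraph::V(g)$type))
})
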