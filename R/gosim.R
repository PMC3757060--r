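# Resnik information-content semantic similarity over the GO is_a DAG and
# its aggregation to gene-level functional similarity.

ancestorsWithSelf <- function(dag, term) c(term, termAncestors(dag, term))

#' Information content of ontology terms
#'
#' Annotations are propagated to ancestors; the probability of a term is
#' the fraction of annotated genes carrying the term or any descendant,
#' and IC(t) = -ln p(t). The root always has IC 0. Terms with no annotated
#' gene after propagation have undefined IC and are dropped (logged).
#'
#' @param annotation named list, gene -> character vector of term ids.
#' @param dag a \linkS4class{GODag}.
#' @return named numeric vector of IC values (natural log units) for every
#'   term with non-zero annotation.
#' @export
informationContent <- function(annotation, dag) {
    if (!length(annotation)) stop("empty annotation set")
    bad <- setdiff(unique(unlist(annotation)), dagTerms(dag))
    if (length(bad))
        stop("annotated terms missing from DAG: ",
             paste(utils::head(bad, 5), collapse = ", "))
    counts <- stats::setNames(integer(length(dagTerms(dag))), dagTerms(dag))
    for (terms in annotation) {
        prop <- unique(unlist(lapply(terms, ancestorsWithSelf, dag = dag)))
        counts[prop] <- counts[prop] + 1L
    }
    n_genes <- length(annotation)
    dropped <- names(counts)[counts == 0]
    if (length(dropped))
        logFilter("IC: terms with annotation", length(counts),
                  sum(counts > 0), "(zero-annotation terms dropped)")
    ic <- -log(counts[counts > 0] / n_genes)
    ic[dag@root] <- 0
    ic
}

# Resnik term-pair similarity: IC of the maximum-IC common ancestor
termSimilarity <- function(t1, t2, dag, ic) {
    common <- intersect(ancestorsWithSelf(dag, t1), ancestorsWithSelf(dag, t2))
    common <- intersect(common, names(ic))
    if (!length(common)) return(0)
    max(ic[common])
}

#' Gene-level Resnik functional similarity
#'
#' Term pairs are scored by the IC of their maximum-IC common ancestor
#' (MICA); gene pairs aggregate term scores by best-match average (mean
#' over one gene's terms of the maximum similarity to the other's,
#' symmetrized) or by the maximum over all term pairs.
#'
#' @param genes character vector of annotated gene ids.
#' @param annotation named list, gene -> terms.
#' @param dag a \linkS4class{GODag}.
#' @param aggregate \code{"bma"} (default) or \code{"max"}.
#' @return list with \code{sim} (symmetric similarity matrix) and
#'   \code{dis} (dissimilarity \code{max(sim) - sim}, zero diagonal).
#' @export
geneSimilarityMatrix <- function(genes, annotation, dag,
                                 aggregate = c("bma", "max")) {
    aggregate <- match.arg(aggregate)
    unann <- genes[!genes %in% names(annotation) |
                   !vapply(annotation[genes], function(x)
                       length(x) > 0, logical(1))]
    if (length(unann))
        stop("unannotated genes must be excluded upstream: ",
             paste(utils::head(unann, 5), collapse = ", "))
    ic <- informationContent(annotation, dag)
    terms_used <- unique(unlist(annotation[genes]))
    terms_used <- intersect(terms_used, names(ic))
    ts <- matrix(0, length(terms_used), length(terms_used),
                 dimnames = list(terms_used, terms_used))
    for (i in seq_along(terms_used))
        for (j in i:length(terms_used))
            ts[i, j] <- ts[j, i] <-
                termSimilarity(terms_used[i], terms_used[j], dag, ic)
    n <- length(genes)
    S <- matrix(0, n, n, dimnames = list(genes, genes))
    tsets <- lapply(annotation[genes], intersect, x = terms_used)
    for (i in seq_len(n)) {
        for (j in i:n) {
            block <- ts[tsets[[i]], tsets[[j]], drop = FALSE]
            s <- if (aggregate == "max") max(block)
                 else (mean(apply(block, 1, max)) +
                       mean(apply(block, 2, max))) / 2
            S[i, j] <- S[j, i] <- s
        }
    }
    D <- max(S) - S
    diag(D) <- 0
    list(sim = S, dis = D)
}
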