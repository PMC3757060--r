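#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' \code{membership} returns the fuzzy membership matrix;
#' \code{hardLabels} the argmax cluster labels; \code{networkGraph} the
#' underlying \code{igraph} object of a \linkS4class{CoRegNetwork};
#' \code{dagTerms} the term ids of a \linkS4class{GODag};
#' \code{termParents} the direct \code{is_a} parents of a term;
#' \code{termAncestors} the proper ancestors (excluding the term itself);
#' \code{configSlot} a named configuration value.
#'
#' @param object an object of the documented class.
#' @param term a term id.
#' @param name a \linkS4class{PipelineConfig} slot name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname accessors
#' @export
setMethod("membership", "FuzzyClustering", function(object) object@membership)

#' @rdname accessors
#' @export
setGeneric("hardLabels", function(object) standardGeneric("hardLabels"))

#' @rdname accessors
#' @export
setMethod("hardLabels", "FuzzyClustering", function(object) {
    structure(object@labels, names = rownames(object@membership))
})

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setMethod("networkGraph", "CoRegNetwork", function(object) object@graph)

#' @rdname accessors
#' @export
setGeneric("dagTerms", function(object) standardGeneric("dagTerms"))

#' @rdname accessors
#' @export
setMethod("dagTerms", "GODag", function(object) names(object@parents))

#' @rdname accessors
#' @export
setGeneric("termParents", function(object, term) standardGeneric("termParents"))

#' @rdname accessors
#' @export
setMethod("termParents", "GODag", function(object, term) {
    if (!term %in% names(object@parents))
        stop("unknown term: ", term)
    object@parents[[term]]
})

#' @rdname accessors
#' @export
setGeneric("termAncestors", function(object, term)
    standardGeneric("termAncestors"))

#' @rdname accessors
#' @export
setMethod("termAncestors", "GODag", function(object, term) {
    if (!term %in% names(object@parents))
        stop("unknown term: ", term)
    seen <- character(); frontier <- term
    repeat {
        nxt <- setdiff(unique(unlist(object@parents[frontier])), seen)
        if (!length(nxt)) break
        seen <- c(seen, nxt); frontier <- nxt
    }
    seen
})

#' @rdname accessors
#' @export
setGeneric("configSlot", function(object, name) standardGeneric("configSlot"))

#' @rdname accessors
#' @export
setMethod("configSlot", "PipelineConfig", function(object, name) {
    if (!name %in% slotNames(object)) stop("unknown config slot: ", name)
    slot(object, name)
})
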