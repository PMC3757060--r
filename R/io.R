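# Readers and writers for the pipeline's plain-text interchange formats.
# Internal genomic coordinates are 0-based half-open throughout; BED-like
# inputs are consumed as-is and 1-based closed inputs are converted at the
# boundary ([a,b] -> [a-1, b)).

#' Construct an expression matrix with a two-level group factor
#'
#' @param values numeric matrix of log2 intensities, features x samples,
#'   with row and column names.
#' @param groups named character/factor of "high"/"low" per sample.
#' @return a list of class \code{ExpressionMatrix} with elements
#'   \code{values} and \code{groups}.
#' @export
expressionMatrix <- function(values, groups) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix needs feature and sample names")
    if (anyDuplicated(rownames(values)))
        stop("duplicate feature ids in expression matrix")
    groups <- groups[colnames(values)]
    if (any(is.na(groups)))
        stop("every sample needs a group assignment")
    groups <- factor(as.character(groups), levels = c("high", "low"))
    names(groups) <- colnames(values)
    if (any(is.na(groups)))
        stop("groups must be 'high' or 'low'")
    if (any(table(groups) < 2))
        stop("each group needs >=2 samples")
    if (any(!is.finite(values)))
        stop("expression matrix contains missing or non-finite values")
    structure(list(values = values, groups = groups),
              class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
    cat("ExpressionMatrix:", nrow(x$values), "features x",
        ncol(x$values), "samples (",
        sum(x$groups == "high"), "high /", sum(x$groups == "low"), "low )\n")
    invisible(x)
}

#' Read an expression matrix and its sample-group table
#'
#' The matrix file is TSV with the feature id in the first column and sample
#' ids in the header; the group file is a two-column TSV (sample, group)
#' with groups \code{high}/\code{low}.
#'
#' @param values_file,groups_file file paths.
#' @param missing \code{"reject"} (default) errors on missing entries;
#'   \code{"impute"} replaces them by the feature's mean.
#' @return an \code{\link{expressionMatrix}}.
#' @export
readExpression <- function(values_file, groups_file,
                           missing = c("reject", "impute")) {
    missing <- match.arg(missing)
    tab <- utils::read.delim(values_file, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
        stop("malformed expression file (need id column + samples): ",
             values_file)
    values <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(values))
        stop("non-numeric expression values in ", values_file)
    rownames(values) <- as.character(tab[[1]])
    if (anyNA(values)) {
        if (missing == "reject")
            stop("missing values in ", values_file,
                 " (set missing='impute' to mean-impute)")
        for (i in which(rowSums(is.na(values)) > 0)) {
            mu <- mean(values[i, ], na.rm = TRUE)
            values[i, is.na(values[i, ])] <- mu
        }
    }
    grp <- utils::read.delim(groups_file, header = TRUE,
                             stringsAsFactors = FALSE)
    if (ncol(grp) < 2) stop("malformed group file: ", groups_file)
    groups <- stats::setNames(as.character(grp[[2]]), as.character(grp[[1]]))
    expressionMatrix(values, groups)
}

writeExpression <- function(expr, values_file, groups_file) {
    df <- data.frame(feature = rownames(expr$values), expr$values,
                     check.names = FALSE)
    utils::write.table(df, values_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
        data.frame(sample = names(expr$groups),
                   group = as.character(expr$groups)),
        groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a miRNA target-prediction table
#'
#' Three-column TSV (mirna, gene, context_score). Duplicate (mirna, gene)
#' pairs are collapsed to the strongest (minimum) context score; rows with a
#' non-finite score are rejected and counted.
#'
#' @param file path.
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{context_score}.
#' @export
readTargetPredictions <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("malformed prediction file: ", file)
    names(tab)[1:3] <- c("mirna", "gene", "context_score")
    tab$context_score <- as.numeric(tab$context_score)
    n0 <- nrow(tab)
    bad <- !is.finite(tab$context_score)
    if (any(bad)) tab <- tab[!bad, , drop = FALSE]
    logFilter("predictions: finite score", n0, nrow(tab))
    # keep the most repressive (minimum) score per pair
    o <- order(tab$mirna, tab$gene, tab$context_score)
    tab <- tab[o, , drop = FALSE]
    dup <- duplicated(tab[, c("mirna", "gene")])
    if (any(dup)) {
        logFilter("predictions: dedup (min score)", nrow(tab), sum(!dup))
        tab <- tab[!dup, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab[, c("mirna", "gene", "context_score")]
}

#' Read a BED-like TFBS table
#'
#' Four-column TSV (tf, chrom, start, end), 0-based half-open by default.
#' Rows with \code{start >= end} or negative coordinates are rejected with a
#' count.
#'
#' @param file path.
#' @param oneBased set TRUE for 1-based closed input; intervals are
#'   converted to 0-based half-open (\code{[a,b] -> [a-1,b)}).
#' @return data.frame with columns \code{tf}, \code{chrom}, \code{start},
#'   \code{end}.
#' @export
readTFBS <- function(file, oneBased = FALSE) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (ncol(tab) < 4) stop("malformed TFBS file: ", file)
    names(tab)[1:4] <- c("tf", "chrom", "start", "end")
    tab$start <- as.numeric(tab$start); tab$end <- as.numeric(tab$end)
    if (oneBased) tab$start <- tab$start - 1
    n0 <- nrow(tab)
    ok <- is.finite(tab$start) & is.finite(tab$end) &
        tab$start >= 0 & tab$start < tab$end
    tab <- tab[ok, , drop = FALSE]
    logFilter("TFBS: valid intervals", n0, nrow(tab))
    rownames(tab) <- NULL
    tab[, c("tf", "chrom", "start", "end")]
}

#' Read a TSS annotation table
#'
#' Five-column TSV (feature, kind, chrom, tss, strand) with kind in
#' \code{gene}/\code{mirna}, 0-based TSS positions and strand \code{+}/
#' \code{-}. A feature listed with several TSSs keeps the first (logged).
#'
#' @param file path.
#' @return data.frame with one row per feature.
#' @export
readTSS <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (ncol(tab) < 5) stop("malformed TSS file: ", file)
    names(tab)[1:5] <- c("feature", "kind", "chrom", "tss", "strand")
    tab$tss <- as.numeric(tab$tss)
    n0 <- nrow(tab)
    ok <- tab$kind %in% c("gene", "mirna") & tab$strand %in% c("+", "-") &
        is.finite(tab$tss) & tab$tss >= 0
    tab <- tab[ok, , drop = FALSE]
    logFilter("TSS: valid rows", n0, nrow(tab))
    dup <- duplicated(tab$feature)
    if (any(dup)) {
        logFilter("TSS: first TSS per feature", nrow(tab), sum(!dup))
        tab <- tab[!dup, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab[, c("feature", "kind", "chrom", "tss", "strand")]
}

#' Read an undirected PPI edge list
#'
#' Two-column TSV. Self-loops are dropped and edges deduplicated
#' irrespective of order.
#'
#' @param file path.
#' @return data.frame with columns \code{a}, \code{b}, each edge once with
#'   \code{a < b} lexicographically.
#' @export
readPPI <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed PPI file: ", file)
    names(tab)[1:2] <- c("a", "b")
    tab$a <- as.character(tab$a); tab$b <- as.character(tab$b)
    normalizePPI(tab, src = file)
}

normalizePPI <- function(tab, src = "ppi") {
    n0 <- nrow(tab)
    tab <- tab[tab$a != tab$b, c("a", "b"), drop = FALSE]
    swap <- tab$a > tab$b
    tmp <- tab$a[swap]; tab$a[swap] <- tab$b[swap]; tab$b[swap] <- tmp
    tab <- tab[!duplicated(tab), , drop = FALSE]
    logFilter("PPI: simple undirected edges", n0, nrow(tab))
    rownames(tab) <- NULL
    tab
}

#' Read a GMT gene-set file
#'
#' @param file path; each line: set id, description, tab-separated genes.
#' @return named list, set id -> character vector of genes.
#' @export
readGMT <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("malformed GMT line: ", substr(l, 1, 60))
        unique(parts[-(1:2)])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    sets
}

#' Read GAF-lite gene annotations
#'
#' Three-column TSV (gene, term, namespace); only rows matching
#' \code{namespace} are kept.
#'
#' @param file path.
#' @param namespace namespace filter (default biological_process).
#' @return named list, gene -> character vector of term ids.
#' @export
readGAF <- function(file, namespace = "biological_process") {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("malformed GAF-lite file: ", file)
    names(tab)[1:3] <- c("gene", "term", "namespace")
    tab <- tab[tab$namespace == namespace, , drop = FALSE]
    split(tab$term, tab$gene) |> lapply(unique)
}

#' Read an OBO subset into a GODag
#'
#' Parses only \code{id:}, \code{is_a:} and \code{namespace:} tags of
#' \code{[Term]} stanzas, retaining one namespace.
#'
#' @param file path.
#' @param namespace namespace to retain.
#' @return a \linkS4class{GODag}.
#' @export
readOBO <- function(file, namespace = "biological_process") {
    lines <- readLines(file)
    parents <- list(); cur <- NULL; cur_ns <- NA_character_
    cur_parents <- character(); in_term <- FALSE
    flush <- function() {
        if (!is.null(cur) && identical(cur_ns, namespace))
            parents[[cur]] <<- cur_parents
    }
    for (l in lines) {
        l <- trimws(l)
        if (l == "[Term]") {
            flush(); cur <- NULL; cur_ns <- NA_character_
            cur_parents <- character(); in_term <- TRUE
        } else if (grepl("^\\[", l)) {
            flush(); in_term <- FALSE; cur <- NULL
        } else if (in_term && startsWith(l, "id:")) {
            cur <- trimws(sub("^id:", "", l))
        } else if (in_term && startsWith(l, "namespace:")) {
            cur_ns <- trimws(sub("^namespace:", "", l))
        } else if (in_term && startsWith(l, "is_a:")) {
            tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
            cur_parents <- c(cur_parents, tgt)
        }
    }
    flush()
    if (!length(parents)) stop("no terms in namespace '", namespace,
                               "' found in ", file)
    # parents outside the namespace subset are dropped at the boundary
    ids <- names(parents)
    parents <- lapply(parents, function(p) intersect(p, ids))
    roots <- ids[vapply(parents, length, 1L) == 0]
    if (length(roots) != 1)
        stop("expected a single root, found: ", paste(roots, collapse = ", "))
    new("GODag", parents = parents, namespace = namespace, root = roots)
}

#' Write a GODag as an OBO subset
#'
#' @param dag a \linkS4class{GODag}.
#' @param file output path.
#' @export
writeOBO <- function(dag, file) {
    con <- file(file, "w"); on.exit(close(con))
    writeLines("format-version: 1.2", con)
    for (id in names(dag@parents)) {
        writeLines(c("", "[Term]", paste0("id: ", id),
                     paste0("namespace: ", dag@namespace),
                     paste0("is_a: ", dag@parents[[id]])), con)
    }
    invisible(NULL)
}

#' Write a co-regulatory network to file
#'
#' Supported formats: \code{graphml} (full attributes, round-trippable),
#' \code{sif} (node-kind-node triples), \code{tsv} (a node table
#' \code{<file>.nodes.tsv} and an edge table \code{<file>}).
#'
#' @param net a \linkS4class{CoRegNetwork}.
#' @param file output path.
#' @param format one of \code{"graphml"}, \code{"sif"}, \code{"tsv"}.
#' @export
writeNetwork <- function(net, file, format = c("graphml", "sif", "tsv")) {
    if (!format[1] %in% c("graphml", "sif", "tsv"))
        stop("unknown format '", format[1],
             "'; supported: graphml, sif, tsv")
    format <- match.arg(format)
    g <- networkGraph(net)
    if (format == "graphml") {
        igraph::write_graph(g, file, format = "graphml")
    } else if (format == "sif") {
        if (igraph::gsize(g) > 0) {
            el <- igraph::as_edgelist(g)
            writeLines(paste(el[, 1], igraph::E(g)$kind, el[, 2],
                             sep = "\t"), file)
        } else {
            # isolated nodes: bare names; empty network: empty file
            nm <- igraph::V(g)$name
            writeLines(if (is.null(nm)) character(0) else nm, file)
        }
    } else {
        nd <- data.frame(node = igraph::V(g)$name,
                         type = igraph::V(g)$type %||%
                             character(igraph::gorder(g)),
                         log2fc = igraph::V(g)$log2fc %||%
                             numeric(igraph::gorder(g)))
        utils::write.table(nd, paste0(file, ".nodes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        el <- igraph::as_edgelist(g)
        ed <- data.frame(a = el[, 1], b = el[, 2],
                         kind = if (igraph::gsize(g)) igraph::E(g)$kind
                                else character(0))
        utils::write.table(ed, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(file)
}

#' Read a GraphML network written by \code{writeNetwork}
#'
#' @param file path.
#' @param cluster_id cluster label to attach.
#' @return a \linkS4class{CoRegNetwork}.
#' @export
readNetworkGraphML <- function(file, cluster_id = "C?") {
    g <- igraph::read_graph(file, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    new("CoRegNetwork", graph = g, cluster_id = cluster_id)
}

#' Load and validate all pipeline inputs
#'
#' @param paths named list of file paths: \code{mirna_expr},
#'   \code{mirna_groups}, \code{mrna_expr}, \code{mrna_groups},
#'   \code{predictions}, \code{tfbs}, \code{tss}, \code{ppi}, \code{gmt} or
#'   \code{gaf}, \code{obo}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return named list of typed inputs (an input bundle).
#' @export
loadInputs <- function(paths, config = pipelineConfig()) {
    need <- c("mirna_expr", "mirna_groups", "mrna_expr", "mrna_groups",
              "predictions", "tfbs", "tss", "ppi", "obo")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p)) stop("file not found: ", p)
    dag <- readOBO(paths$obo)
    annotation <-
        if (!is.null(paths$gaf)) readGAF(paths$gaf)
        else if (!is.null(paths$gmt)) invertSets(readGMT(paths$gmt))
        else stop("need a 'gaf' or 'gmt' annotation path")
    bad <- setdiff(unique(unlist(annotation)), dagTerms(dag))
    if (length(bad))
        stop("annotation terms missing from DAG: ",
             paste(utils::head(bad, 5), collapse = ", "))
    list(
        mirna_expr = readExpression(paths$mirna_expr, paths$mirna_groups),
        mrna_expr = readExpression(paths$mrna_expr, paths$mrna_groups),
        predictions = readTargetPredictions(paths$predictions),
        tfbs = readTFBS(paths$tfbs),
        tss = readTSS(paths$tss),
        ppi = readPPI(paths$ppi),
        annotation = annotation,
        dag = dag,
        config = config
    )
}

# term -> genes  =>  gene -> terms
invertSets <- function(sets) {
    df <- data.frame(term = rep(names(sets), lengths(sets)),
                     gene = unlist(sets, use.names = FALSE))
    split(df$term, df$gene) |> lapply(unique)
}
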