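# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::phyper / stats::p.adjust): brute
# force, enumeration, and direct formula application only.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# upper-tail hypergeometric by full enumeration of all size-n draws from a
# population of N items of which the first K are successes
oracleHyperEnum <- function(k, K, N, n) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)
    mean(hits >= k)
}

# BH step-up by direct definition: adj_i = min over j with p_(j) >= p_(i)
# of m * p_(j) / j, clipped at 1
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(adj_sorted, 1)[order(o)]
}

# exact betweenness by enumerating every shortest path (DFS over the BFS
# predecessor structure) for every unordered pair
oracleBetweenness <- function(adj) {
    n <- nrow(adj)
    btw <- numeric(n)
    for (s in 1:(n - 1)) {
        # BFS from s
        dist <- rep(Inf, n); dist[s] <- 0
        frontier <- s
        while (length(frontier)) {
            nxt <- integer(0)
            for (u in frontier) for (v in which(adj[u, ] == 1))
                if (dist[v] > dist[u] + 1) {
                    dist[v] <- dist[u] + 1
                    nxt <- c(nxt, v)
                }
            frontier <- unique(nxt)
        }
        for (t in (s + 1):n) {
            if (!is.finite(dist[t])) next
            # enumerate all shortest s-t paths by backtracking from t
            paths <- list(t)
            repeat {
                done <- all(vapply(paths, function(pp) pp[1] == s,
                                   logical(1)))
                if (done) break
                nxt_paths <- list()
                for (pp in paths) {
                    h <- pp[1]
                    if (h == s) { nxt_paths[[length(nxt_paths) + 1]] <- pp }
                    else for (u in which(adj[h, ] == 1 &
                                         dist == dist[h] - 1))
                        nxt_paths[[length(nxt_paths) + 1]] <- c(u, pp)
                }
                paths <- nxt_paths
            }
            npath <- length(paths)
            for (pp in paths) {
                inner <- setdiff(pp, c(s, t))
                btw[inner] <- btw[inner] + 1 / npath
            }
        }
    }
    btw
}

# adjusted Rand index by direct contingency-table formula
ari <- function(a, b) {
    tab <- table(a, b)
    sc <- function(x) sum(choose(x, 2))
    sij <- sc(tab); si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
    expd <- si * sj / choose(sum(tab), 2)
    (sij - expd) / ((si + sj) / 2 - expd)
}

# tiny hand-checkable DAG:
#        root
#       /    \
#      A      B
#     / \      \
#    A1  A2     B1
makeTestDag <- function() {
    new("GODag",
        parents = list(root = character(0), A = "root", B = "root",
                       A1 = "A", A2 = "A", B1 = "B"),
        namespace = "biological_process", root = "root")
}

# wrap a bare igraph in a CoRegNetwork with placeholder attributes
asNet <- function(g, cluster = "C1") {
    igraph::V(g)$type <- "primary_target"
    igraph::V(g)$log2fc <- 0
    if (igraph::gsize(g) > 0) igraph::E(g)$kind <- "ppi"
    if (is.null(igraph::V(g)$name))
        igraph::V(g)$name <- paste0("n", seq_len(igraph::gorder(g)))
    new("CoRegNetwork", graph = g, cluster_id = cluster)
}

emptyRecordsDf <- function() data.frame(
    motif = character(0), cluster = character(0), mirna = character(0),
    tf = character(0), primary = character(0), secondary = character(0),
    stringsAsFactors = FALSE)

smallParams <- function(seed = 1, ...) {
    simulationParams(seed = seed, n_mirnas = 30, n_genes = 150, n_tfs = 8,
                     n_de_mirnas_up = 5, n_de_mirnas_down = 6,
                     targets_per_mirna = 20, n_planted_ffl3 = 3,
                     n_planted_ffl4 = 2, ...)
}

smallConfig <- function(seed = 1, ...) {
    pipelineConfig(seed = seed, n_permutations = 100,
                   k_grid = 2:8, ...)
}
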