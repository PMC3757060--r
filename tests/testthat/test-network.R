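rec3 <- function(m, f, g, cl = "C1") data.frame(
    motif = "ffl3", cluster = cl, mirna = m, tf = f, primary = g,
    secondary = NA_character_, stringsAsFactors = FALSE)
rec4 <- function(m, f, g, s, cl = "C1") data.frame(
    motif = "ffl4", cluster = cl, mirna = m, tf = f, primary = g,
    secondary = s, stringsAsFactors = FALSE)

test_that("motif merging builds the typed union graph", {
    # one 3-node FFL without a TF->miRNA site: 3 nodes, 2 edges
    net <- mergeMotifs(rec3("m1", "T1", "g1"))
    g <- networkGraph(net)
    expect_equal(igraph::gorder(g), 3)
    expect_equal(igraph::gsize(g), 2)
    expect_setequal(igraph::E(g)$kind, c("mirna_target", "tf_target"))
    # with the TF bound to the miRNA promoter: third edge appears
    tfmap <- list(mirna_targets = list(T1 = "m1"),
                  gene_targets = list(T1 = "g1"), expressed_tfs = "T1")
    net2 <- mergeMotifs(rec3("m1", "T1", "g1"), tf_map = tfmap)
    expect_equal(igraph::gsize(networkGraph(net2)), 3)
    # two FFLs sharing the target: nodes and edges deduplicate
    net3 <- mergeMotifs(rbind(rec3("m1", "T1", "g1"),
                              rec3("m2", "T1", "g1")))
    expect_equal(igraph::gorder(networkGraph(net3)), 4)
    expect_equal(igraph::gsize(networkGraph(net3)), 3)
    # empty records: valid empty network
    net0 <- mergeMotifs(emptyRecordsDf())
    expect_equal(igraph::gorder(networkGraph(net0)), 0)
    expect_true(methods::validObject(net0))
    # a 4-node motif adds the PPI bridge and the secondary type
    net4 <- mergeMotifs(rec4("m1", "T1", "g1", "g2"))
    g4 <- networkGraph(net4)
    expect_setequal(igraph::E(g4)$kind,
                    c("mirna_target", "tf_target", "ppi"))
    tp <- setNames(igraph::V(g4)$type, igraph::V(g4)$name)
    expect_equal(unname(tp["g2"]), "secondary_target")
    # the regulatory role dominates: primary in one motif, secondary in
    # another stays primary
    net5 <- mergeMotifs(rbind(rec4("m1", "T1", "g1", "g2"),
                              rec3("m2", "T2", "g2")))
    tp5 <- setNames(igraph::V(networkGraph(net5))$type,
                    igraph::V(networkGraph(net5))$name)
    expect_equal(unname(tp5["g2"]), "primary_target")
    # log2FC and DE flags attach to known features
    net6 <- mergeMotifs(rec3("m1", "T1", "g1"), lfc = c(m1 = -2, g1 = 1))
    g6 <- networkGraph(net6)
    at <- setNames(igraph::V(g6)$log2fc, igraph::V(g6)$name)
    expect_equal(unname(at[c("m1", "g1", "T1")]), c(-2, 1, 0))
})

test_that("centralities match closed forms and the brute-force oracle", {
    # star: five miRNAs and one TF all hit a single hub target
    star <- do.call(rbind, lapply(1:5, function(i)
        rec3(paste0("m", i), "Thub", "ghub")))
    cent <- centralities(mergeMotifs(star))
    deg <- setNames(cent$degree, cent$node)
    expect_equal(unname(deg["ghub"]), 6)      # 5 miRNAs + 1 TF
    expect_true(all(deg[setdiff(names(deg), "ghub")] == 1))
    # path a-b-c: middle node carries the single shortest path
    g <- igraph::make_graph(~ a - b, b - c)
    cent2 <- centralities(asNet(g))
    btw <- setNames(cent2$betweenness, cent2$node)
    expect_equal(unname(btw[c("a", "b", "c")]), c(0, 1, 0))
    # random graph vs independent path-counting oracle
    set.seed(13)
    n <- 14
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (runif(1) < 0.25) adj[i, j] <- adj[j, i] <- 1
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cent3 <- centralities(asNet(gg))
    expect_equal(cent3$betweenness, oracleBetweenness(adj),
                 tolerance = 1e-9)
    expect_equal(cent3$degree, rowSums(adj))
})

test_that("hub calling uses per-type ceilings with deterministic ties", {
    # 12 miRNAs, one TF, 20 targets; all edges through a few targets
    recs <- do.call(rbind, lapply(1:12, function(i)
        do.call(rbind, lapply(1:5, function(j)
            rec3(sprintf("m%02d", i), "T1", sprintf("g%02d", (i + j) %% 20))))))
    net <- mergeMotifs(recs)
    hubs <- callHubs(net, 0.25, 0.25, 0.05)
    expect_equal(sum(hubs$hub[hubs$hub_type == "mirna"]), 3)  # ceil(.25*12)
    expect_equal(sum(hubs$hub[hubs$hub_type == "tf"]), 1)
    n_t <- sum(hubs$hub_type == "target")
    expect_equal(sum(hubs$hub[hubs$hub_type == "target"]),
                 ceiling(0.05 * n_t))
    # equal degrees break ties by betweenness then id, deterministically
    hubs2 <- callHubs(net, 0.25, 0.25, 0.05)
    expect_identical(hubs, hubs2)
    # hub fraction arithmetic: 200 targets at 5% -> 10
    expect_equal(ceiling(0.05 * 200), 10)
    expect_error(callHubs(net, 0, 0.25, 0.05))
})

test_that("walktrap recovers planted communities", {
    # two 5-cliques joined by one edge
    edges <- c()
    for (i in 1:4) for (j in (i + 1):5) edges <- c(edges, i, j)
    for (i in 6:9) for (j in (i + 1):10) edges <- c(edges, i, j)
    edges <- c(edges, 5, 6)
    g <- igraph::make_graph(edges, directed = FALSE)
    igraph::V(g)$name <- paste0("n", 1:10)
    mods <- walktrapModules(asNet(g))
    expect_equal(length(unique(mods$membership)), 2)
    expect_equal(length(unique(mods$membership[1:5])), 1)
    expect_equal(length(unique(mods$membership[6:10])), 1)
    expect_gte(mods$modularity, 0)
    # complete graph: a single module
    gK <- igraph::make_full_graph(6)
    igraph::V(gK)$name <- paste0("k", 1:6)
    modsK <- walktrapModules(asNet(gK))
    expect_equal(length(unique(modsK$membership)), 1)
    # modules partition the node set exactly
    expect_setequal(names(mods$membership), paste0("n", 1:10))
    expect_equal(sum(mods$summary$n_nodes), 10)
    expect_error(walktrapModules(mergeMotifs(emptyRecordsDf())), "empty")
})

test_that("module annotation labels by top enriched set", {
    recs <- rbind(rec3("m1", "T1", "g1"), rec3("m1", "T1", "g2"),
                  rec3("m2", "T2", "g3"), rec3("m2", "T2", "g4"))
    net <- mergeMotifs(recs)
    mods <- walktrapModules(net)
    sets <- list(setA = c("g1", "g2", "T1"), setB = c("g3", "g4", "T2"))
    anno <- annotateModules(net, mods, sets, enrich_fdr = 0.5)
    lab <- setNames(anno$label, anno$module)
    m_g1 <- mods$membership[["g1"]]; m_g3 <- mods$membership[["g3"]]
    if (m_g1 != m_g3) {
        expect_equal(unname(lab[as.character(m_g1)]), "setA")
        expect_equal(unname(lab[as.character(m_g3)]), "setB")
    }
    # modules without a qualifying term keep the placeholder label
    anno2 <- annotateModules(net, mods, list(zz = "unrelated"),
                             enrich_fdr = 0.05)
    expect_true(all(anno2$label == "-"))
})

test_that("the merge -> centralities -> hubs chain is order-invariant", {
    sim <- quietly(simulateBundle(smallParams(seed = 17)))
    res <- quietly(runPipeline(sim$bundle, smallConfig(seed = 17)))
    recs <- res$ffl$records
    expect_gt(nrow(recs), 1)
    recs_shuf <- recs[rev(seq_len(nrow(recs))), ]
    cl <- recs$cluster[1]
    a <- callHubs(mergeMotifs(recs[recs$cluster == cl, ]))
    b <- callHubs(mergeMotifs(recs_shuf[recs_shuf$cluster == cl, ]))
    b <- b[match(a$node, b$node), ]
    expect_equal(a$degree, b$degree)
    expect_equal(a$betweenness, b$betweenness)
    expect_equal(a$hub, b$hub)
})
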