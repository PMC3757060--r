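mkExpr7 <- function(vals) {
    colnames(vals) <- paste0("s", 1:7)
    expressionMatrix(vals, setNames(rep(c("high", "low"), c(4, 3)),
                                    colnames(vals)))
}

test_that("TF target mapping requires complete promoter containment and
           expressed TFs", {
    tss <- data.frame(feature = c("gA", "gB", "mirX"),
                      kind = c("gene", "gene", "mirna"),
                      chrom = c("chr1", "chr1", "chr2"),
                      tss = c(2000, 50000, 2000),
                      strand = c("+", "-", "+"))
    tfbs <- data.frame(
        tf = c("TFin", "TFedge", "TFlow", "TFmir", "TFgone"),
        chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
        start = c(100, 3995, 100, 1000, 100),
        end = c(110, 4005, 110, 1010, 110))
    vals <- rbind(gA = rnorm(7, 9), gB = rnorm(7, 9),
                  TFin = rnorm(7, 9),
                  TFedge = rnorm(7, 9),
                  TFlow = c(rep(7.9, 4), rep(8.0, 3)),
                  TFmir = rnorm(7, 9))
    expr <- mkExpr7(vals)
    tm <- quietly(mapTfTargets(tfbs, tss, expr, halfwidth = 2000,
                               tf_expr_min = 8))
    # [100,110) lies inside [0,4000): a hit
    expect_equal(tm$gene_targets$TFin, "gA")
    # [3995,4005) straddles the promoter end: no hit
    expect_equal(length(tm$gene_targets$TFedge), 0)
    # group means 7.9/8.0: expressed in one group, retained
    expect_true("TFlow" %in% tm$expressed_tfs)
    expect_equal(tm$gene_targets$TFlow, "gA")
    # miRNA promoters feed the TF->miRNA map
    expect_equal(tm$mirna_targets$TFmir, "mirX")
    # a TF absent from the matrix is dropped
    expect_false("TFgone" %in% tm$expressed_tfs)
})

test_that("3-node FFL test equals the shared enumeration oracle", {
    predicted <- paste0("g", 1:10)
    functional <- paste0("g", 1:5)
    tf_targets <- paste0("g", c(1:3, 6))      # K = 4, k = 3
    t3 <- ffl3Test(predicted, functional, tf_targets)
    expect_equal(t3$p, 66 / 252, tolerance = 1e-12)
    expect_equal(t3$p, oracleHyperEnum(3, 4, 10, 5), tolerance = 1e-12)
    expect_setequal(t3$common, paste0("g", 1:3))
    # no TF binding in the null population: untestable, p = 1
    expect_equal(ffl3Test(predicted, functional, "elsewhere")$p, 1)
    expect_equal(ffl3Test(predicted, character(0), tf_targets)$k, 0)
    # global-universe variant
    tg <- ffl3Test(predicted, functional, tf_targets,
                   universe = paste0("g", 1:20))
    expect_equal(tg$N, 20)
})

test_that("first-neighbor sets retain the targets themselves", {
    ppi <- data.frame(a = c("A", "A", "X"), b = c("B", "C", "Y"))
    nb <- neighborNetwork(list(m1 = "A", m2 = "Z"), ppi)
    expect_setequal(nb$m1, c("A", "B", "C"))
    # a target absent from the PPI contributes only itself
    expect_equal(nb$m2, "Z")
})

test_that("4-node FFL test uses the neighbor-network null", {
    nb <- paste0("g", 1:10)
    de <- paste0("g", 1:5)
    t4 <- ffl4Test(nb, tf_targets = paste0("g", c(1:3, 6)), de_genes = de)
    expect_equal(t4$p, 66 / 252, tolerance = 1e-12)
    # TF binds every neighbor: forced outcome, p = 1
    tAll <- ffl4Test(nb, tf_targets = nb, de_genes = de)
    expect_equal(tAll$k, tAll$n)
    expect_equal(tAll$p, 1)
    expect_equal(ffl4Test(character(0), nb, de)$p, 1)
    expect_equal(ffl4Test(nb, character(0), de)$p, 1)
})

test_that("pair discovery adjusts within (cluster x motif) families", {
    sim <- quietly(simulateBundle(smallParams(seed = 21)))
    cfg <- smallConfig(seed = 21)
    res <- quietly(runPipeline(sim$bundle, cfg))
    pairs <- res$ffl$pairs
    expect_true(nrow(pairs) > 0)
    for (cl in unique(pairs$cluster)) for (mt in c("ffl3", "ffl4")) {
        ix <- pairs$cluster == cl & pairs$motif == mt
        if (!any(ix)) next
        expect_equal(pairs$fdr[ix], bhFdr(pairs$p[ix]), tolerance = 1e-12,
                     label = paste("family", cl, mt))
    }
    expect_true(all(pairs$significant == (pairs$fdr < cfg@ffl_fdr)))
    # every record belongs to a significant pair and revalidates
    recs <- res$ffl$records
    if (nrow(recs)) {
        ok <- verifyFFLRecords(recs, res$target_map, res$tf_map,
                               sim$bundle$ppi, res$de_mrna_sig$feature)
        expect_true(all(ok))
    }
})

test_that("all p = 1 yields no significant pairs", {
    pairs <- data.frame(cluster = "C1", motif = "ffl3",
                        mirna = paste0("m", 1:4), tf = "T",
                        N = 10, K = 0, n = 5, k = 0, p = 1)
    expect_true(all(bhFdr(pairs$p) == 1))
})

test_that("coexpression evaluation detects shifts with the right
           sidedness", {
    set.seed(9)
    base <- rnorm(7)
    vals <- rbind(
        g1 = base, g2 = base + rnorm(7, sd = 1e-3),   # near-identical
        g3 = -base + rnorm(7, sd = 1e-3),             # anti-correlated
        matrix(rnorm(40 * 7), 40, 7,
               dimnames = list(paste0("bg", 1:40), NULL)))
    expr <- mkExpr7(vals)
    recs <- data.frame(motif = "ffl3", cluster = "C1", mirna = "m1",
                       tf = "T1", primary = c("g1", "g2"),
                       secondary = NA_character_)
    ev <- quietly(coexpressionEval(recs, expr, B = 200, seed = 1))
    expect_equal(ev$mean_obs, 1, tolerance = 1e-4)
    expect_lt(ev$p, 0.05)
    # perfectly anti-correlated co-regulated genes must NOT reject
    recs2 <- data.frame(motif = "ffl3", cluster = "C1", mirna = "m1",
                        tf = "T1", primary = c("g1", "g3"),
                        secondary = NA_character_)
    ev2 <- quietly(coexpressionEval(recs2, expr, B = 200, seed = 1))
    expect_gt(ev2$p, 0.5)
    # zero-variance genes are skipped
    vals2 <- rbind(vals, flat = rep(1, 7))
    recs3 <- rbind(recs, data.frame(motif = "ffl3", cluster = "C1",
                                    mirna = "m1", tf = "T1",
                                    primary = "flat",
                                    secondary = NA_character_))
    ev3 <- quietly(coexpressionEval(recs3, mkExpr7(vals2), B = 50,
                                    seed = 1))
    expect_equal(ev3$n_pairs, 1)   # only the g1-g2 pair survives
})

test_that("coexpression under the null is calibrated", {
    set.seed(10)
    vals <- matrix(rnorm(50 * 7), 50, 7,
                   dimnames = list(paste0("g", 1:50), NULL))
    expr <- mkExpr7(vals)
    ps <- vapply(1:20, function(i) {
        g <- sample(rownames(vals), 4)
        recs <- data.frame(motif = "ffl3", cluster = "C1", mirna = "m",
                           tf = "T", primary = g,
                           secondary = NA_character_)
        quietly(coexpressionEval(recs, expr, B = 60, seed = i))$p
    }, numeric(1))
    # roughly uniform: no pile-up at 0
    expect_gt(mean(ps), 0.2)
    expect_lt(mean(ps < 0.05), 0.31)
})
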