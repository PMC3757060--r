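test_that("zero-noise limit plants exact fold changes", {
    sim <- quietly(simulateBundle(
        smallParams(seed = 2, noise_sd = 0, de_lfc_sd = 0, de_lfc_mean = 2)))
    expr <- sim$bundle$mirna_expr
    hi <- expr$groups == "high"; lo <- expr$groups == "low"
    for (i in seq_len(nrow(sim$truth$de_mirnas))) {
        m <- sim$truth$de_mirnas$mirna[i]
        obs <- mean(expr$values[m, hi]) - mean(expr$values[m, lo])
        expect_equal(obs, sim$truth$de_mirnas$log2fc[i], tolerance = 1e-12)
        expect_equal(abs(obs), 2, tolerance = 1e-12)
    }
})

test_that("the generator is deterministic given the seed", {
    s1 <- quietly(simulateBundle(smallParams(seed = 9)))
    s2 <- quietly(simulateBundle(smallParams(seed = 9)))
    expect_identical(s1$bundle$mirna_expr$values, s2$bundle$mirna_expr$values)
    expect_identical(s1$bundle$predictions, s2$bundle$predictions)
    expect_identical(s1$bundle$tfbs, s2$bundle$tfbs)
    expect_identical(s1$truth, s2$truth)
    # byte-identical files too
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeBundle(s1, d1); writeBundle(s2, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    s3 <- quietly(simulateBundle(smallParams(seed = 10)))
    expect_false(identical(s1$bundle$mirna_expr$values,
                           s3$bundle$mirna_expr$values))
})

test_that("planted fold changes match the generating distribution", {
    p <- simulationParams(seed = 4, n_genes = 200)
    sim <- quietly(simulateBundle(p))
    expr <- sim$bundle$mirna_expr
    hi <- expr$groups == "high"; lo <- expr$groups == "low"
    down <- sim$truth$de_mirnas$mirna[sim$truth$de_mirnas$log2fc < 0]
    obs <- vapply(down, function(m)
        mean(expr$values[m, hi]) - mean(expr$values[m, lo]), numeric(1))
    # sample lfc ~ N(-mean, de_lfc_sd^2 + noise_sd^2 (1/4 + 1/3))
    sd_tot <- sqrt(p@de_lfc_sd^2 + p@noise_sd^2 * (1 / 4 + 1 / 3))
    expect_lt(abs(mean(obs) + p@de_lfc_mean),
              3 * sd_tot / sqrt(length(obs)))
})

test_that("ground truth is consistent with the emitted files", {
    sim <- quietly(simulateBundle(smallParams(seed = 6)))
    b <- sim$bundle; tr <- sim$truth
    preds <- paste(b$predictions$mirna, b$predictions$gene)
    # every functional pair is a prediction with a qualifying score
    fp <- tr$functional_pairs
    expect_true(all(paste(fp$mirna, fp$gene) %in% preds))
    strong <- b$predictions$context_score <= -0.1
    expect_true(all(paste(fp$mirna, fp$gene) %in% preds[strong]))
    # every planted 3-node triple has a TFBS fully inside the target's
    # promoter
    tssv <- setNames(b$tss$tss, b$tss$feature)
    w <- 2000
    for (i in seq_len(nrow(tr$ffl3_triples))) {
        f <- tr$ffl3_triples$tf[i]; g <- tr$ffl3_triples$target[i]
        hit <- b$tfbs$tf == f & b$tfbs$chrom == "chr1" &
            b$tfbs$start >= tssv[g] - w & b$tfbs$end <= tssv[g] + w
        expect_true(any(hit), label = paste("ffl3 TFBS", f, g))
    }
    # every planted quad has its PPI edge and a bound secondary
    ppik <- c(paste(b$ppi$a, b$ppi$b), paste(b$ppi$b, b$ppi$a))
    for (i in seq_len(nrow(tr$ffl4_quads))) {
        q <- tr$ffl4_quads[i, ]
        expect_true(paste(q$primary, q$secondary) %in% ppik)
        hit <- b$tfbs$tf == q$tf & b$tfbs$chrom == "chr1" &
            b$tfbs$start >= tssv[q$secondary] - w &
            b$tfbs$end <= tssv[q$secondary] + w
        expect_true(any(hit))
    }
    # boundary decoys exist: sites that straddle a promoter edge
    straddle <- mapply(function(s, e, ch) {
        if (ch != "chr1") return(FALSE)
        any(b$tss$chrom == "chr1" & s < b$tss$tss + w & e > b$tss$tss + w)
    }, b$tfbs$start, b$tfbs$end, b$tfbs$chrom)
    expect_true(any(straddle))
})

test_that("infeasible planting requests error out", {
    expect_error(
        quietly(simulateBundle(smallParams(n_planted_ffl3 = 20,
                                           n_planted_ffl4 = 20))),
        "infeasible")
    expect_error(simulationParams(n_de_mirnas_up = 50, n_de_mirnas_down = 50,
                                  n_mirnas = 60),
                 "exceed")
})

test_that("the null generator plants no effects", {
    sim <- quietly(nullBundle(smallParams(seed = 8)))
    expect_true(all(sim$truth$de_mirnas$log2fc == 0))
    expect_true(all(sim$truth$de_genes$log2fc == 0))
    # permuting group labels leaves the statistic distribution symmetric
    de <- quietly(moderatedT(sim$bundle$mirna_expr))
    expect_lt(abs(mean(de$t)), 3 * sd(de$t) / sqrt(nrow(de)) + 0.2)
})
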