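mkExpr <- function(vals, groups = NULL) {
    if (is.null(groups))
        groups <- setNames(rep(c("high", "low"), c(4, 3)), colnames(vals))
    expressionMatrix(vals, groups)
}

test_that("variance filter keeps the most variable features with a
           deterministic tie rule", {
    set.seed(1)
    vals <- rbind(a = rnorm(7, sd = 3), b = rnorm(7, sd = 2),
                  c = rnorm(7, sd = 1), d = rnorm(7, sd = 0.1))
    colnames(vals) <- paste0("s", 1:7)
    ex <- mkExpr(vals)
    kept <- quietly(varianceFilter(ex, 0.75))
    expect_equal(nrow(kept$values), 3)
    v <- apply(vals, 1, var)
    expect_setequal(rownames(kept$values), names(sort(v, TRUE))[1:3])
    expect_identical(quietly(varianceFilter(ex, 1))$values, ex$values)
    # exact tie at the cut: lexicographically smaller id survives
    vals2 <- rbind(zz = c(1, 2, 1, 2, 1, 2, 1), aa = c(2, 1, 2, 1, 2, 1, 2),
                   top = c(0, 9, 0, 9, 0, 9, 0))
    colnames(vals2) <- paste0("s", 1:7)
    kept2 <- quietly(varianceFilter(mkExpr(vals2), 2 / 3))
    expect_setequal(rownames(kept2$values), c("top", "aa"))
    expect_error(quietly(varianceFilter(mkExpr(vals2), 1.5)), "keep_fraction")
})

test_that("moderated t handles degenerate features as specified", {
    set.seed(2)
    vals <- matrix(rnorm(70), 10, 7,
                   dimnames = list(sprintf("f%02d", 1:10), paste0("s", 1:7)))
    vals["f01", ] <- c(5, 5, 5, 5, 5, 5, 5)      # flat: lfc 0, p 1
    de <- moderatedT(mkExpr(vals))
    r <- de[de$feature == "f01", ]
    expect_equal(r$log2fc, 0)
    expect_equal(r$t, 0)
    expect_equal(r$p, 1)
    expect_true(all(de$direction == ifelse(de$log2fc >= 0, "up", "down")))
    # FDR is non-decreasing when ordered by p
    o <- order(de$p)
    expect_true(all(diff(de$fdr[o]) >= -1e-12))
})

test_that("a single feature falls back to the ordinary pooled t-test", {
    set.seed(3)
    x <- matrix(rnorm(7, mean = c(2, 2, 2, 2, 0, 0, 0)), 1, 7,
                dimnames = list("only", paste0("s", 1:7)))
    de <- moderatedT(mkExpr(x))
    tt <- t.test(x[1, 1:4], x[1, 5:7], var.equal = TRUE)
    expect_equal(de$p, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(de$t), abs(unname(tt$statistic)), tolerance = 1e-10)
})

test_that("null p-values are uniform", {
    set.seed(4)
    vals <- matrix(rnorm(500 * 7), 500, 7,
                   dimnames = list(sprintf("f%03d", 1:500), paste0("s", 1:7)))
    de <- moderatedT(mkExpr(vals))
    expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("moderated t agrees with the limma cross-check", {
    set.seed(5)
    vals <- matrix(rnorm(300 * 7, sd = rep(runif(300, 0.5, 2), 7)), 300, 7,
                   dimnames = list(sprintf("f%03d", 1:300), paste0("s", 1:7)))
    vals[1:30, 1:4] <- vals[1:30, 1:4] + 2
    de <- moderatedT(mkExpr(vals))
    design <- cbind(1, c(1, 1, 1, 1, 0, 0, 0))
    fit <- limma::eBayes(limma::lmFit(vals, design))
    expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
    expect_gt(cor(de$t, fit$t[, 2]), 0.999)
    expect_gt(cor(-log10(de$p), -log10(fit$p.value[, 2])), 0.99)
})

test_that("BH adjustment matches hand-worked values and stays in range", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_equal(bhFdr(0.37), 0.37)
    expect_error(bhFdr(c(0.5, 1.2)), "0,1")
    expect_identical(bhFdr(numeric(0)), numeric(0))
})

test_that("DE filters apply the printed operators exactly", {
    de <- data.frame(
        feature = c("keep", "lowfc", "edgefdr", "edgeok"),
        log2fc = c(-2.28, 0.99, 1.00, 1.00),
        t = 0, p = c(1e-6, 1e-3, 0.05, 0.049),
        fdr = c(0.000013, 0.001, 0.05, 0.049),
        direction = c("down", "up", "up", "up"),
        mean_high = 0, mean_low = 0)
    out <- quietly(filterDE(de, "fdr", 0.05, 1.0))
    expect_setequal(out$feature, c("keep", "edgeok"))
    # |lfc| boundary is inclusive, p boundary strict
    expect_false("lowfc" %in% out$feature)
    expect_false("edgefdr" %in% out$feature)
})

test_that("detection power increases with the planted effect size", {
    recovered <- vapply(c(0.5, 3), function(eff) {
        sim <- quietly(simulateBundle(smallParams(
            seed = 11, de_lfc_mean = eff, de_lfc_sd = 0.1)))
        de <- quietly(filterDE(
            moderatedT(varianceFilter(sim$bundle$mirna_expr, 0.75)),
            "fdr", 0.05, 1.0))
        sum(sim$truth$de_mirnas$mirna %in% de$feature)
    }, numeric(1))
    expect_gt(recovered[2], recovered[1])
})
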