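# planted two-block dissimilarity: within ~ small, between = 10
plantedDiss <- function(n1 = 8, n2 = 8, within = 0.5, between = 10,
                        seed = 1) {
    set.seed(seed)
    n <- n1 + n2
    d <- matrix(between, n, n)
    d[1:n1, 1:n1] <- within * abs(rnorm(n1 * n1, 0.5, 0.1))
    d[(n1 + 1):n, (n1 + 1):n] <- within * abs(rnorm(n2 * n2, 0.5, 0.1))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    rownames(d) <- colnames(d) <- sprintf("x%02d", 1:n)
    d
}

test_that("FANNY recovers a planted two-block structure crisply", {
    d <- plantedDiss()
    fit <- fannyClust(d, k = 2, r = 1.1, seed = 1)
    U <- membership(fit)
    expect_true(all(abs(rowSums(U) - 1) < 1e-9))
    expect_true(all(apply(U, 1, max) >= 0.99))
    labs <- hardLabels(fit)
    expect_equal(length(unique(labs[1:8])), 1)
    expect_equal(length(unique(labs[9:16])), 1)
    expect_false(labs[[1]] == labs[[16]])
    # objective beats the uniform membership and the fit is near-crisp
    n <- nrow(d)
    U0 <- matrix(1 / 2, n, 2)
    expect_lt(fit@objective, coregFFL:::fannyObjective(U0, d, 1.1))
})

test_that("equal dissimilarities: uniform membership is a fixed point and
           the optimizer never does worse", {
    d <- matrix(1, 6, 6); diag(d) <- 0
    rownames(d) <- colnames(d) <- letters[1:6]
    # symmetry: starting exactly uniform, the update stays uniform
    U0 <- matrix(1 / 3, 6, 3)
    it <- coregFFL:::fannyIterate(U0, d, r = 2)
    expect_true(all(abs(it$U - 1 / 3) < 1e-9))
    # the returned optimum is at least as good as the symmetric solution
    fit <- fannyClust(d, k = 3, r = 2, seed = 1)
    expect_lte(fit@objective,
               coregFFL:::fannyObjective(U0, d, 2) + 1e-12)
})

test_that("small fuzziness approaches a hard partition", {
    d <- plantedDiss()
    fit <- fannyClust(d, k = 2, r = 1.01, seed = 1)
    expect_true(all(apply(membership(fit), 1, max) > 0.999))
})

test_that("FANNY matches the cluster-package reference on planted data", {
    d <- plantedDiss(seed = 3)
    fit <- fannyClust(d, k = 2, r = 1.2, seed = 1)
    ref <- cluster::fanny(as.dist(d), k = 2, memb.exp = 1.2)
    expect_equal(ari(hardLabels(fit), ref$clustering), 1)
})

test_that("fannyClust validates its inputs", {
    d <- plantedDiss()
    expect_error(fannyClust(d, k = 1), "k must be >= 2")
    expect_error(fannyClust(d, k = 16), "smaller")
    expect_error(fannyClust(d, k = 2, r = 1), "r must be > 1")
    d2 <- d; d2[1, 2] <- 99
    expect_error(fannyClust(d2, k = 2), "symmetric")
})

test_that("Dunn coefficient follows its closed form", {
    crisp <- diag(2)[c(1, 1, 2, 2), ]
    expect_equal(dunnCoefficient(crisp), c(fc = 1, fc_norm = 1))
    unif <- matrix(1 / 3, 6, 3)
    expect_equal(dunnCoefficient(unif),
                 c(fc = 1 / 3, fc_norm = 0), tolerance = 1e-12)
    U <- rbind(c(0.8, 0.2), c(0.6, 0.4))
    expect_equal(unname(dunnCoefficient(U)["fc"]), 0.6)
    expect_error(dunnCoefficient(matrix(1, 3, 1)), "k >= 2")
})

test_that("Dunn index measures separation over diameter", {
    # two tight clusters: separation 10, diameters 1
    d <- matrix(10, 4, 4)
    d[1:2, 1:2] <- 1; d[3:4, 3:4] <- 1; diag(d) <- 0
    expect_equal(dunnIndex(c(1, 1, 2, 2), d), 10)
    # overlapping clusters: separation below diameter
    d2 <- matrix(2, 4, 4); d2[1, 2] <- d2[2, 1] <- 5; diag(d2) <- 0
    expect_lt(dunnIndex(c(1, 1, 2, 2), d2), 1)
    # identical items split apart is degenerate
    dz <- matrix(0, 4, 4)
    expect_error(dunnIndex(c(1, 1, 2, 2), dz), "degenerate")
    # singletons only: infinite separation ratio
    d3 <- matrix(3, 2, 2); diag(d3) <- 0
    expect_equal(dunnIndex(c(1, 2), d3), Inf)
    expect_error(dunnIndex(c(1, 1), d3), "2 non-empty")
})

test_that("grid selection finds the planted fuzziness and cluster number", {
    d <- plantedDiss(n1 = 10, n2 = 10, seed = 5)
    sel <- quietly(selectParameters(d, r_grid = c(1.1, 1.3),
                                    k_grid = 2:6, seed = 1))
    expect_equal(sel$k_star, 2)
    expect_equal(sel$r_star, 1.1)
    expect_equal(nrow(sel$diagnostics), 2 * 5)
    expect_gt(sel$diagnostics$dunn_index[
        sel$diagnostics$r == 1.1 & sel$diagnostics$k == 2], 1)
    # a structureless blob triggers the weak-structure warning
    set.seed(6)
    db <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
    expect_warning(selectParameters(db, r_grid = 1.1, k_grid = 2:4,
                                    seed = 1),
                   "Dunn index > 1")
})
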