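test_that("adjacency is |cor|^beta with unit diagonal", {
    x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
    a <- adjacencyMatrix(x, beta = 11)
    expect_equal(a["a", "b"], 1)        # perfectly correlated
    expect_equal(a["a", "c"], 1)        # unsigned: r = -1 -> 1
    expect_equal(diag(a), setNames(rep(1, 3), c("a", "b", "c")))
    # r = 0.5 at beta = 11
    expect_equal(0.5^11, 4.8828125e-4)
    expect_error(adjacencyMatrix(x[, 1:2], beta = 2), "samples")
    expect_warning(adjacencyMatrix(rbind(x, flat = c(1, 1, 1, 1)), 2),
                   "zero-variance")
})

test_that("TOM matches hand values and the double-loop oracle", {
    a3 <- matrix(1, 3, 3)
    expect_equal(tomSimilarity(a3)[1, 2], 1)  # complete graph
    # isolated pair: a_ij = 0 everywhere off-diagonal
    iso <- diag(4)
    expect_equal(tomSimilarity(iso)[1, 2], 0)
    set.seed(41)
    for (n in c(4, 7, 10)) {
        a <- randomAdjacency(n)
        expect_equal(tomSimilarity(a), tomOracle(a), tolerance = 1e-10)
    }
})

test_that("TOM is symmetric with entries in [0, 1]", {
    set.seed(42)
    for (i in 1:5) {
        tom <- tomSimilarity(randomAdjacency(8))
        expect_equal(tom, t(tom), tolerance = 1e-12)
        expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    }
})

test_that("planted zero-noise blocks are recovered exactly", {
    cfg <- simulationConfig(nGenes = 30, nSamples = 12,
        moduleSpec = data.frame(size = c(10, 10), loading = 1, noiseSD = 0),
        seed = 19)
    sim <- simulateCoexpression(cfg)
    res <- runCoexpressionModules(sim$expr, beta = 6, minModuleSize = 5)
    lab <- moduleLabels(res)
    mods <- setdiff(unique(lab[sim$truth$module != "background"]),
                    "unassigned")
    expect_equal(length(mods), 2)
    # every planted module maps onto exactly one detected label
    for (m in c("module1", "module2")) {
        got <- lab[sim$truth$gene[sim$truth$module == m]]
        expect_equal(length(unique(got)), 1)
        expect_false(unique(got) == "unassigned")
    }
    # determinism
    res2 <- runCoexpressionModules(sim$expr, beta = 6, minModuleSize = 5)
    expect_identical(moduleLabels(res2), lab)
})

test_that("fewer genes than the minimum module size leaves all unassigned", {
    set.seed(2)
    x <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("g", 1:5), NULL))
    expect_warning(res <- detectModules(tomSimilarity(adjacencyMatrix(x, 2)),
                                        minModuleSize = 50),
                   "unassigned")
    expect_true(all(res == "unassigned"))
})

test_that("module recovery stays high across seeds at moderate noise", {
    skip_if_not_installed("mclust")
    ari <- vapply(1:20, function(s) {
        cfg <- simulationConfig(nGenes = 60, nSamples = 24,
            moduleSpec = data.frame(size = c(25, 25), loading = 1,
                                    noiseSD = 0.3),
            seed = 1000 + s)
        sim <- simulateCoexpression(cfg)
        res <- runCoexpressionModules(sim$expr, beta = 11, minModuleSize = 10)
        mclust::adjustedRandIndex(moduleLabels(res)[sim$truth$gene],
                                  sim$truth$module)
    }, numeric(1))
    expect_true(all(ari >= 0.9))
})

test_that("eigengene matches the closed-form 2x2 first eigenvector", {
    # two standardized genes: PC1 of their covariance is (1,1)/sqrt(2),
    # so the eigengene is proportional to the mean profile
    x <- rbind(g1 = c(1, 3, 2, 4), g2 = c(2, 6, 4, 8))
    eg <- moduleEigengene(x, c("g1", "g2"))
    z <- t(scale(t(x)))
    hand <- colMeans(z)
    hand <- hand / sqrt(sum(hand^2))
    expect_equal(unname(eg$eigengene), unname(hand), tolerance = 1e-9)
    expect_equal(eg$varianceExplained, 1, tolerance = 1e-9)
    expect_equal(sum(eg$eigengene^2), 1)
    # orientation: flipping every member gene leaves the result invariant
    eg2 <- moduleEigengene(-x, c("g1", "g2"))
    expect_equal(abs(unname(eg2$eigengene)), abs(unname(eg$eigengene)),
                 tolerance = 1e-9)
    expect_gt(mean(cor(eg2$eigengene, t(-x))), 0)
    expect_error(moduleEigengene(rbind(c(1, 1, 1)), 1), "constant")
})

test_that("module-trait correlation matches the t-transform by hand", {
    set.seed(61)
    e <- matrix(rnorm(20), 2, 10, dimnames = list(c("M1", "M2"), NULL))
    trait <- e[1, ]  # trait equal to an eigengene
    mt <- moduleTraitCor(e, trait)
    expect_equal(mt$r[1], 1)
    expect_lt(mt$p[1], 1e-12)
    # n = 10, r = 0.8: t = 0.8 sqrt(8 / 0.36) = 3.771, p ~ 0.0055
    r <- 0.8; n <- 10
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(t, 3.771, tolerance = 1e-3)
    expect_equal(2 * pt(-t, n - 2), 0.005456, tolerance = 1e-4)
    # trait orthogonalized against the (centered) eigengene: r = 0
    y <- rnorm(10)
    y <- y - mean(y)
    e2 <- e[2, ] - mean(e[2, ])
    y <- y - as.numeric(crossprod(e2, y) / crossprod(e2)) * e2
    expect_equal(moduleTraitCor(e, y)$r[2], 0, tolerance = 1e-12)
    expect_error(moduleTraitCor(e[, 1:2], trait[1:2]), "samples")
})

test_that("the MPV transform applies mid-parent heterosis to expression", {
    lm <- rbind(g1 = c(F1 = 2, M1 = 6, H = 6),
                g2 = c(F1 = 4, M1 = 4, H = 4),
                g3 = c(F1 = 0, M1 = 0, H = 5))
    design <- data.frame(hybrid = "H", female = "F1", male = "M1")
    expect_warning(mx <- mpvTransform(lm, design), "zero mid-parent")
    expect_equal(mx["g1", "H"], 50)  # F=2, M=6, H=6 -> MP=4
    expect_equal(mx["g2", "H"], 0)   # H equal to MP everywhere
    expect_false("g3" %in% rownames(mx))
    # rescaling all FPKMs leaves the matrix unchanged
    expect_equal(suppressWarnings(mpvTransform(lm * 7, design)), mx)
})
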