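test_that("same config and seed reproduce identical simulations", {
    cfg <- simulationConfig(nGenes = 150, seed = 99,
                            patternMix = c(P5 = 0.2, null = 0.8))
    a <- simulateTrioCounts(cfg)
    b <- simulateTrioCounts(cfg)
    expect_identical(SummarizedExperiment::assay(a, "counts"),
                     SummarizedExperiment::assay(b, "counts"))
    expect_identical(S4Vectors::metadata(a)$truth,
                     S4Vectors::metadata(b)$truth)
    expect_identical(S4Vectors::metadata(a)$traits,
                     S4Vectors::metadata(b)$traits)
})

test_that("simulation layout matches the diallel design", {
    cfg <- simulationConfig(nGenes = 50, nFemale = 3, nMale = 2,
                            replicates = 4, seed = 2)
    se <- simulateTrioCounts(cfg)
    cd <- SummarizedExperiment::colData(se)
    expect_equal(ncol(se), (3 + 2 + 6) * 4)
    expect_equal(nrow(S4Vectors::metadata(se)$trioDesign), 6)
    expect_equal(sum(cd$role == "hybrid"), 24)
    # planted group means respect the pattern ordering exactly before noise
    tr <- S4Vectors::metadata(se)$truth
    expect_true(all(tr$pattern == "null"))
})

test_that("planted truth is consistent with the pattern definitions", {
    mix <- setNames(rep(1 / 13, 13), c(paste0("P", 1:12), "null"))
    cfg <- simulationConfig(nGenes = 260, patternMix = mix, seed = 4)
    tru <- S4Vectors::metadata(simulateTrioCounts(cfg))$truth
    # P3 plants a parent-parent difference; P7/P10 plant none
    expect_true(all(tru$degFM[tru$pattern == "P3"]))
    expect_false(any(tru$degFM[tru$pattern %in% c("P7", "P10")]))
    # hybrid differs from both parents in every over-dominant pattern
    od <- tru$pattern %in% paste0("P", 7:12)
    expect_true(all(tru$degFH[od] & tru$degMH[od]))
    # null genes plant no differences at all
    nullg <- tru$pattern == "null"
    expect_false(any(tru$degFM[nullg] | tru$degFH[nullg] | tru$degMH[nullg]))
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(nGenes = 100, patternMix = c(P1 = 0.6)),
                 "sum to 1")
    expect_error(simulationConfig(replicates = 1), "replicates")
    expect_error(simulationConfig(baselineMean = -5), "baselineMean")
    expect_error(
        simulationConfig(nGenes = 10,
                         moduleSpec = data.frame(size = 50, loading = 1,
                                                 noiseSD = 0.1)),
        "exceed")
})

test_that("FPKM follows counts * 1e9 / (length * librarySize)", {
    m <- matrix(c(10, 0, 100), 3, 1,
                dimnames = list(c("g1", "g2", "g3"), "s1"))
    fp <- countsToFPKM(m, geneLengths = c(1000, 800, 2000),
                       librarySizes = c(1e6))
    expect_equal(unname(fp[, 1]), c(10, 0, 100 * 1e9 / (2000 * 1e6)))
    # third gene: 100 reads, 2 kb, 1M mapped -> 50; at 2M mapped -> 25
    fp2 <- countsToFPKM(m, geneLengths = c(1000, 800, 2000),
                        librarySizes = c(2e6))
    expect_equal(unname(fp2[3, 1]), 25)
    expect_error(countsToFPKM(m, geneLengths = c(1000, 800)), "match")
})

test_that("FPKM of simulated data centers on the planted means", {
    cfg <- simulationConfig(nGenes = 300, seed = 8, dispersion = 0.01,
                            patternMix = c(P4 = 0.5, null = 0.5))
    se <- countsToFPKM(simulateTrioCounts(cfg))
    lm <- lineMeans(se)
    tru <- S4Vectors::metadata(se)$truth
    p4 <- tru$gene[tru$pattern == "P4"]
    # female lines planted 4x the male lines for P4 genes
    ratio <- rowMeans(lm[p4, paste0("F", 1:4)]) /
             rowMeans(lm[p4, paste0("M", 1:4)])
    expect_equal(median(ratio), 4, tolerance = 0.1)
})

test_that("coexpression simulation plants modules and trait correlation", {
    cfg <- simulationConfig(nGenes = 100, nSamples = 24,
        moduleSpec = data.frame(size = c(30, 30), loading = 1,
                                noiseSD = c(0, 0.2)),
        traitModuleR = 0.8, seed = 31)
    sim <- simulateCoexpression(cfg)
    sim2 <- simulateCoexpression(cfg)
    expect_identical(sim$trait, sim2$trait)
    expect_identical(sim$expr, sim2$expr)
    # zero-noise module: pairwise correlations exactly +/- 1
    m1 <- sim$truth$gene[sim$truth$module == "module1"]
    cc <- cor(t(sim$expr[m1[1:5], ]))
    expect_equal(abs(unname(cc)), matrix(1, 5, 5))
    # trait tracks module 1's factor, not module 2's
    expect_gt(cor(sim$trait, sim$factors[1, ]), 0.6)
    expect_lt(abs(cor(sim$trait, sim$factors[2, ])), 0.45)
})

test_that("trait correlation with non-target factors stays small over seeds", {
    rs <- vapply(1:12, function(s) {
        cfg <- simulationConfig(nGenes = 40, nSamples = 24,
            moduleSpec = data.frame(size = c(15, 15), loading = 1,
                                    noiseSD = 0.1),
            traitModuleR = 0, seed = s)
        sim <- simulateCoexpression(cfg)
        abs(cor(sim$trait, sim$factors[2, ]))
    }, numeric(1))
    # |r| of two independent N(0,1) vectors at n = 24: sd about 0.21
    expect_lt(median(rs), 0.3)
    expect_lt(mean(rs > 0.5), 0.2)
})

test_that("expression TSVs round-trip through the package readers", {
    cfg <- simulationConfig(nGenes = 40, seed = 12)
    se <- countsToFPKM(simulateTrioCounts(cfg))
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTSV(SummarizedExperiment::assay(se, "fpkm"), tmp)
    back <- readExpressionTSV(tmp)
    expect_equal(back, SummarizedExperiment::assay(se, "fpkm"),
                 tolerance = 1e-12)
})
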