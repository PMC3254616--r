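test_that("Welch t test matches the explicit textbook formula", {
    a <- c(1, 2, 3)
    b <- c(4, 5, 6)
    res <- twoSampleTests(a, b)
    # oracle: explicit Welch statistic and Satterthwaite df
    se2 <- var(a) / 3 + var(b) / 3
    tOracle <- (mean(a) - mean(b)) / sqrt(se2)
    dfOracle <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
    pOracle <- 2 * pt(abs(tOracle), dfOracle, lower.tail = FALSE)
    expect_equal(res$tStatistic, tOracle, tolerance = 1e-12)
    expect_equal(res$df, dfOracle, tolerance = 1e-12)
    expect_equal(res$welchP, pOracle, tolerance = 1e-12)
    expect_equal(res$meanA, 2)
    expect_equal(res$meanB, 5)
})

test_that("identical samples give t = 0 and p = 1; F test is orientation-safe", {
    a <- c(1, 2, 3, 4)
    res <- twoSampleTests(a, a)
    expect_equal(res$tStatistic, 0)
    expect_equal(res$welchP, 1)
    expect_equal(res$fStatistic, 1)
    # larger variance goes into the numerator either way
    x <- c(1, 2, 3)
    y <- c(0, 5, 10)
    expect_equal(twoSampleTests(x, y)$fStatistic,
                 twoSampleTests(y, x)$fStatistic)
    expect_gte(twoSampleTests(x, y)$fStatistic, 1)
    expect_error(twoSampleTests(c(1, 1), c(1, 1)), "zero variance")
})

test_that("permutation p-value is exact in degenerate and enumerable cases", {
    flat <- permutationTest(rep(2, 6), 1:3, nPerm = 500, seed = 1)
    expect_equal(flat$pValue, 1)   # every permuted difference equals observed

    # N = 4, set {1, 2}, values (10, 9, 1, 2): exhaustive null over the
    # 6 subsets has exactly one difference >= the observed 8, so p = 1/6
    res <- permutationTest(c(10, 9, 1, 2), c(1, 2), nPerm = 10000, seed = 2)
    expect_equal(res$observed, 8)
    pExact <- 1 / 6
    se <- sqrt(pExact * (1 - pExact) / 10000)
    expect_lt(abs(res$pValue - pExact), 3 * se)
    expect_equal(res$pValueCorrected,
                 (res$pValue * 10000 + 1) / 10001, tolerance = 1e-12)

    expect_error(permutationTest(1:4, integer(0)), "proper subset")
    expect_error(permutationTest(1:4, 1:4), "proper subset")
})

test_that("permutation p-values are reproducible and roughly uniform under the null", {
    set.seed(55)
    fixed <- rnorm(50)
    r1 <- permutationTest(fixed, 1:10, nPerm = 200, seed = 5)
    r2 <- permutationTest(fixed, 1:10, nPerm = 200, seed = 5)
    expect_identical(r1$pValue, r2$pValue)
    set.seed(77)
    vals <- rnorm(40)
    res <- lapply(1:40, function(i) {
        set.seed(1000 + i)
        v <- sample(vals)
        permutationTest(v, 1:8, nPerm = 100)
    })
    ps <- vapply(res, `[[`, numeric(1), "pValue")
    psc <- vapply(res, `[[`, numeric(1), "pValueCorrected")
    expect_gt(mean(ps), 0.3)   # coarse uniformity check
    expect_lt(mean(ps), 0.7)
    expect_true(all(ps >= 0 & ps <= 1))
    expect_true(all(psc > 0 & psc <= 1))   # corrected p can never be zero
})

test_that("threshold detection separates disjoint amplitude supports", {
    set.seed(3)
    amps <- c(runif(400, 0, 0.1), runif(100, 0.3, 0.4))
    ref <- 401:500
    rep <- detectThreshold(amps, ref)
    thr <- thresholdValue(rep)
    expect_false(is.na(thr))
    # oracle: direct application of the persistent-relative-gap definition
    grid <- unique(sort(c(0, amps)))
    sAll <- vapply(grid, function(a) mean(amps > a), numeric(1))
    sExcl <- vapply(grid, function(a) mean(amps[-ref] > a), numeric(1))
    gapOk <- sAll > 0 & (sAll - sExcl) / sAll >= 0.05
    persistent <- rev(cummin(rev(ifelse(sAll > 0, gapOk, TRUE)))) == 1 & gapOk
    expect_equal(thr, grid[which(persistent)[1]])
    # the threshold sits below the reference support and keeps every
    # reference gene
    expect_lt(thr, 0.3)
    expect_true(all(amps[ref] > thr))
    expect_gte(genesAboveThreshold(rep), 100L)
    # survival-curve contracts
    expect_true(all(diff(rep@survivalAll) <= 1e-12))
    expect_true(all(diff(rep@survivalExcluded) <= 1e-12))
    expect_equal(rep@survivalAll[1], 1 - mean(amps == 0))
})

test_that("no threshold is reported when the reference set carries no signal", {
    set.seed(4)
    amps <- runif(500)
    rep <- detectThreshold(amps, 1:100, minGap = 0.05)
    expect_true(is.na(thresholdValue(rep)))
})

test_that("recovery evaluation is exact on self-comparison and offset-invariant", {
    set.seed(6)
    truth <- S4Vectors::DataFrame(gene = sprintf("g%03d", 1:200),
                                  amplitude = runif(200),
                                  phase = runif(200, 0, 2 * pi))
    tab <- S4Vectors::DataFrame(gene = truth$gene,
                                amplitude = truth$amplitude,
                                phase = truth$phase * 180 / pi)
    res <- evaluateRecovery(tab, truth)
    expect_equal(res$amplitudePearson, 1.0, tolerance = 1e-12)
    expect_equal(res$phaseSinePearsonAligned, 1.0, tolerance = 1e-6)
    expect_gte(res$phaseSinePearsonAligned, res$phaseSinePearsonRaw)

    # a global phase shift must not change the aligned correlation
    shifted <- tab
    shifted$phase <- (tab$phase + 137) %% 360
    resS <- evaluateRecovery(shifted, truth)
    expect_equal(resS$phaseSinePearsonAligned, res$phaseSinePearsonAligned,
                 tolerance = 1e-4)
    expect_error(evaluateRecovery(tab[1:2, ], truth[1:2, ]), "three genes")
})

test_that("circular median handles the wrap-around where the ordinary median fails", {
    # oracle: brute-force arc-distance minimization over a fine grid
    phases <- c(10, 20, 350)
    grid <- seq(0, 359.9, by = 0.1)
    cost <- vapply(grid, function(c) {
        d <- abs(phases - c) %% 360
        sum(pmin(d, 360 - d))
    }, numeric(1))
    oracle <- grid[which.min(cost)]
    expect_equal(circularMedian(phases), oracle)
    expect_equal(circularMedian(phases), 10)
    expect_equal(circularMedian(42), 42)     # singleton
})

test_that("group phase medians are computed per label, circular and ordinary", {
    tab <- S4Vectors::DataFrame(gene = c("a", "b", "c", "d"),
                                amplitude = rep(1, 4),
                                phase = c(10, 20, 350, 180))
    groups <- c(a = "G1", b = "G1", c = "G1", d = "M")
    res <- medianPhaseByGroup(tab, groups)
    expect_equal(res$circularMedian[res$group == "G1"], 10)
    expect_equal(res$ordinaryMedian[res$group == "G1"], 20)
    expect_equal(res$circularMedian[res$group == "M"], 180)
    expect_error(medianPhaseByGroup(tab, c(z = "G2")), "no genes")
})

test_that("set-overlap report counts every Venn region", {
    ov <- setOverlapReport(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
    expect_identical(ov$pairwise["A", "B"], 2L)
    expect_identical(ov$sizes, c(A = 3L, B = 3L))
    regions <- setNames(ov$regions$count, ov$regions$region)
    expect_identical(regions[["A&B"]], 2L)
    expect_identical(regions[["A"]], 1L)
    expect_identical(regions[["B"]], 1L)

    dis <- setOverlapReport(list(A = c("x"), B = c("y"), C = c("z")))
    expect_true(all(dis$pairwise[upper.tri(dis$pairwise)] == 0L))
    expect_error(setOverlapReport(list(A = "x")), "two sets")
})
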