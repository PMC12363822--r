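test_that("preprocessing zeroes sub-threshold rates and is idempotent", {
    m <- matrix(c(1e-4, 2e-3, 1e-3, 0.5), 2)
    out <- preprocessRates(m)
    expect_equal(out, matrix(c(0, 2e-3, 1e-3, 0.5), 2))  # strict less-than
    expect_identical(preprocessRates(out), out)
    expect_equal(preprocessRates(matrix(1e-4, 3, 3)), matrix(0, 3, 3))
    expect_error(preprocessRates(matrix(-1, 1, 1)), "nonnegative")
})

test_that("overlap is the cosine of mean rate vectors", {
    A <- rbind(c(1, 1), c(1, 1), c(0, 0))
    B <- rbind(c(1, 1), c(0, 0), c(1, 1))
    expect_equal(overlapPair(A, A), 1)
    expect_equal(overlapPair(A, B), 0.5)   # (1,1,0)x(1,0,1)
    # disjoint active sets
    C1 <- rbind(c(1, 1), c(0, 0))
    C2 <- rbind(c(0, 0), c(1, 1))
    expect_equal(overlapPair(C1, C2), 0)
    expect_error(overlapPair(matrix(0, 2, 2), C1), "zero vector")
})

test_that("overlap shuffle matches the permutation-enumeration oracle", {
    set.seed(31)
    A <- matrix(runif(5 * 3), 5)
    B <- matrix(runif(5 * 3), 5)
    # enough realizations to trigger exact enumeration
    o <- overlapShuffle(A, B, nRealizations = factorial(5), seed = 1)
    expect_equal(as.numeric(o), overlapShuffleOracle(A, B),
                 tolerance = 1e-12)
    # constant vectors are permutation-invariant
    K <- matrix(1, 4, 2)
    expect_equal(as.numeric(overlapShuffle(K, K, 5, seed = 2)), 1)
    # reproducible under a fixed seed in the sampled regime
    A2 <- matrix(runif(40), 20)
    B2 <- matrix(runif(40), 20)
    expect_identical(overlapShuffle(A2, B2, 10, seed = 7),
                     overlapShuffle(A2, B2, 10, seed = 7))
})

test_that("spatial correlation averages co-active neuron profile cosines", {
    A <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
    B <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1))
    # neuron 1: cos = 1; neuron 2: disjoint supports, cos = 0; neuron 3
    # inactive in A -> excluded
    out <- spatialCorrPair(A, B)
    expect_equal(out$rho, 0.5)
    expect_equal(out$nActive, 2L)
    expect_equal(spatialCorrPair(A, A)$rho, 1)
    # no co-active neurons: flagged, not an error
    out0 <- spatialCorrPair(rbind(c(1, 1), c(0, 0)),
                            rbind(c(0, 0), c(1, 1)))
    expect_true(is.na(out0$rho))
    expect_equal(out0$nActive, 0L)
})

test_that("spatial-correlation shuffle matches pair enumeration", {
    set.seed(32)
    A <- matrix(runif(3 * 4) + 0.1, 3)
    B <- matrix(runif(3 * 4) + 0.1, 3)
    # nPairs covers all 6 ordered pairs: exact enumeration
    out <- spatialCorrShuffle(A, B, nPairs = 6, nRealizations = 4,
                              seed = 5)
    expect_equal(out$rho, spatialCorrShuffleOracle(A, B),
                 tolerance = 1e-12)
    # identical constant fields: shuffle mean is exactly 1
    K <- matrix(1, 5, 3)
    expect_equal(spatialCorrShuffle(K, K, 10, 3, seed = 1)$rho, 1)
    # fewer than two co-active neurons: flagged
    out1 <- spatialCorrShuffle(rbind(c(1, 1), c(0, 0)),
                               rbind(c(1, 1), c(0, 0)),
                               10, 2, seed = 1)
    expect_true(is.na(out1$rho))
})

test_that("sampled shuffle estimators are unbiased against enumeration", {
    set.seed(33)
    A <- matrix(runif(6 * 5), 6)
    B <- matrix(runif(6 * 5), 6)
    # many sampled realizations approach the exact permutation mean
    v <- attr(overlapShuffle(A, B, nRealizations = 719, seed = 9),
              "values")
    expect_lt(abs(mean(v) - overlapShuffleOracle(A, B)),
              3 * sd(v) / sqrt(length(v)))
    # sampled pair subsets approach the exact ordered-pair mean
    s <- spatialCorrShuffle(A, B, nPairs = 10, nRealizations = 400,
                            seed = 10)
    expect_lt(abs(s$rho - spatialCorrShuffleOracle(A, B)),
              3 * sd(s$values) / sqrt(length(s$values)))
})

test_that("the one-sample test behaves at its boundaries", {
    # textbook case
    v <- c(0.9, 0.91, 0.89, 0.9)
    out <- summarizeAndTest(v, 0.3)
    expect_equal(out$t, (0.9 - 0.3) / (sd(v) / 2), tolerance = 1e-12)
    expect_true(out$significant)
    expect_true(summarizeAndTest(v, 0.3, nTests = 100)$significant)
    # all values equal to the shuffle mean: degenerate, not significant
    out2 <- summarizeAndTest(rep(0.5, 4), 0.5)
    expect_true(out2$degenerate)
    expect_false(out2$significant)
    # degenerate but different: exact inequality reported
    out3 <- summarizeAndTest(rep(0.7, 4), 0.5)
    expect_true(out3$degenerate)
    expect_true(out3$significant)
})

test_that("permutation null is tight for exchangeable populations", {
    # i.i.d. neuron mean rates: overlap and shuffle overlap must agree
    set.seed(34)
    reps <- 40
    diffs <- replicate(reps, {
        A <- matrix(rexp(512), 512)
        B <- matrix(rexp(512), 512)
        overlapPair(A, B) - as.numeric(overlapShuffle(A, B, 5,
                                                      seed = sample.int(1e6, 1)))
    })
    expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(reps))
})

test_that("remappingStats assembles pairwise tables and effects", {
    run <- fixtureRun("space_feature_toy", seed = 4L, resolution = 30L)
    st <- remappingStats(run, seed = 6)
    tab <- statsTable(st)
    expect_equal(nrow(tab), 3L)            # K(K-1)/2 for K = 3
    expect_true(all(tab$overlap >= 0 & tab$overlap <= 1))
    expect_true(all(tab$overlapShuffle >= 0 & tab$overlapShuffle <= 1))
    expect_true(all(is.na(tab$spatialCorr) |
                    (tab$spatialCorr >= -1 & tab$spatialCorr <= 1)))
    s <- statsSummary(st)
    expect_true(is.finite(s$overlap$effect))
    # reproducibility of the full stats object
    st2 <- remappingStats(run, seed = 6)
    expect_identical(statsTable(st2), tab)
})
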