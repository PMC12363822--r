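test_that("decoder codes impose their normalisation exactly", {
    # M code: unit columns
    bM <- sampleDecoder(64, 8, "M", seed = 1)
    expect_lt(max(abs(colSums(decoderMatrix(bM)^2) - 1)), 1e-12)
    # C code: each row-pair block of each column has norm sqrt(2/Y)
    bC <- sampleDecoder(32, 4, "C", seed = 2)
    D <- decoderMatrix(bC)
    for (j in 1:2) {
        blk <- D[(2 * j - 1):(2 * j), ]
        expect_lt(max(abs(colSums(blk^2) - 2 / 4)), 1e-12)
    }
    expect_lt(max(abs(colSums(D^2) - 1)), 1e-12)   # implies unit columns
    # CM code: positional and cognitive sub-columns each have norm 1/sqrt(2)
    labs <- list(positional = 1:2, cognitive = 3:4)
    bCM <- sampleDecoder(24, 4, "CM", partLabels = labs, seed = 3)
    D <- decoderMatrix(bCM)
    expect_lt(max(abs(colSums(D[1:2, ]^2) - 0.5)), 1e-12)
    expect_lt(max(abs(colSums(D[3:4, ]^2) - 0.5)), 1e-12)
    # pM code: pure positional then pure cognitive columns
    bpM <- sampleDecoder(8, 4, "pM", partLabels = labs,
                         pureCounts = c(2L, 2L), seed = 4)
    D <- decoderMatrix(bpM)
    expect_equal(D[3:4, 1:2], matrix(0, 2, 2))
    expect_equal(D[1:2, 3:4], matrix(0, 2, 2))
    expect_lt(max(abs(colSums(D^2) - 1)), 1e-12)
    # identity code
    bI <- sampleDecoder(5, 5, "identity")
    expect_equal(decoderMatrix(bI), diag(5))
})

test_that("the encoder is the right pseudo-inverse of the decoder", {
    for (s in 1:3) {
        b <- sampleDecoder(64, 8, "M", seed = s)
        expect_lt(max(abs(decoderMatrix(b) %*% encoderMatrix(b) - diag(8))),
                  1e-8)
    }
})

test_that("optimal thresholds are half the squared column norms", {
    b <- sampleDecoder(16, 4, "M", seed = 5)
    expect_equal(thresholds(optimalThresholds(b)), rep(0.5, 16))
    D <- decoderMatrix(b); D[, 3] <- 2 * D[, 3]
    expect_equal(thresholds(optimalThresholds(D))[3], 2)
    D[, 1] <- 0
    expect_equal(thresholds(optimalThresholds(D))[1], 0)
})

test_that("suppression raises chosen thresholds reproducibly", {
    b <- sampleDecoder(48, 4, "M", seed = 6)
    T0 <- optimalThresholds(b)
    expect_identical(thresholds(suppress(T0, 0)), thresholds(T0))
    expect_equal(thresholds(suppress(T0, 1)), rep(10, 48))
    Th <- suppress(T0, 0.5, seed = 11)
    expect_length(suppressedNeurons(Th), 24L)
    expect_identical(suppressedNeurons(Th),
                     suppressedNeurons(suppress(T0, 0.5, seed = 11)))
    expect_true(all(thresholds(Th)[suppressedNeurons(Th)] == 10))
    # release restores reference values on a subset
    Tb <- release(Th, T0, fraction = 0.5, seed = 12)
    expect_length(suppressedNeurons(Tb), 12L)
    rel <- setdiff(suppressedNeurons(Th), suppressedNeurons(Tb))
    expect_equal(thresholds(Tb)[rel], thresholds(T0)[rel])
})

test_that("single-neuron steady state follows the closed form", {
    d <- c(1, 0)
    D <- matrix(d, 2, 1)
    for (c in c(0, 0.4, 0.5, 1, 2)) {
        sol <- steadyStateRates(c * d, D, 0.5)
        expect_equal(sol$rates, max(0, c - 0.5), tolerance = 1e-6)
    }
    # zero input with positive thresholds: silent network
    sol0 <- steadyStateRates(c(0, 0), D, 0.5)
    expect_equal(sol0$rates, 0)
})

test_that("duplicated columns create a solution manifold with a fixed sum", {
    d <- c(0.6, 0.8)
    D <- cbind(d, d)
    for (c in seq(0.6, 3, length.out = 10)) {
        sol <- steadyStateRates(c * d, D, c(0.5, 0.5))
        expect_equal(sum(sol$rates), max(0, c - 0.5), tolerance = 1e-6)
        # objective equals the 1-d closed form at r = c - 1/2
        r <- max(0, c - 0.5)
        expect_equal(sol$objective, (c - r)^2 + 2 * 0.5 * r,
                     tolerance = 1e-6)
    }
})

test_that("the QP solver matches the support-enumeration oracle", {
    for (s in 1:25) {
        N <- sample(2:6, 1); Y <- sample(1:3, 1)
        inst <- randomQpInstance(N, Y, seed = 1000 + s)
        sol <- steadyStateRates(inst$y, inst$D, inst$T)
        ora <- qpOracle(inst$D, inst$y, inst$T)
        expect_lt(abs(sol$objective - ora$objective), 1e-6)
        expect_lt(sol$kkt, 1e-7)
        expect_true(all(sol$rates >= 0))
        expect_lt(kktResidual(inst$D, inst$y, inst$T, sol$rates), 1e-7)
    }
})

test_that("raising a neuron's threshold never increases its rate", {
    for (s in 1:10) {
        inst <- randomQpInstance(5, 3, seed = 2000 + s)
        T2 <- inst$T
        i <- sample(5, 1)
        T2[i] <- T2[i] + runif(1, 0.1, 2)
        r1 <- steadyStateRates(inst$y, inst$D, inst$T)$rates
        r2 <- steadyStateRates(inst$y, inst$D, T2)$rates
        expect_lte(r2[i], r1[i] + 1e-9)
    }
})

test_that("rate maps decompose into readout and null parts", {
    b <- sampleDecoder(32, 4, "M", seed = 8)
    T0 <- optimalThresholds(b)
    g <- buildPositionGrid(1, 20)
    lt <- makeLatentTrajectory(g)
    y <- rescaleEmbedding(applyMap(sampleMultichartMap(4, 2, 3), lt), 4, 1)
    rm <- runRateMap(y, b, T0, positions = g)
    expect_true(all(rates(rm) >= 0))
    # D maps the null part to zero
    expect_lt(max(abs(decoderMatrix(b) %*% nullPart(rm))), 1e-8)
    # rates = E (D rates) + null part
    recon <- encoderMatrix(b) %*% decodedEmbedding(rm) + nullPart(rm)
    expect_equal(recon, rates(rm), tolerance = 1e-10)
    # all-zero input gives an all-zero map
    rm0 <- runRateMap(matrix(0, 4, 3), b, T0)
    expect_equal(rates(rm0), matrix(0, 32, 3))
    # suppressed neurons with bounded drive are exactly silent
    Th <- suppress(T0, 0.5, seed = 4)
    rmS <- runRateMap(y, b, Th, positions = g)
    expect_true(all(rates(rmS)[suppressedNeurons(Th), ] == 0))
})

test_that("feedforward rates approximate the solved competition", {
    b <- sampleDecoder(32, 4, "M", seed = 9)
    # orthonormal columns: driving with one column singles out that neuron
    D <- diag(4)
    expect_equal(feedforwardRates(D[, 2], D)[, 1], c(0, 1, 0, 0))
    expect_equal(feedforwardRates(rep(0, 4), decoderMatrix(b))[, 1],
                 rep(0, 32))
    # positive rank correlation with the solved rates
    g <- buildPositionGrid(1, 15)
    lt <- makeLatentTrajectory(g)
    y <- rescaleEmbedding(applyMap(sampleMultichartMap(4, 2, 5), lt), 4, 1)
    rm <- runRateMap(y, b, optimalThresholds(b), positions = g)
    ff <- feedforwardRates(y, b)
    sp <- vapply(seq_len(ncol(y)), function(i)
        suppressWarnings(cor(ff[, i], rates(rm)[, i], method = "spearman")),
        numeric(1))
    expect_gt(median(sp, na.rm = TRUE), 0)
})

test_that("decoding recovers the latents and refuses implicit space", {
    b <- sampleDecoder(48, 4, "M", seed = 10)
    g <- buildPositionGrid(1, 30)
    lt <- makeLatentTrajectory(g)
    map <- sampleMultichartMap(4, 2, seed = 6)
    # perfect rates r = E z give back z exactly
    y <- applyMap(map, lt)
    rPerfect <- encoderMatrix(b) %*% y
    dec <- decodeEnvironment(rPerfect, b, map, lt, rescaleExponent = 0)
    expect_equal(dec$zhat, latentMatrix(lt), tolerance = 1e-8)
    # solved rates decode position within a tight circular tolerance
    ys <- rescaleEmbedding(y, 4, 1)
    rm <- runRateMap(ys, b, optimalThresholds(b), positions = g)
    dec2 <- decodeEnvironment(rates(rm), b, map, lt, rescaleExponent = 1)
    err <- circularDistance(dec2$phat[1, ], positionPoints(g)[, 1])
    expect_lt(max(err), 0.05)
    # implicit-space runs refuse position decoding
    cog <- matrix(seq(-0.9, 0.9, length.out = 30), 1)
    lt0 <- makeLatentTrajectory(g, cognitive = cog,
                                includePosition = FALSE)
    expect_error(decodeEnvironment(rPerfect[, 1, drop = FALSE], b,
                                   identityMap(2), lt0),
                 "implicit-space")
})
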