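test_that("position grids are uniform, periodic lattices", {
    g <- buildPositionGrid(1, 5)
    expect_equal(positionPoints(g)[, 1], c(-1, -0.6, -0.2, 0.2, 0.6))
    g2 <- buildPositionGrid(2, 4)
    expect_equal(nrow(positionPoints(g2)), 16L)
    expect_equal(max(positionPoints(g2)), 0.5)
    d <- diff(sort(unique(positionPoints(g2)[, 1])))
    expect_lt(max(abs(d - g2@spacing)), 1e-15)
    expect_error(buildPositionGrid(1, 1), "resolution")
})

test_that("configurations enforce scenario invariants", {
    expect_error(experimentConfig("implicit_space", N = 16L, P = 1L,
                                  C = 2L),
                 "P = 0")
    expect_error(experimentConfig("multichart_lowD", N = 8L, P = 1L,
                                  Y = 16L),
                 "Z <= Y <= N")
    expect_error(experimentConfig("grid_realignment", N = 16L, P = 1L,
                                  m = 1L),
                 "m >= 2")
    expect_error(experimentConfig("space_feature", N = 16L, P = 1L,
                                  C = 0L),
                 "C >= 1")
    # defaults are filled per scenario
    cfg <- experimentConfig("grid_realignment", N = 24L, P = 1L, m = 2L,
                            resolution = 10L)
    expect_equal(cfg@code, "C")
    expect_equal(cfg@Y, 4L)
    expect_equal(cfg@frequencies, c(0L, 1L))
})

test_that("mixed-selective runs keep decoder and thresholds fixed", {
    cfg <- experimentConfig("space_feature", N = 24L, P = 1L, C = 1L,
                            K = 3L, resolution = 16L, seed = 5L)
    run <- runExperiment(cfg)
    expect_length(run@environments, 3L)
    # channel isolation: same decoder and thresholds in every environment
    t1 <- thresholds(run@environments[[1]]$thresholds)
    for (e in run@environments) {
        expect_identical(thresholds(e$thresholds), t1)
        expect_identical(mapMatrix(e$map), diag(4))
    }
    # shared positional latent rows, differing cognitive rows
    z1 <- latentMatrix(run@environments[[1]]$latent)
    z2 <- latentMatrix(run@environments[[2]]$latent)
    expect_false(isTRUE(all.equal(z1[3:4, ], z2[3:4, ])))
})

test_that("encoder-decoder runs share latents and vary the map", {
    cfg <- experimentConfig("multichart_lowD", N = 24L, P = 1L, Y = 3L,
                            K = 3L, resolution = 16L, seed = 6L)
    run <- runExperiment(cfg)
    z1 <- latentMatrix(run@environments[[1]]$latent)
    for (e in run@environments[-1])
        expect_identical(latentMatrix(e$latent), z1)
    expect_gt(norm(mapMatrix(run@environments[[1]]$map) -
                   mapMatrix(run@environments[[2]]$map), "F"), 1e-3)
})

test_that("a zero-variance cognitive process removes the change channel", {
    cfg <- experimentConfig("space_feature", N = 24L, P = 1L, C = 1L,
                            K = 3L, sigma = 0, resolution = 16L, seed = 7L)
    run <- runExperiment(cfg)
    r1 <- rates(rateMaps(run)[[1]])
    for (rm in rateMaps(run)[-1])
        expect_equal(rates(rm), r1, tolerance = 1e-12)
    st <- remappingStats(run, seed = 3)
    expect_equal(statsTable(st)$overlap, rep(1, 3), tolerance = 1e-10)
    expect_equal(statsTable(st)$spatialCorr, rep(1, 3), tolerance = 1e-10)
})

test_that("runs are bit-reproducible under a fixed seed", {
    cfg <- experimentConfig("grid_realignment", N = 16L, P = 1L, m = 2L,
                            K = 2L, resolution = 12L, seed = 8L)
    r1 <- runExperiment(cfg)
    r2 <- runExperiment(cfg)
    expect_identical(rates(rateMaps(r1)[[1]]), rates(rateMaps(r2)[[1]]))
    expect_identical(rates(rateMaps(r1)[[2]]), rates(rateMaps(r2)[[2]]))
})

test_that("the null-space protocol modulates rates only in the null space", {
    cfg <- experimentConfig("null_space_suppress", N = 48L, P = 1L,
                            Y = 8L, resolution = 50L, seed = 9L)
    full <- nullSpaceProtocol(cfg)
    expect_named(full@environments, c("default", "birth", "suppressed"))
    D <- decoderMatrix(full@decoder)
    y <- full@environments$default$y
    # identical embedding input in all conditions
    expect_identical(y, full@environments$birth$y)
    expect_identical(y, full@environments$suppressed$y)
    # suppressed neurons are exactly silent in their condition
    for (cond in names(full@environments)) {
        e <- full@environments[[cond]]
        expect_true(all(rates(e$rateMap)[suppressedNeurons(e$thresholds), ]
                        == 0))
    }
    # the decoded position is preserved while the population map is
    # largely replaced (map suppression with a compensating reserve)
    rdef <- rates(full@environments$default$rateMap)
    rsup <- rates(full@environments$suppressed$rateMap)
    expect_lt(overlapPair(preprocessRates(rdef), preprocessRates(rsup)),
              0.9)
    dec <- function(cond) {
        e <- full@environments[[cond]]
        decodeEnvironment(rates(e$rateMap), full@decoder, e$map,
                          e$latent)$phat[1, ]
    }
    ptrue <- positionPoints(full@environments$default$latent@positions)[, 1]
    pd <- dec("default"); ps <- dec("suppressed")
    expect_lt(median(circularDistance(pd, ptrue)), 0.05)
    expect_lt(median(circularDistance(ps, ptrue)), 0.05)
    expect_lt(median(circularDistance(pd, ps)), 0.05)
    # birth releases previously silent neurons into the map
    born <- setdiff(suppressedNeurons(full@environments$default$thresholds),
                    suppressedNeurons(full@environments$birth$thresholds))
    expect_gt(length(born), 0L)
    rbirth <- rates(full@environments$birth$rateMap)
    expect_gt(sum(rbirth[born, ]), 0)
})
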