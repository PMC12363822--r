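test_that("angular encoding hits the anchor points and stays on the circle", {
    expect_equal(encodeAngular(-1)[, 1], c(1, 0))
    expect_equal(encodeAngular(0)[, 1], c(-1, 0))
    expect_equal(encodeAngular(0.5)[, 1], c(0, -1))
    p <- seq(-1, 1, length.out = 101)
    z <- encodeAngular(p)
    expect_lt(max(abs(colSums(z^2) - 1)), 1e-12)
    expect_error(encodeAngular(1.2), "lie in")
})

test_that("angular decoding inverts the encoding on [-1, 1)", {
    expect_equal(decodeAngular(1, 0), -1)
    expect_equal(decodeAngular(0, 1), -0.5)
    expect_equal(decodeAngular(-2, 0), 0)   # scale invariance
    set.seed(42)
    p <- runif(5000, -1, 1 - 1e-12)
    z <- encodeAngular(p)
    expect_lt(max(abs(decodeAngular(z[1, ], z[2, ]) - p)), 1e-12)
    # boundary identification: p = 1 decodes to the same circular point
    z1 <- encodeAngular(1)
    expect_lt(circularDistance(decodeAngular(z1[1], z1[2]), -1), 1e-12)
    expect_error(decodeAngular(0, 0), "zero vector")
})

test_that("grid encoding generalises the single-module code", {
    p <- seq(-1, 0.99, length.out = 23)
    expect_equal(encodeGrid(p, gridModuleSpec(0L)), encodeAngular(p))
    # module 2 at frequency exponent 1: alpha2 = (3/2) pi (p+1)
    z <- encodeGrid(1, gridModuleSpec(c(0L, 1L)))
    expect_equal(z[3:4, 1], c(-1, 0))       # cos(3pi), sin(3pi)
    z0 <- encodeGrid(0, gridModuleSpec(c(0L, 1L)))
    expect_equal(z0[3:4, 1], c(0, -1))      # 3pi/2
    # all-zero exponents: m identical copies of module 1
    zz <- encodeGrid(p, new("GridModuleSpec", m = 3L,
                            frequencies = c(0L, 0L, 0L)))
    expect_equal(zz[1:2, ], zz[3:4, ])
    expect_equal(zz[1:2, ], zz[5:6, ])
})

test_that("grid position decodes from the first module only", {
    z <- encodeGrid(0.25, gridModuleSpec(c(0L, 1L, 2L)))
    expect_equal(decodeGridPosition(z), 0.25)
    z[3:6, 1] <- 99                          # other modules are ignored
    expect_equal(decodeGridPosition(z), 0.25)
    expect_equal(decodeGridPosition(c(0, -1, 0.3, 0.4)), 0.5)
    expect_error(decodeGridPosition(c(0, 0, 1, 0)), "zero vector")
})

test_that("grid module specs are validated", {
    expect_error(gridModuleSpec(c(1L, 2L)), "first module")
    expect_error(gridModuleSpec(c(0L, 2L, 1L)), "nondecreasing")
    expect_silent(gridModuleSpec(c(0L, 0L, 2L)))
})

test_that("part-wise normalisation yields unit columns and is idempotent", {
    z <- c(1, 0, 0, 1)
    parts <- list(positional = 1:2, cognitive = 3:4)
    zn <- normalizeLatent(z, parts)
    expect_equal(sqrt(sum(zn[1:2]^2)), 1 / sqrt(2))
    expect_equal(sqrt(sum(zn[3:4]^2)), 1 / sqrt(2))
    expect_equal(sum(zn^2), 1)
    # single part scales to unit norm
    expect_equal(sum(normalizeLatent(c(0, 3), list(a = 1:2))^2), 1)
    # idempotence and per-part scale invariance
    set.seed(7)
    zm <- matrix(rnorm(4 * 11), 4)
    a <- normalizeLatent(zm, parts)
    expect_equal(normalizeLatent(a, parts), a, tolerance = 1e-14)
    zs <- zm; zs[1:2, ] <- 5 * zs[1:2, ]
    expect_equal(normalizeLatent(zs, parts), a, tolerance = 1e-14)
    expect_error(normalizeLatent(c(0, 0, 1, 1), parts), "zero-norm")
})

test_that("latent trajectories have the documented layout and norms", {
    g <- buildPositionGrid(1, 16)
    spec <- gridModuleSpec(c(0L, 1L))
    cog <- matrix(seq(-0.9, 0.9, length.out = 16), nrow = 1)
    lt <- makeLatentTrajectory(g, spec, cognitive = cog)
    expect_equal(nrow(latentMatrix(lt)), 2 * 2 * 1 + 2)  # 2mP + 2C
    expect_lt(max(abs(colSums(latentMatrix(lt)^2) - 1)), 1e-12)
    # positional part occupies the first 2m rows
    expect_equal(lt@parts$positional, 1:4)
    expect_equal(lt@parts$cognitive, 5:6)
    # implicit-space variant drops position entirely
    lt0 <- makeLatentTrajectory(g, cognitive = cog, includePosition = FALSE)
    expect_equal(nrow(latentMatrix(lt0)), 2)
    expect_equal(lt0@P, 0L)
    expect_error(makeLatentTrajectory(g, includePosition = FALSE),
                 "at least one cognitive")
})
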