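## Environment-specific linear maps from latent space into the embedding
## space: random column-orthonormal "charts", per-module rotations for grid
## realignment, and the identity for mixed-selective scenarios.

#' Sample a random multi-chart embedding map
#'
#' Draws R (Y x Z) uniformly from the set of matrices with orthonormal
#' columns (QR of an i.i.d. Gaussian matrix, with the sign of the R-factor
#' diagonal fixed so the decomposition — and hence the draw — is unique).
#'
#' @param Y Embedding dimensionality (>= Z).
#' @param Z Latent dimensionality.
#' @param seed Integer seed.
#' @return An [EmbeddingMap-class] with scenario "multichart".
#' @export
sampleMultichartMap <- function(Y, Z, seed = 1L) {
    Y <- as.integer(Y); Z <- as.integer(Z)
    if (Z > Y) stop("Z must be <= Y")
    R <- withSeed(seed, {
        G <- matrix(stats::rnorm(Y * Z), nrow = Y)
        qrG <- qr(G)
        Q <- qr.Q(qrG)
        ## fix signs: make diag of the R factor positive for uniqueness
        d <- sign(diag(qr.R(qrG)))
        d[d == 0] <- 1
        sweep(Q, 2L, d, `*`)
    })
    new("EmbeddingMap", R = R, scenario = "multichart",
        seed = as.integer(seed))
}

#' Sample a grid-realignment embedding map
#'
#' Block-diagonal R with one independent 2x2 rotation per module and
#' positional dimension, each rotation angle drawn Uniform[0, 2pi).
#' Rotating a module's (cos a, sin a) pair by da yields
#' (cos(a + da), sin(a + da)): realignment is a per-module phase shift.
#'
#' @param spec A [GridModuleSpec-class].
#' @param P Number of positional dimensions (blocks repeat per dimension).
#' @param seed Integer seed.
#' @return An [EmbeddingMap-class] with scenario "grid_realignment"; the
#'   rotation angles are attached as attribute `"angles"` of the matrix.
#' @export
sampleRealignmentMap <- function(spec, P = 1L, seed = 1L) {
    stopifnot(is(spec, "GridModuleSpec"))
    validObject(spec)
    P <- as.integer(P)
    nblocks <- spec@m * P
    da <- withSeed(seed, stats::runif(nblocks, 0, 2 * pi))
    R <- matrix(0, 2L * nblocks, 2L * nblocks)
    for (b in seq_len(nblocks)) {
        i <- 2L * b - 1L
        R[i:(i + 1L), i:(i + 1L)] <-
            matrix(c(cos(da[b]), sin(da[b]),
                     -sin(da[b]), cos(da[b])), 2L, 2L)
    }
    attr(R, "angles") <- da
    new("EmbeddingMap", R = R, scenario = "grid_realignment",
        seed = as.integer(seed))
}

#' The identity embedding map
#'
#' Used by mixed-selective scenarios where embedding and latent spaces
#' coincide (y = z).
#'
#' @param Z Latent (= embedding) dimensionality.
#' @return An [EmbeddingMap-class] with scenario "identity".
#' @export
identityMap <- function(Z) {
    new("EmbeddingMap", R = diag(as.integer(Z)), scenario = "identity",
        seed = NA_integer_)
}

#' Apply an embedding map to a latent trajectory
#'
#' y = R z columnwise. Since R is a column-isometry, column norms are
#' preserved.
#'
#' @param map An [EmbeddingMap-class].
#' @param z A [LatentTrajectory-class] or a numeric matrix (Z x n).
#' @return Numeric matrix (Y x n).
#' @export
applyMap <- function(map, z) {
    stopifnot(is(map, "EmbeddingMap"))
    zm <- if (is(z, "LatentTrajectory")) z@z else z
    if (nrow(zm) != ncol(map@R))
        stop("latent dimensionality does not match the map")
    map@R %*% zm
}

#' Rescale embedding variables with dimensionality
#'
#' y <- Y^q y with exponent q = 1 by default (the linear rule y <- Y y):
#' with unit-norm decoder columns, feedforward alignments of a unit-norm
#' embedding input shrink with Y, and the rescale keeps a stable fraction
#' of the population above threshold as the embedding grows. Exponent 1/2
#' (drive exactly O(1)) and 0 (rescale off) are available for comparison.
#'
#' @param y Numeric matrix (Y x n).
#' @param Y Embedding dimensionality (defaults to `nrow(y)`).
#' @param exponent One of 0, 0.5, 1.
#' @return Rescaled matrix.
#' @export
rescaleEmbedding <- function(y, Y = nrow(y), exponent = 1) {
    if (!exponent %in% c(0, 0.5, 1))
        stop("exponent must be one of 0, 0.5, 1")
    as.numeric(Y)^exponent * y
}
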