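## Environment-specific cognitive variables: constant offsets plus smooth
## Gaussian-process fluctuations over position, wrapped into [-1, 1).

#' Construct a cognitive-variable specification
#'
#' @param C Integer, number of cognitive variables.
#' @param sigma Numeric in [0, 1]: offset scale and GP marginal s.d. With
#'   `sigma < 1` offsets are Normal(0, sigma); at the extreme `sigma = 1`
#'   they are Uniform[-1, 1].
#' @param lengthscale GP kernel lengthscale v > 0 on the [-1, 1] position
#'   scale; default 0.3 gives fluctuations with a handful of bumps per
#'   traversal.
#' @param seed Integer seed.
#' @return A [CognitiveSpec-class].
#' @export
cognitiveSpec <- function(C = 1L, sigma = 0.2, lengthscale = 0.3,
                          seed = 1L) {
    new(Class = "CognitiveSpec", C = as.integer(C), sigma = as.numeric(sigma),
        lengthscale = as.numeric(lengthscale), seed = as.integer(seed))
}

#' Sample constant cognitive offsets
#'
#' One offset per cognitive variable: Normal(0, sigma) when sigma < 1
#' (sigma is the standard deviation), Uniform[-1, 1] when sigma = 1.
#'
#' @param spec A [CognitiveSpec-class].
#' @param seed Integer seed; defaults to `spec@seed`.
#' @return Numeric vector of length C.
#' @export
sampleOffsets <- function(spec, seed = spec@seed) {
    stopifnot(is(spec, "CognitiveSpec"))
    validObject(spec)
    withSeed(seed, {
        if (spec@sigma == 1) {
            stats::runif(spec@C, -1, 1)
        } else {
            stats::rnorm(spec@C, mean = 0, sd = spec@sigma)
        }
    })
}

## squared-exponential kernel matrix over grid points (rows = points)
.seKernel <- function(pts, sigmaV, lengthscale) {
    d2 <- as.matrix(stats::dist(pts))^2
    sigmaV^2 * exp(-d2 / (2 * lengthscale^2))
}

#' Sample Gaussian-process fluctuations over a position grid
#'
#' Draws C independent realisations of a zero-mean GP with squared
#' exponential kernel \eqn{K(x, x') = \sigma_v^2 \exp(-\|x - x'\|^2 /
#' (2 v^2))} evaluated at the grid points (squared Euclidean distance for
#' multi-dimensional grids). A 1e-9 diagonal jitter stabilises the Cholesky
#' factorisation.
#'
#' @param spec A [CognitiveSpec-class]; `sigma` is used as \eqn{\sigma_v}.
#' @param grid A [PositionGrid-class].
#' @param seed Integer seed; defaults to `spec@seed`.
#' @return Numeric matrix (C x n_points).
#' @export
sampleGP <- function(spec, grid, seed = spec@seed) {
    stopifnot(is(spec, "CognitiveSpec"), is(grid, "PositionGrid"))
    validObject(spec)
    n <- nrow(grid@points)
    if (spec@C == 0L) return(matrix(0, 0L, n))
    if (spec@sigma == 0) return(matrix(0, spec@C, n))
    K <- .seKernel(grid@points, spec@sigma, spec@lengthscale)
    L <- tryCatch(chol(K + 1e-9 * diag(n)),
                  error = function(e)
                      stop("GP kernel matrix is not positive definite ",
                           "after jitter: ", conditionMessage(e)))
    withSeed(seed, {
        W <- matrix(stats::rnorm(spec@C * n), nrow = spec@C)
        W %*% L    # rows ~ GP(0, K) since L'L = K (chol is upper triangular)
    })
}

#' Generate a bounded cognitive trajectory
#'
#' c(p) = k + g(p) with offsets k from [sampleOffsets] and GP fluctuations
#' g from [sampleGP], then wrapped componentwise by
#' \eqn{c \leftarrow ((c + 1) \bmod 2) - 1} so every value lies in [-1, 1),
#' consistent with the circular latent geometry.
#'
#' @param spec A [CognitiveSpec-class].
#' @param grid A [PositionGrid-class].
#' @param seed Integer seed; defaults to `spec@seed`. Offsets and GP
#'   draws use derived sub-seeds so the two sources are independent.
#' @return Numeric matrix (C x n_points) with entries in [-1, 1); the
#'   offsets used are attached as attribute `"offsets"`.
#' @export
makeCognitiveTrajectory <- function(spec, grid, seed = spec@seed) {
    k <- sampleOffsets(spec, seed = deriveSeed(seed, 1L))
    g <- sampleGP(spec, grid, seed = deriveSeed(seed, 2L))
    cc <- ((k + g + 1) %% 2) - 1
    attr(cc, "offsets") <- k
    cc
}

#' Deterministic reward-location cognitive profile
#'
#' A single cognitive variable peaking at the reward location:
#' \eqn{c(p) = \exp(-(p - \mu)^2 / (2 \sigma_r^2)) - 1}, with range
#' (-1, 0] and maximum 0 at \eqn{p = \mu}.
#'
#' @param grid A [PositionGrid-class] (first coordinate is used).
#' @param mu Reward location in [-1, 1].
#' @param sigmaR Reward spread, > 0.
#' @return Numeric matrix (1 x n_points).
#' @export
rewardProfile <- function(grid, mu, sigmaR) {
    stopifnot(is(grid, "PositionGrid"))
    if (!is.numeric(sigmaR) || sigmaR <= 0)
        stop("sigmaR must be > 0")
    p <- grid@points[, 1L]
    matrix(exp(-(p - mu)^2 / (2 * sigmaR^2)) - 1, nrow = 1L)
}
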