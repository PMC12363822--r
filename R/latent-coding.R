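## Angular latent coding: fixed mappings between environmental variables in
## [-1, 1] and points on the unit circle, with the multi-module grid variant.

#' Angular encoding of a bounded variable
#'
#' Maps \eqn{p \in [-1, 1]} to the angle \eqn{\alpha = \pi (p + 1)} and
#' returns the point \eqn{(\cos\alpha, \sin\alpha)} on the unit circle.
#' Vectorised over `p`; returns a 2 x length(p) matrix.
#'
#' @param p Numeric vector with entries in [-1, 1].
#' @return Numeric matrix (2 x length(p)); each column has unit norm.
#' @examples
#' encodeAngular(c(-1, 0, 0.5))
#' @export
encodeAngular <- function(p) {
    if (!is.numeric(p) || any(!is.finite(p)))
        stop("p must be finite numeric")
    if (any(p < -1 | p > 1))
        stop("p must lie in [-1, 1]")
    a <- pi * (p + 1)
    rbind(cos(a), sin(a))
}

#' Angular decoding back to the bounded variable
#'
#' Inverts [encodeAngular]: reads the direction of `(z1, z2)`, recovers the
#' angle \eqn{\alpha \in [0, 2\pi)} and returns \eqn{p = \alpha/\pi - 1}.
#' Scale-invariant (only the direction matters); the boundary point
#' \eqn{p = 1} is identified with \eqn{p = -1}, so outputs lie in [-1, 1).
#'
#' @param z1,z2 Numeric vectors, the (cos, sin) latent pair; must not both
#'   be zero at any entry.
#' @return Numeric vector of decoded values in [-1, 1).
#' @examples
#' decodeAngular(1, 0)    # -1
#' decodeAngular(0, 1)    # -0.5
#' @export
decodeAngular <- function(z1, z2) {
    if (any(z1 == 0 & z2 == 0))
        stop("angular decode undefined for the zero vector")
    a <- atan2(z2, z1) %% (2 * pi)
    a / pi - 1
}

#' Circular distance between two decoded positions
#'
#' Distance on the periodic interval [-1, 1) (period 2), used to score
#' position-decoding error.
#'
#' @param a,b Numeric vectors in [-1, 1).
#' @return Numeric vector of distances in [0, 1].
#' @export
circularDistance <- function(a, b) {
    d <- (a - b) %% 2
    pmin(d, 2 - d)
}

#' Construct a grid-module specification
#'
#' @param frequencies Integer vector of per-module frequency exponents; the
#'   first must be 0 and the sequence nondecreasing. Module j encodes
#'   position at angular frequency \eqn{(3/2)^{f_j}}.
#' @return A [GridModuleSpec-class].
#' @examples
#' gridModuleSpec(c(0, 1, 2))
#' @export
gridModuleSpec <- function(frequencies = 0L) {
    f <- as.integer(frequencies)
    new("GridModuleSpec", m = length(f), frequencies = f)
}

#' Multi-module grid encoding of position
#'
#' Each module j maps \eqn{p} to the angle
#' \eqn{\alpha_j = (3/2)^{f_j} \pi (p + 1)} and contributes a (cos, sin)
#' pair; pairs are concatenated over modules. Module 1 (frequency exponent 0)
#' reproduces [encodeAngular] exactly and is the positional readout.
#'
#' @param p Numeric vector in [-1, 1].
#' @param spec A [GridModuleSpec-class].
#' @return Numeric matrix (2 m x length(p)).
#' @export
encodeGrid <- function(p, spec) {
    stopifnot(is(spec, "GridModuleSpec"))
    validObject(spec)
    if (!is.numeric(p) || any(!is.finite(p)))
        stop("p must be finite numeric")
    if (any(p < -1 | p > 1))
        stop("p must lie in [-1, 1]")
    out <- matrix(0, nrow = 2L * spec@m, ncol = length(p))
    for (j in seq_len(spec@m)) {
        a <- (3 / 2)^spec@frequencies[j] * pi * (p + 1)
        out[2L * j - 1L, ] <- cos(a)
        out[2L * j, ] <- sin(a)
    }
    out
}

#' Decode position from the first grid module
#'
#' With the first module pinned to a single period over [-1, 1], position is
#' read from its (cos, sin) pair alone; higher-frequency modules are ignored
#' by this simplified readout.
#'
#' @param z Numeric matrix (2 m x n) or vector (length 2 m), grid-encoded
#'   latents grouped by module.
#' @return Numeric vector of decoded positions in [-1, 1).
#' @export
decodeGridPosition <- function(z) {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
    if (nrow(z) < 2L) stop("need at least one (cos, sin) module pair")
    decodeAngular(z[1L, ], z[2L, ])
}

#' Normalise a latent vector part-wise
#'
#' Rescales each labelled part (e.g. positional block, cognitive block) of
#' every column to a fixed norm so that the full column has unit norm:
#' with two parts each gets norm \eqn{1/\sqrt 2}; with a single part it gets
#' norm 1. Columnwise over matrices; idempotent.
#'
#' @param z Numeric matrix (Z x n) or vector.
#' @param parts Named list of integer row-index vectors partitioning the
#'   rows of `z`.
#' @param partNorms Optional numeric vector of target norms, one per part;
#'   defaults to `1/sqrt(length(parts))` each.
#' @return Matrix of the same shape with each part at its target norm.
#' @export
normalizeLatent <- function(z, parts, partNorms = NULL) {
    drop1 <- is.null(dim(z))
    if (drop1) z <- matrix(z, ncol = 1L)
    if (!length(parts)) stop("parts must name at least one row block")
    idx <- sort(unlist(parts, use.names = FALSE))
    if (!identical(idx, seq_len(nrow(z))))
        stop("parts must partition the rows of z")
    if (is.null(partNorms))
        partNorms <- rep(1 / sqrt(length(parts)), length(parts))
    if (length(partNorms) != length(parts))
        stop("need one target norm per part")
    for (k in seq_along(parts)) {
        rows <- parts[[k]]
        nrm <- sqrt(colSums(z[rows, , drop = FALSE]^2))
        if (any(nrm == 0))
            stop("cannot normalise a zero-norm part")
        z[rows, ] <- sweep(z[rows, , drop = FALSE], 2L,
                           partNorms[k] / nrm, `*`)
    }
    if (drop1) z[, 1L] else z
}

## ---------------------------------------------------------------------------
## LatentTrajectory construction
## ---------------------------------------------------------------------------

#' Build the latent trajectory for a position grid
#'
#' Applies the angular (or multi-module grid) encoding independently to each
#' positional coordinate, appends angular-encoded cognitive variables if
#' given, and normalises positional and cognitive parts so each column of z
#' has unit norm. Row layout: for each positional dimension i, modules
#' j = 1..m contribute a (cos, sin) pair; then one pair per cognitive
#' variable.
#'
#' @param grid A [PositionGrid-class].
#' @param gridSpec A [GridModuleSpec-class]; default is a single module.
#' @param cognitive Optional numeric matrix (C x n_points) of cognitive
#'   values in [-1, 1] (e.g. from [makeCognitiveTrajectory]).
#' @param normalize Logical; part-normalise the columns (default TRUE).
#' @param includePosition Logical; set FALSE for implicit-space coding,
#'   where the grid describes the physical track but position itself is not
#'   represented in the latent (P = 0).
#' @return A [LatentTrajectory-class].
#' @export
makeLatentTrajectory <- function(grid, gridSpec = gridModuleSpec(0L),
                                 cognitive = NULL, normalize = TRUE,
                                 includePosition = TRUE) {
    stopifnot(is(grid, "PositionGrid"), is(gridSpec, "GridModuleSpec"))
    pts <- grid@points
    P <- if (includePosition) grid@dims else 0L
    m <- gridSpec@m
    n <- nrow(pts)
    C <- if (is.null(cognitive)) 0L else nrow(cognitive)
    if (C > 0L && ncol(cognitive) != n)
        stop("cognitive matrix must have one column per grid point")
    if (P == 0L && C == 0L)
        stop("the latent must include position or at least one cognitive ",
             "variable")

    blocks <- vector("list", P + C)
    for (i in seq_len(P))
        blocks[[i]] <- encodeGrid(pts[, i], gridSpec)
    if (C > 0L)
        for (k in seq_len(C))
            blocks[[P + k]] <- encodeAngular(cognitive[k, ])
    z <- do.call(rbind, blocks)

    posRows <- seq_len(2L * m * P)
    cogRows <- if (C > 0L) 2L * m * P + seq_len(2L * C) else integer()
    parts <- list()
    if (P > 0L) parts$positional <- posRows
    if (C > 0L) parts$cognitive <- cogRows
    if (normalize) z <- normalizeLatent(z, parts)

    new(Class = "LatentTrajectory", positions = grid, z = z, parts = parts,
        P = P, C = C, m = m)
}
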