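#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

## ---------------------------------------------------------------------------
## PositionGrid
## ---------------------------------------------------------------------------

#' PositionGrid: a regular lattice of positions on [-1, 1)^P
#'
#' Positions are discretised on an equally-spaced grid over the periodic
#' square \eqn{[-1, 1)^P}; the upper edge is excluded because \eqn{p = 1} and
#' \eqn{p = -1} are identified by the angular code. Rows of `points` are
#' positions in row-major order over the lattice.
#'
#' @slot dims Integer, number of positional variables P.
#' @slot resolution Integer, grid points per dimension.
#' @slot points Numeric matrix (n_points x P) of coordinates in [-1, 1).
#' @slot spacing Numeric, uniform step per dimension.
#' @export
setClass("PositionGrid",
    representation(dims = "integer", resolution = "integer",
                   points = "matrix", spacing = "numeric"))

setValidity("PositionGrid", function(object) {
    msg <- character()
    pts <- object@points
    if (ncol(pts) != object@dims)
        msg <- c(msg, "points must have one column per positional variable")
    if (nrow(pts) != object@resolution^object@dims)
        msg <- c(msg, "point count must equal resolution^dims")
    if (length(pts) && (min(pts) < -1 || max(pts) >= 1))
        msg <- c(msg, "all coordinates must lie in [-1, 1)")
    if (anyDuplicated(pts))
        msg <- c(msg, "grid points must be unique")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GridModuleSpec
## ---------------------------------------------------------------------------

#' GridModuleSpec: spatial-frequency layout of grid modules
#'
#' Each module j encodes position at angular frequency \eqn{(3/2)^{f_j}}.
#' The first module is pinned to frequency exponent 0 so that it forms a
#' bijection with position and can serve as the positional readout.
#'
#' @slot m Integer, number of modules (>= 1).
#' @slot frequencies Integer vector of frequency exponents, f[1] = 0,
#'   nondecreasing.
#' @export
setClass("GridModuleSpec",
    representation(m = "integer", frequencies = "integer"))

setValidity("GridModuleSpec", function(object) {
    msg <- character()
    f <- object@frequencies
    if (object@m < 1L) msg <- c(msg, "m must be >= 1")
    if (length(f) != object@m)
        msg <- c(msg, "frequencies must have one entry per module")
    if (length(f) && f[1L] != 0L)
        msg <- c(msg, "the first module must have frequency exponent 0")
    if (length(f) && any(f < 0L))
        msg <- c(msg, "frequency exponents must be nonnegative")
    if (length(f) > 1L && any(diff(f) < 0L))
        msg <- c(msg, "frequency exponents must be nondecreasing")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CognitiveSpec
## ---------------------------------------------------------------------------

#' CognitiveSpec: generator settings for cognitive-variable trajectories
#'
#' A cognitive variable is a constant environment-specific offset plus a
#' smooth Gaussian-process fluctuation over position, wrapped back into
#' [-1, 1). One parameter `sigma` controls both the offset scale and the GP
#' marginal standard deviation; `lengthscale` is the GP kernel lengthscale on
#' the [-1, 1] position scale.
#'
#' @slot C Integer, number of cognitive variables.
#' @slot sigma Numeric in [0, 1].
#' @slot lengthscale Numeric > 0.
#' @slot seed Integer seed.
#' @export
setClass("CognitiveSpec",
    representation(C = "integer", sigma = "numeric",
                   lengthscale = "numeric", seed = "integer"))

setValidity("CognitiveSpec", function(object) {
    msg <- character()
    if (object@C < 0L) msg <- c(msg, "C must be >= 0")
    if (object@sigma < 0 || object@sigma > 1)
        msg <- c(msg, "sigma must lie in [0, 1]")
    if (object@lengthscale <= 0)
        msg <- c(msg, "lengthscale must be > 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## LatentTrajectory
## ---------------------------------------------------------------------------

#' LatentTrajectory: angular latent variables over a position grid
#'
#' Columns of `z` are latent vectors for successive grid points. Rows are
#' organised as P x m positional (cos, sin) pairs followed by C cognitive
#' pairs; `parts` holds the positional and cognitive row-index blocks used
#' for part-wise normalisation.
#'
#' @slot positions A [PositionGrid-class].
#' @slot z Numeric matrix (Z x n_points).
#' @slot parts Named list of integer row-index vectors
#'   (`positional`, `cognitive`).
#' @slot P,C,m Integers describing the layout (Z = 2*m*P + 2*C).
#' @export
setClass("LatentTrajectory",
    representation(positions = "PositionGrid", z = "matrix", parts = "list",
                   P = "integer", C = "integer", m = "integer"))

setValidity("LatentTrajectory", function(object) {
    msg <- character()
    Z <- 2L * object@m * object@P + 2L * object@C
    if (nrow(object@z) != Z)
        msg <- c(msg, "z must have 2*m*P + 2*C rows")
    if (ncol(object@z) != nrow(object@positions@points))
        msg <- c(msg, "z must have one column per grid point")
    idx <- sort(unlist(object@parts, use.names = FALSE))
    if (length(idx) && !identical(idx, seq_len(Z)))
        msg <- c(msg, "parts must partition the latent rows")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EmbeddingMap
## ---------------------------------------------------------------------------

#' EmbeddingMap: environment-specific latent-to-embedding rotation
#'
#' A column-orthonormal matrix R (Y x Z) carrying the latent trajectory into
#' the embedding space: `multichart` maps are uniform random column-isometries,
#' `grid_realignment` maps are block-diagonal per-module 2x2 rotations, and
#' `identity` is used by mixed-selective scenarios.
#'
#' @slot R Numeric matrix (Y x Z) with orthonormal columns.
#' @slot scenario One of "multichart", "grid_realignment", "identity".
#' @slot seed Integer seed used to draw the map (NA for identity).
#' @export
setClass("EmbeddingMap",
    representation(R = "matrix", scenario = "character", seed = "integer"))

setValidity("EmbeddingMap", function(object) {
    msg <- character()
    R <- object@R
    if (ncol(R) > nrow(R))
        msg <- c(msg, "embedding dimension Y must be >= latent dimension Z")
    G <- crossprod(R)
    if (max(abs(G - diag(ncol(R)))) > 1e-10)
        msg <- c(msg, "columns of R must be orthonormal (R'R = I to 1e-10)")
    if (!object@scenario %in% c("multichart", "grid_realignment", "identity"))
        msg <- c(msg, "unknown embedding-map scenario")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DecoderBank
## ---------------------------------------------------------------------------

#' DecoderBank: linear decoder, derived encoder and weight code
#'
#' D (Y x N) holds one decoding-weight column per neuron; E is the right
#' pseudo-inverse of D (so D E = Id_Y). The `code` records the normalisation
#' applied to the random weights: mixed (M, unit columns), conjunctive (C,
#' equal-norm row pairs), conjunctive-mixed (CM, equal positional/cognitive
#' blocks), pure-and-mixed (pM, some purely positional / purely cognitive
#' neurons) or identity.
#'
#' @slot D Numeric matrix (Y x N).
#' @slot E Numeric matrix (N x Y), right pseudo-inverse of D.
#' @slot code One of "M", "C", "CM", "pM", "identity".
#' @slot partLabels Named list of integer row-index vectors of D
#'   (`positional`, `cognitive`); may be empty for M/C/identity codes.
#' @slot seed Integer seed.
#' @export
setClass("DecoderBank",
    representation(D = "matrix", E = "matrix", code = "character",
                   partLabels = "list", seed = "integer"))

setValidity("DecoderBank", function(object) {
    msg <- character()
    D <- object@D; E <- object@E
    if (!object@code %in% c("M", "C", "CM", "pM", "identity"))
        msg <- c(msg, "unknown decoder code")
    if (nrow(E) != ncol(D) || ncol(E) != nrow(D))
        msg <- c(msg, "E must be the (N x Y) right pseudo-inverse of D")
    else if (max(abs(D %*% E - diag(nrow(D)))) > 1e-8)
        msg <- c(msg, "D %*% E must equal the identity to 1e-8")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ThresholdVector
## ---------------------------------------------------------------------------

#' ThresholdVector: per-neuron firing thresholds with optional suppression
#'
#' The optimal (default) threshold of neuron i is half its squared
#' decoding-weight norm. Suppression raises selected thresholds to `Tsuppr`
#' (default 10, about 10x the normal value), silencing those neurons while
#' leaving the decoded latents to be carried by the rest of the population.
#'
#' @slot values Numeric nonnegative vector of length N.
#' @slot suppressed Integer indices currently held at `Tsuppr`.
#' @slot Tsuppr Numeric, the elevated threshold value.
#' @export
setClass("ThresholdVector",
    representation(values = "numeric", suppressed = "integer",
                   Tsuppr = "numeric"))

setValidity("ThresholdVector", function(object) {
    msg <- character()
    if (any(object@values < 0)) msg <- c(msg, "thresholds must be >= 0")
    s <- object@suppressed
    if (length(s) && (any(s < 1L) || any(s > length(object@values))))
        msg <- c(msg, "suppressed indices out of range")
    if (length(s) && any(object@values[s] != object@Tsuppr))
        msg <- c(msg, "suppressed entries must equal Tsuppr")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RateMap
## ---------------------------------------------------------------------------

#' RateMap: steady-state firing rates over a position grid
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are neurons, columns are
#' grid positions. Assays `rates` (nonnegative steady-state rates) and
#' `nullPart` (the component of the rates in the decoder's null space,
#' rates - E D rates). `colData` carries the position coordinates and
#' per-position solver diagnostics (objective, KKT residual); the decoded
#' embedding D %*% rates is kept in the `decoded` slot.
#'
#' @slot decoded Numeric matrix (Y x n_points), the linear readout D r.
#' @slot environment Character label of the simulated environment/condition.
#' @export
setClass("RateMap",
    contains = "SummarizedExperiment",
    representation(decoded = "matrix", environment = "character"))

setValidity("RateMap", function(object) {
    msg <- character()
    if (!all(c("rates", "nullPart") %in% names(assays(object))))
        msg <- c(msg, "RateMap needs assays 'rates' and 'nullPart'")
    else {
        r <- assay(object, "rates")
        if (min(r) < 0) msg <- c(msg, "rates must be nonnegative")
        if (!identical(dim(r), dim(assay(object, "nullPart"))))
            msg <- c(msg, "assay dimensions must agree")
    }
    if (ncol(object@decoded) != ncol(object))
        msg <- c(msg, "decoded must have one column per position")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ExperimentConfig
## ---------------------------------------------------------------------------

.remapScenarios <- c("multichart_lowD", "multichart_fullD",
                     "grid_realignment", "space_feature", "implicit_space",
                     "null_space_birth", "null_space_suppress")

#' ExperimentConfig: a validated remapping-scenario configuration
#'
#' Bundles network size (N), variable counts (P positional, C cognitive),
#' grid modules (m, frequency exponents), embedding dimension (Y), number of
#' environments (K), grid resolution, the cognitive generator settings, the
#' decoder weight code, the embedding rescale exponent, the suppression
#' fraction for null-space protocols, and the master seed. Scenario-specific
#' constraints are enforced at construction.
#'
#' @slot scenario One of the supported scenario names.
#' @slot N,P,C,m,Y,K,resolution Integers.
#' @slot frequencies Integer frequency exponents (grid scenarios).
#' @slot sigma,lengthscale Cognitive generator parameters.
#' @slot code Decoder weight code.
#' @slot rescaleExponent Exponent q in the embedding rescale y <- Y^q y.
#' @slot spar Suppression fraction for null-space protocols.
#' @slot Tsuppr Elevated threshold used for suppression.
#' @slot seed Master integer seed.
#' @export
setClass("ExperimentConfig",
    representation(scenario = "character", N = "integer", P = "integer",
                   C = "integer", m = "integer", frequencies = "integer",
                   Y = "integer", K = "integer", resolution = "integer",
                   sigma = "numeric", lengthscale = "numeric",
                   code = "character", rescaleExponent = "numeric",
                   spar = "numeric", Tsuppr = "numeric", seed = "integer"))

setValidity("ExperimentConfig", function(object) {
    msg <- character()
    s <- object@scenario
    Z <- 2L * object@m * object@P + 2L * object@C
    if (!s %in% .remapScenarios)
        msg <- c(msg, paste0("unknown scenario '", s, "'"))
    if (object@resolution < 2L) msg <- c(msg, "resolution must be >= 2")
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (object@spar < 0 || object@spar > 1)
        msg <- c(msg, "spar must lie in [0, 1]")
    if (!object@rescaleExponent %in% c(0, 0.5, 1))
        msg <- c(msg, "rescaleExponent must be one of 0, 0.5, 1")
    if (s %in% c("multichart_lowD", "null_space_birth",
                 "null_space_suppress")) {
        if (object@C != 0L) msg <- c(msg, paste0(s, " requires C = 0"))
        if (object@m != 1L) msg <- c(msg, paste0(s, " requires m = 1"))
        if (object@Y < Z || object@Y > object@N)
            msg <- c(msg, "multichart requires Z <= Y <= N")
        if (object@code != "M")
            msg <- c(msg, paste0(s, " uses the M code"))
    }
    if (s == "multichart_fullD") {
        if (object@C != 0L || object@m != 1L)
            msg <- c(msg, "multichart_fullD requires C = 0, m = 1")
        if (object@Y != object@N)
            msg <- c(msg, "multichart_fullD requires Y = N")
        if (object@code != "identity")
            msg <- c(msg, "multichart_fullD uses the identity code")
    }
    if (s == "grid_realignment") {
        if (object@C != 0L) msg <- c(msg, "grid_realignment requires C = 0")
        if (object@m < 2L) msg <- c(msg, "grid_realignment requires m >= 2")
        if (object@Y != Z) msg <- c(msg, "grid_realignment requires Y = Z")
        if (object@code != "C")
            msg <- c(msg, "grid_realignment uses the C code")
        if (length(object@frequencies) != object@m)
            msg <- c(msg, "frequencies must have one entry per module")
    }
    if (s == "space_feature") {
        if (object@P < 1L || object@C < 1L)
            msg <- c(msg, "space_feature requires P >= 1 and C >= 1")
        if (object@m != 1L) msg <- c(msg, "space_feature requires m = 1")
        if (object@Y != Z) msg <- c(msg, "space_feature requires Y = Z")
        if (!object@code %in% c("CM", "pM"))
            msg <- c(msg, "space_feature uses the CM (or pM) code")
    }
    if (s == "implicit_space") {
        if (object@P != 0L) msg <- c(msg, "implicit_space requires P = 0")
        if (object@C < 1L) msg <- c(msg, "implicit_space requires C >= 1")
        if (object@Y != Z) msg <- c(msg, "implicit_space requires Y = Z")
        if (object@code != "M")
            msg <- c(msg, "implicit_space uses the M code")
    }
    if (s %in% c("null_space_birth", "null_space_suppress") &&
        object@K != 1L)
        msg <- c(msg, "null-space scenarios use a single environment")
    if (object@N < object@Y && object@code != "identity")
        msg <- c(msg, "N must be >= Y for the pseudo-inverse to exist")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RemappingRun
## ---------------------------------------------------------------------------

#' RemappingRun: one simulated remapping experiment
#'
#' Holds the validated configuration, the decoder bank shared across
#' environments, and one entry per environment with the latent trajectory,
#' embedding map, thresholds, the embedding input y, and the solved
#' \linkS4class{RateMap}.
#'
#' @slot config An [ExperimentConfig-class].
#' @slot decoder A [DecoderBank-class], fixed across environments.
#' @slot environments List (length K) of per-environment lists with elements
#'   `latent`, `map`, `thresholds`, `y`, `rateMap`, `seed`.
#' @export
setClass("RemappingRun",
    representation(config = "ExperimentConfig", decoder = "DecoderBank",
                   environments = "list"))

## ---------------------------------------------------------------------------
## RemappingStats
## ---------------------------------------------------------------------------

#' RemappingStats: overlap and spatial-correlation statistics for a run
#'
#' Per-environment-pair overlap (cosine similarity of mean rate vectors) and
#' spatial correlation (mean over co-active neurons of rate-profile cosines),
#' shuffle-control values, grand means, standardized effect sizes and
#' one-sample t-tests of the pairwise values against the shuffle grand mean.
#'
#' @slot pairs A data.frame with one row per unordered environment pair.
#' @slot overlap Named list: mean, shuffleMean, shuffleSD, effect, t, p,
#'   significant, degenerate.
#' @slot spatialCorr Same structure as `overlap`.
#' @slot nShuffles Integer shuffle realizations per pair.
#' @slot nTests Integer Bonferroni divisor used.
#' @slot seed Integer seed of the shuffle stream.
#' @export
setClass("RemappingStats",
    representation(pairs = "data.frame", overlap = "list",
                   spatialCorr = "list", nShuffles = "integer",
                   nTests = "integer", seed = "integer"))
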