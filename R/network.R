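## The autoencoder network: decoder-weight sampling under the M / C / CM /
## pM / identity codes, pseudo-inverse encoder, thresholds with suppression,
## and the nonnegative-QP steady-state rate solver with null decomposition.

## right pseudo-inverse of a full-row-rank Y x N matrix
.rightPinv <- function(D) {
    G <- tcrossprod(D)                      # D D' (Y x Y)
    E <- tryCatch(t(D) %*% solve(G),
                  error = function(e)
                      stop("decoder matrix is rank deficient: ",
                           conditionMessage(e)))
    if (max(abs(D %*% E - diag(nrow(D)))) > 1e-8)
        stop("decoder matrix is numerically rank deficient")
    E
}

#' Sample a decoder bank
#'
#' Draws i.i.d. Gaussian decoding weights D (Y x N, one column per neuron)
#' and applies the requested normalisation code:
#' \describe{
#'   \item{M}{mixed: every column normalised to unit norm (uniform on the
#'     (Y-1)-sphere).}
#'   \item{C}{conjunctive: each consecutive (cos, sin) row pair of each
#'     column normalised to \eqn{\sqrt{2/Y}}, so the full column is unit
#'     norm and every latent angle receives equal-magnitude weight.}
#'   \item{CM}{conjunctive-mixed: the positional row block is conjunctive
#'     across its pairs and the cognitive block left mixed, with each block
#'     normalised to \eqn{1/\sqrt 2} so both variable types carry equal
#'     overall weight.}
#'   \item{pM}{pure-and-mixed: the first `pureCounts[1]` neurons have zero
#'     cognitive rows, the next `pureCounts[2]` zero positional rows (each
#'     nonzero block normalised to unit column norm), the rest follow the M
#'     code.}
#'   \item{identity}{D = Id_N (full-dimensional multi-chart case).}
#' }
#' The encoder E is the right pseudo-inverse of D.
#'
#' @param N Number of neurons.
#' @param Y Embedding dimensionality (N >= Y except for identity).
#' @param code One of "M", "C", "CM", "pM", "identity".
#' @param partLabels Named list with integer row indices `positional` and
#'   `cognitive` (required for CM and pM).
#' @param pureCounts Integer vector (pureP, pureC) for the pM code.
#' @param seed Integer seed.
#' @return A [DecoderBank-class].
#' @export
sampleDecoder <- function(N, Y, code = c("M", "C", "CM", "pM", "identity"),
                          partLabels = list(), pureCounts = c(0L, 0L),
                          seed = 1L) {
    code <- match.arg(code)
    N <- as.integer(N); Y <- as.integer(Y)
    if (code == "identity") {
        D <- diag(N)
        return(new("DecoderBank", D = D, E = D, code = code,
                   partLabels = partLabels, seed = as.integer(seed)))
    }
    if (N < Y) stop("N must be >= Y for the pseudo-inverse to exist")
    D <- withSeed(seed, matrix(stats::rnorm(Y * N), nrow = Y))
    normCols <- function(M, target = 1) {
        nrm <- sqrt(colSums(M^2))
        if (any(nrm == 0)) stop("degenerate zero column drawn")
        sweep(M, 2L, target / nrm, `*`)
    }
    if (code == "M") {
        D <- normCols(D)
    } else if (code == "C") {
        if (Y %% 2L != 0L) stop("C code requires even Y")
        for (j in seq_len(Y %/% 2L)) {
            rows <- (2L * j - 1L):(2L * j)
            D[rows, ] <- normCols(D[rows, , drop = FALSE], sqrt(2 / Y))
        }
    } else if (code == "CM") {
        pos <- partLabels$positional; cog <- partLabels$cognitive
        if (is.null(pos) || is.null(cog))
            stop("CM code needs positional and cognitive part labels")
        npairs <- length(pos) %/% 2L
        for (j in seq_len(npairs)) {        # conjunctive positional pairs
            rows <- pos[(2L * j - 1L):(2L * j)]
            D[rows, ] <- normCols(D[rows, , drop = FALSE],
                                  sqrt(1 / (2 * npairs)))
        }
        D[cog, ] <- normCols(D[cog, , drop = FALSE], 1 / sqrt(2))
    } else if (code == "pM") {
        pos <- partLabels$positional; cog <- partLabels$cognitive
        if (is.null(pos) || is.null(cog))
            stop("pM code needs positional and cognitive part labels")
        pureP <- as.integer(pureCounts[1L]); pureC <- as.integer(pureCounts[2L])
        if (pureP + pureC > N) stop("pure counts exceed N")
        if (pureP > 0L) {
            ip <- seq_len(pureP)
            D[cog, ip] <- 0
            D[pos, ip] <- normCols(D[pos, ip, drop = FALSE])
        }
        if (pureC > 0L) {
            ic <- pureP + seq_len(pureC)
            D[pos, ic] <- 0
            D[cog, ic] <- normCols(D[cog, ic, drop = FALSE])
        }
        rest <- setdiff(seq_len(N), seq_len(pureP + pureC))
        if (length(rest))
            D[, rest] <- normCols(D[, rest, drop = FALSE])
    }
    new("DecoderBank", D = D, E = .rightPinv(D), code = code,
        partLabels = partLabels, seed = as.integer(seed))
}

#' Optimal firing thresholds
#'
#' The threshold that makes the steady-state network an exact autoencoder
#' penalty: \eqn{T_i = \frac12 \|D_i\|^2} (half the squared decoding-weight
#' norm, i.e. 1/2 for unit-norm columns).
#'
#' @param D A [DecoderBank-class] or a numeric decoder matrix (Y x N).
#' @return A [ThresholdVector-class].
#' @export
optimalThresholds <- function(D) {
    Dm <- if (is(D, "DecoderBank")) D@D else D
    new("ThresholdVector", values = 0.5 * colSums(Dm^2),
        suppressed = integer(), Tsuppr = 10)
}

#' Suppress a random fraction of neurons
#'
#' Chooses `floor(N * spar)` neurons uniformly at random (excluding already
#' suppressed ones when `from` is given) and raises their thresholds to
#' `Tsuppr`, silencing them for any bounded drive.
#'
#' @param T A [ThresholdVector-class].
#' @param spar Fraction in [0, 1] of the candidate pool to suppress.
#' @param seed Integer seed.
#' @param Tsuppr Elevated threshold (default 10).
#' @param from Optional integer vector of candidate indices; defaults to all
#'   neurons.
#' @return A new [ThresholdVector-class].
#' @export
suppress <- function(T, spar, seed = 1L, Tsuppr = 10, from = NULL) {
    stopifnot(is(T, "ThresholdVector"))
    if (spar < 0 || spar > 1) stop("spar must lie in [0, 1]")
    N <- length(T@values)
    pool <- if (is.null(from)) seq_len(N) else as.integer(from)
    k <- floor(length(pool) * spar)
    pick <- if (k == 0L) integer() else
        withSeed(seed, sort(sample(pool, k)))
    v <- T@values
    v[pick] <- Tsuppr
    new("ThresholdVector", values = v,
        suppressed = sort(union(T@suppressed[v[T@suppressed] == Tsuppr],
                                pick)),
        Tsuppr = Tsuppr)
}

#' Release suppressed neurons
#'
#' Restores a seeded random subset of the currently suppressed neurons to
#' the reference thresholds (modelling, e.g., newly participating cells).
#'
#' @param T A [ThresholdVector-class] with suppressed neurons.
#' @param reference A [ThresholdVector-class] supplying the restored values
#'   (typically [optimalThresholds]).
#' @param fraction Fraction of the candidate suppressed set to release.
#' @param seed Integer seed.
#' @param from Optional integer vector restricting the candidate pool;
#'   defaults to every currently suppressed neuron.
#' @return A new [ThresholdVector-class].
#' @export
release <- function(T, reference, fraction, seed = 1L, from = NULL) {
    stopifnot(is(T, "ThresholdVector"), is(reference, "ThresholdVector"))
    s <- if (is.null(from)) T@suppressed
         else intersect(T@suppressed, as.integer(from))
    k <- floor(length(s) * fraction)
    pick <- if (k == 0L) integer() else withSeed(seed, sort(sample(s, k)))
    v <- T@values
    v[pick] <- reference@values[pick]
    new("ThresholdVector", values = v,
        suppressed = setdiff(T@suppressed, pick), Tsuppr = T@Tsuppr)
}

#' Steady-state firing rates for one embedding input
#'
#' Solves the convex program
#' \deqn{r^* = \arg\min_{r \ge 0} \|y - D r\|^2 + 2 T^\top r}
#' the steady state of the competitive autoencoder network. Deterministic
#' cyclic coordinate descent from a cold start; the KKT residual contract is
#' 1e-7 (stationarity for active neurons, dual feasibility for silent ones).
#'
#' @param y Numeric vector (length Y).
#' @param D A [DecoderBank-class] or decoder matrix.
#' @param T A [ThresholdVector-class] or numeric threshold vector.
#' @param tol Internal solver tolerance (default 1e-9).
#' @param maxSweeps Sweep budget before declaring non-convergence.
#' @return List with `rates`, `objective`, `kkt`, `sweeps`.
#' @export
steadyStateRates <- function(y, D, T, tol = 1e-9, maxSweeps = 200000L) {
    Dm <- if (is(D, "DecoderBank")) D@D else D
    Tv <- if (is(T, "ThresholdVector")) T@values else T
    if (any(Tv < 0)) stop("thresholds must be nonnegative")
    sol <- .nnqpSolve(Dm, matrix(y, ncol = 1L), Tv, tol = tol,
                      maxSweeps = maxSweeps)
    if (sol$kkt[1L] > 1e-7)
        stop(sprintf(paste0("QP solver did not reach the KKT contract: ",
                            "residual %.3e after %d sweeps"),
                     sol$kkt[1L], sol$sweeps[1L]))
    list(rates = sol$rates[, 1L], objective = sol$objective[1L],
         kkt = sol$kkt[1L], sweeps = sol$sweeps[1L])
}

#' Solve the steady-state rates over a whole position grid
#'
#' Runs [steadyStateRates] for every column of `y` and assembles a
#' [RateMap-class]: nonnegative rates, the linear readout D r, and the
#' null-space component r - E D r (which D maps to zero). Rates below 1e-12
#' are clamped to exact zero.
#'
#' @param y Numeric matrix (Y x n_points) of embedding inputs.
#' @param D A [DecoderBank-class].
#' @param T A [ThresholdVector-class] or numeric vector.
#' @param positions Optional [PositionGrid-class] for the column metadata.
#' @param environment Character label.
#' @param tol,maxSweeps Solver settings as in [steadyStateRates].
#' @return A [RateMap-class].
#' @export
runRateMap <- function(y, D, T, positions = NULL, environment = "env",
                       tol = 1e-9, maxSweeps = 200000L) {
    stopifnot(is(D, "DecoderBank"))
    Tv <- if (is(T, "ThresholdVector")) T@values else T
    sol <- .nnqpSolve(D@D, y, Tv, tol = tol, maxSweeps = maxSweeps)
    bad <- which(sol$kkt > 1e-7)
    if (length(bad))
        stop(sprintf(paste0("QP solver failed the KKT contract at %d ",
                            "position(s); worst residual %.3e (column %d)"),
                     length(bad), max(sol$kkt), which.max(sol$kkt)))
    r <- sol$rates
    r[r < 1e-12] <- 0
    decoded <- D@D %*% r
    nullPart <- r - D@E %*% decoded
    cd <- S4Vectors::DataFrame(objective = as.numeric(sol$objective),
                               kkt = as.numeric(sol$kkt),
                               sweeps = as.integer(sol$sweeps))
    if (!is.null(positions)) {
        pts <- positions@points
        colnames(pts) <- paste0("p", seq_len(ncol(pts)))
        cd <- cbind(S4Vectors::DataFrame(pts), cd)
    }
    suppressed <- if (is(T, "ThresholdVector")) T@suppressed else integer()
    rd <- S4Vectors::DataFrame(threshold = Tv,
                               suppressed = seq_len(nrow(r)) %in% suppressed)
    se <- SummarizedExperiment(
        assays = list(rates = r, nullPart = nullPart),
        rowData = rd, colData = cd)
    new("RateMap", se, decoded = decoded, environment = environment)
}

#' Feedforward rate approximation
#'
#' The visualisation-only linear approximation \eqn{\tilde r = D^\top y};
#' entries may be negative.
#'
#' @param y Numeric matrix (Y x n) or vector.
#' @param D A [DecoderBank-class] or decoder matrix.
#' @return Numeric matrix (N x n).
#' @export
feedforwardRates <- function(y, D) {
    Dm <- if (is(D, "DecoderBank")) D@D else D
    if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
    crossprod(Dm, y)
}

#' Decode environmental variables from firing rates
#'
#' Reads the embedding estimate \eqn{\hat y = D r}, undoes the embedding
#' rescale and rotation (\eqn{\hat z = R^\top \hat y / s}), and applies the
#' angular decode to recover position (module-1 pair per positional
#' dimension) and cognitive variables. Position decoding is refused for
#' implicit-space runs (no positional latent exists).
#'
#' @param rates Numeric matrix (N x n) or a [RateMap-class].
#' @param D A [DecoderBank-class].
#' @param map An [EmbeddingMap-class] (identity for MS scenarios).
#' @param latent A [LatentTrajectory-class] providing the row layout.
#' @param rescaleExponent Exponent used when the input was rescaled.
#' @param decodePosition Logical; set FALSE to skip the positional readout
#'   (required for implicit-space runs, where requesting it is an error).
#' @return List with `zhat` (Z x n), `phat` (P x n or NULL), `chat`
#'   (C x n or NULL).
#' @export
decodeEnvironment <- function(rates, D, map, latent, rescaleExponent = 1,
                              decodePosition = TRUE) {
    r <- if (is(rates, "RateMap")) rates(rates) else rates
    stopifnot(is(D, "DecoderBank"), is(map, "EmbeddingMap"),
              is(latent, "LatentTrajectory"))
    if (decodePosition && latent@P == 0L)
        stop("position cannot be decoded from an implicit-space run: ",
             "no positional latent exists")
    yhat <- D@D %*% r
    s <- as.numeric(nrow(D@D))^rescaleExponent
    zhat <- crossprod(map@R, yhat) / s
    P <- latent@P; C <- latent@C; m <- latent@m
    phat <- NULL
    if (decodePosition) {
        phat <- matrix(0, P, ncol(zhat))
        for (i in seq_len(P)) {
            base <- (i - 1L) * 2L * m     # module-1 pair of dimension i
            phat[i, ] <- decodeAngular(zhat[base + 1L, ], zhat[base + 2L, ])
        }
    }
    chat <- NULL
    if (C > 0L) {
        chat <- matrix(0, C, ncol(zhat))
        off <- 2L * m * P
        for (k in seq_len(C))
            chat[k, ] <- decodeAngular(zhat[off + 2L * k - 1L, ],
                                       zhat[off + 2L * k, ])
    }
    list(zhat = zhat, phat = phat, chat = chat)
}
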