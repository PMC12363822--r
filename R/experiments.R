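## Scenario orchestration: build environment sets for the remapping types
## and produce per-environment rate maps with full provenance.

#' Build a regular position grid
#'
#' Uniform lattice over the periodic square [-1, 1)^P, endpoint-exclusive on
#' the upper edge because p = 1 is identified with p = -1 by the angular
#' code. Points are ordered with the first coordinate varying fastest.
#'
#' @param P Number of positional dimensions.
#' @param resolution Points per dimension (>= 2).
#' @return A [PositionGrid-class].
#' @examples
#' positionPoints(buildPositionGrid(1, 5))[, 1]  # -1 -0.6 -0.2 0.2 0.6
#' @export
buildPositionGrid <- function(P, resolution) {
    P <- as.integer(P); resolution <- as.integer(resolution)
    if (resolution < 2L) stop("resolution must be >= 2")
    axis <- -1 + 2 * (seq_len(resolution) - 1L) / resolution
    pts <- as.matrix(expand.grid(rep(list(axis), P)))
    dimnames(pts) <- NULL
    new("PositionGrid", dims = P, resolution = resolution,
        points = pts, spacing = 2 / resolution)
}

#' Construct and validate an experiment configuration
#'
#' Fills scenario-appropriate defaults (decoder code, Y, frequencies,
#' resolution) and enforces the scenario invariants; see
#' [ExperimentConfig-class] for the constraints.
#'
#' @param scenario One of "multichart_lowD", "multichart_fullD",
#'   "grid_realignment", "space_feature", "implicit_space",
#'   "null_space_birth", "null_space_suppress".
#' @param N Network size.
#' @param P Positional variables (0 for implicit_space).
#' @param C Cognitive variables.
#' @param m Grid modules.
#' @param frequencies Frequency exponents (defaults to 0:(m-1)).
#' @param Y Embedding dimensionality; defaults to Z except for multichart
#'   scenarios, where it must be given (fullD forces Y = N).
#' @param K Number of environments.
#' @param resolution Grid points per dimension; defaults to 100 (1-d track)
#'   or 32 (2-d).
#' @param sigma,lengthscale Cognitive generator parameters.
#' @param code Decoder code; scenario default if missing.
#' @param rescaleExponent Embedding rescale exponent (default 1, the
#'   linear rule y <- Y y).
#' @param spar Suppression fraction for null-space protocols (default 0.5).
#' @param Tsuppr Elevated threshold (default 10).
#' @param seed Master seed.
#' @return A validated [ExperimentConfig-class].
#' @export
experimentConfig <- function(scenario, N, P = 1L, C = 0L, m = 1L,
                             frequencies = NULL, Y = NULL, K = 2L,
                             resolution = NULL, sigma = 0.2,
                             lengthscale = 0.3, code = NULL,
                             rescaleExponent = 1, spar = 0.5,
                             Tsuppr = 10, seed = 1L) {
    scenario <- match.arg(scenario, .remapScenarios)
    P <- as.integer(P); C <- as.integer(C); m <- as.integer(m)
    N <- as.integer(N)
    Z <- 2L * m * P + 2L * C
    if (is.null(code))
        code <- switch(scenario,
                       multichart_lowD = "M", multichart_fullD = "identity",
                       grid_realignment = "C", space_feature = "CM",
                       implicit_space = "M",
                       null_space_birth = "M", null_space_suppress = "M")
    if (is.null(Y))
        Y <- if (scenario == "multichart_fullD") N else Z
    if (is.null(frequencies))
        frequencies <- if (m > 1L) 0:(m - 1L) else 0L
    if (is.null(resolution)) {
        trackDims <- max(P, 1L)
        resolution <- if (trackDims >= 2L) 32L else 100L
    }
    if (scenario %in% c("null_space_birth", "null_space_suppress")) K <- 1L
    cfg <- new(Class = "ExperimentConfig", scenario = scenario,
               N = N, P = P, C = C,
               m = m, frequencies = as.integer(frequencies),
               Y = as.integer(Y), K = as.integer(K),
               resolution = as.integer(resolution),
               sigma = as.numeric(sigma),
               lengthscale = as.numeric(lengthscale), code = code,
               rescaleExponent = as.numeric(rescaleExponent),
               spar = as.numeric(spar), Tsuppr = as.numeric(Tsuppr),
               seed = as.integer(seed))
    validObject(cfg)
    cfg
}

## latent row-part labels for a config (embedding space = latent space)
.configPartLabels <- function(cfg) {
    posRows <- seq_len(2L * cfg@m * cfg@P)
    cogRows <- if (cfg@C > 0L)
        2L * cfg@m * cfg@P + seq_len(2L * cfg@C) else integer()
    labs <- list()
    if (length(posRows)) labs$positional <- posRows
    if (length(cogRows)) labs$cognitive <- cogRows
    labs
}

## the physical track over which rate maps are measured (1-d when P = 0)
.configGrid <- function(cfg) {
    buildPositionGrid(max(cfg@P, 1L), cfg@resolution)
}

#' Run a remapping experiment
#'
#' Builds the decoder bank once, then for each environment constructs the
#' latent trajectory (shared positional part where the scenario requires
#' it), the embedding map (random chart, module realignment, or identity),
#' normalises and rescales the embedding input, and solves the steady-state
#' rates. Per-environment seeds are derived from the master seed so reruns
#' are bit-identical.
#'
#' @param cfg A validated [ExperimentConfig-class].
#' @return A [RemappingRun-class].
#' @export
runExperiment <- function(cfg) {
    stopifnot(is(cfg, "ExperimentConfig"))
    validObject(cfg)
    if (cfg@scenario %in% c("null_space_birth", "null_space_suppress"))
        return(.runNullSpace(cfg))

    grid <- .configGrid(cfg)
    gridSpec <- gridModuleSpec(cfg@frequencies)
    labs <- .configPartLabels(cfg)
    decoder <- sampleDecoder(cfg@N, cfg@Y, cfg@code, partLabels = labs,
                             seed = deriveSeed(cfg@seed, 0L))
    T0 <- optimalThresholds(decoder)
    cogSpec <- cognitiveSpec(cfg@C, cfg@sigma, cfg@lengthscale, cfg@seed)

    envs <- vector("list", cfg@K)
    ## positional latent shared across environments (ED and space-feature)
    sharedLatent <- if (cfg@P > 0L)
        makeLatentTrajectory(grid, gridSpec) else NULL

    for (k in seq_len(cfg@K)) {
        es <- deriveSeed(cfg@seed, k)
        if (cfg@scenario %in% c("multichart_lowD", "multichart_fullD")) {
            latent <- sharedLatent
            map <- sampleMultichartMap(cfg@Y, nrow(latent@z), seed = es)
        } else if (cfg@scenario == "grid_realignment") {
            latent <- sharedLatent
            map <- sampleRealignmentMap(gridSpec, cfg@P, seed = es)
        } else if (cfg@scenario == "space_feature") {
            cog <- makeCognitiveTrajectory(cogSpec, grid, seed = es)
            latent <- makeLatentTrajectory(grid, gridSpec, cognitive = cog)
            map <- identityMap(nrow(latent@z))
        } else if (cfg@scenario == "implicit_space") {
            cog <- makeCognitiveTrajectory(cogSpec, grid, seed = es)
            latent <- makeLatentTrajectory(grid, gridSpec, cognitive = cog,
                                           includePosition = FALSE)
            map <- identityMap(nrow(latent@z))
        }
        y <- rescaleEmbedding(applyMap(map, latent), cfg@Y,
                              cfg@rescaleExponent)
        rm <- runRateMap(y, decoder, T0, positions = grid,
                         environment = paste0("env_", k))
        envs[[k]] <- list(latent = latent, map = map, thresholds = T0,
                          y = y, rateMap = rm, seed = es)
    }
    new("RemappingRun", config = cfg, decoder = decoder,
        environments = envs)
}

#' Null-space threshold-modulation protocol
#'
#' A single environment of the low-dimensional multi-chart model is solved
#' under three threshold conditions sharing an identical embedding input y
#' and decoder. The `default` map has half of the neurons suppressed
#' (elevated thresholds). `birth` models participation of new cells: a
#' seeded fraction `spar` of the suppressed reserve is released into the
#' map. `suppressed` models suppression with replacement: a fraction `spar`
#' of the default-active set is suppressed while an equally seeded fraction
#' of the reserve is released, so an alternative population compensates and
#' the decoded latents are preserved (at `spar = 1` the map is carried by
#' an entirely non-overlapping set of neurons). All rate changes are
#' confined to the decoder's null space.
#'
#' @param cfg An [ExperimentConfig-class] with a null-space scenario.
#' @return A [RemappingRun-class] with environments named "default",
#'   "birth" and "suppressed".
#' @export
nullSpaceProtocol <- function(cfg) {
    stopifnot(is(cfg, "ExperimentConfig"))
    if (!cfg@scenario %in% c("null_space_birth", "null_space_suppress"))
        stop("nullSpaceProtocol requires a null-space scenario config")
    grid <- .configGrid(cfg)
    gridSpec <- gridModuleSpec(cfg@frequencies)
    decoder <- sampleDecoder(cfg@N, cfg@Y, cfg@code,
                             partLabels = .configPartLabels(cfg),
                             seed = deriveSeed(cfg@seed, 0L))
    T0 <- optimalThresholds(decoder)
    latent <- makeLatentTrajectory(grid, gridSpec)
    map <- sampleMultichartMap(cfg@Y, nrow(latent@z),
                               seed = deriveSeed(cfg@seed, 1L))
    y <- rescaleEmbedding(applyMap(map, latent), cfg@Y, cfg@rescaleExponent)

    Tdefault <- suppress(T0, 0.5, seed = deriveSeed(cfg@seed, 2L),
                         Tsuppr = cfg@Tsuppr)
    Tbirth <- release(Tdefault, T0, fraction = cfg@spar,
                      seed = deriveSeed(cfg@seed, 3L))
    ## replacement: silence part of the active map, recruit the reserve
    Tsupp <- release(suppress(Tdefault, cfg@spar,
                              seed = deriveSeed(cfg@seed, 4L),
                              Tsuppr = cfg@Tsuppr,
                              from = setdiff(seq_len(cfg@N),
                                             Tdefault@suppressed)),
                     T0, fraction = cfg@spar,
                     seed = deriveSeed(cfg@seed, 5L),
                     from = Tdefault@suppressed)

    mk <- function(Tv, label) {
        rm <- runRateMap(y, decoder, Tv, positions = grid,
                         environment = label)
        list(latent = latent, map = map, thresholds = Tv, y = y,
             rateMap = rm, seed = cfg@seed)
    }
    envs <- list(default = mk(Tdefault, "default"),
                 birth = mk(Tbirth, "birth"),
                 suppressed = mk(Tsupp, "suppressed"))
    new("RemappingRun", config = cfg, decoder = decoder,
        environments = envs)
}

## runExperiment dispatch for the two null-space scenarios: keep the default
## condition plus the modulated one named by the scenario
.runNullSpace <- function(cfg) {
    full <- nullSpaceProtocol(cfg)
    keep <- if (cfg@scenario == "null_space_birth")
        c("default", "birth") else c("default", "suppressed")
    new("RemappingRun", config = cfg, decoder = full@decoder,
        environments = full@environments[keep])
}
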