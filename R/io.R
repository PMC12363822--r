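## Configuration files, run archives, stats export and seeded fixtures.
## Archives are single self-describing RDS files (uncompressed, float64)
## with an md5 content hash verified on load; re-running the archived
## config with its seeds reproduces the rates bit-identically.

## md5 of an R object via its version-3 serialization
.hashObject <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    con <- file(f, "wb")
    serialize(obj, con, version = 3L, xdr = TRUE)
    close(con)
    unname(tools::md5sum(f))
}

## ExperimentConfig <-> plain list
.configToList <- function(cfg) {
    list(scenario = cfg@scenario, N = cfg@N, P = cfg@P, C = cfg@C,
         m = cfg@m, frequencies = cfg@frequencies, Y = cfg@Y, K = cfg@K,
         resolution = cfg@resolution, sigma = cfg@sigma,
         lengthscale = cfg@lengthscale, code = cfg@code,
         rescaleExponent = cfg@rescaleExponent, spar = cfg@spar,
         Tsuppr = cfg@Tsuppr, seed = cfg@seed)
}

#' Build an experiment configuration from a plain list
#'
#' Used by [loadConfig]; unknown keys are an error and every scenario
#' invariant is checked, with all failures reported together.
#'
#' @param x Named list of configuration fields (at least `scenario` and
#'   `N`).
#' @return A validated [ExperimentConfig-class].
#' @export
configFromList <- function(x) {
    known <- c("scenario", "N", "P", "C", "m", "frequencies", "Y", "K",
               "resolution", "sigma", "lengthscale", "code",
               "rescaleExponent", "spar", "Tsuppr", "seed")
    extra <- setdiff(names(x), known)
    if (length(extra))
        stop("unknown configuration keys: ", paste(extra, collapse = ", "))
    if (is.null(x$scenario) || is.null(x$N))
        stop("configuration must name a scenario and a network size N")
    do.call(experimentConfig, x)
}

#' Load and validate a configuration file
#'
#' Accepts YAML or JSON (chosen by extension, falling back to YAML, which
#' parses JSON as well); defaults are filled by [experimentConfig] and the
#' resolved configuration returned.
#'
#' @param path File path.
#' @return A validated [ExperimentConfig-class].
#' @export
loadConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
        yaml::read_yaml(path)
    }
    configFromList(x)
}

#' Save a configuration file
#'
#' @param cfg An [ExperimentConfig-class].
#' @param path Destination (.yaml or .json by extension).
#' @return Invisibly, `path`.
#' @export
saveConfig <- function(cfg, path) {
    stopifnot(is(cfg, "ExperimentConfig"))
    x <- .configToList(cfg)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    } else {
        yaml::write_yaml(x, path)
    }
    invisible(path)
}

## RemappingRun -> archive list (everything needed to reproduce/analyse)
.runToArchive <- function(run) {
    cfgList <- .configToList(run@config)
    envs <- lapply(run@environments, function(e) {
        rm <- e$rateMap
        list(R = e$map@R, mapScenario = e$map@scenario,
             thresholds = e$thresholds@values,
             suppressed = e$thresholds@suppressed,
             Tsuppr = e$thresholds@Tsuppr,
             z = e$latent@z, P = e$latent@P, C = e$latent@C,
             m = e$latent@m, y = e$y,
             rates = rates(rm), nullPart = nullPart(rm),
             decoded = decodedEmbedding(rm),
             environment = rm@environment,
             diagnostics = as.data.frame(
                 colData(rm)[, c("objective", "kkt", "sweeps")]),
             seed = e$seed)
    })
    body <- list(package = "remapsim",
                 version = as.character(utils::packageVersion("remapsim")),
                 config = cfgList, configHash = .hashObject(cfgList),
                 D = run@decoder@D, E = run@decoder@E,
                 code = run@decoder@code,
                 decoderSeed = run@decoder@seed,
                 environments = envs)
    body$hash <- .hashObject(body)
    body
}

#' Save a remapping run to an archive file
#'
#' Lossless float64 persistence of the full run (config snapshot with hash,
#' decoder, per-environment maps, thresholds, embedding inputs, rates, null
#' parts and solver diagnostics) as a single uncompressed RDS file whose
#' content hash is verified on load.
#'
#' @param run A [RemappingRun-class].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
saveRun <- function(run, path) {
    stopifnot(is(run, "RemappingRun"))
    saveRDS(.runToArchive(run), path, compress = FALSE)
    invisible(path)
}

#' Load and verify a run archive
#'
#' @param path Archive file written by [saveRun].
#' @return The archive list (class "remapArchive"), with the stored hash
#'   checked against the recomputed content hash.
#' @export
loadRun <- function(path) {
    if (!file.exists(path)) stop("no such archive: ", path)
    x <- readRDS(path)
    h <- x$hash
    body <- x[setdiff(names(x), "hash")]
    if (!identical(.hashObject(body), h))
        stop("archive is corrupted: content hash mismatch")
    class(x) <- "remapArchive"
    x
}

#' Extract the per-environment rate matrices from an archive
#'
#' @param archive A list returned by [loadRun] (or a
#'   [RemappingRun-class]).
#' @return Named list of nonnegative matrices (neurons x positions).
#' @export
archiveRates <- function(archive) {
    if (is(archive, "RemappingRun"))
        return(lapply(rateMaps(archive), rates))
    lapply(archive$environments, `[[`, "rates")
}

#' Write per-environment rate maps as CSV tables
#'
#' One file per environment (rows = neurons, columns = positions), a plain
#' interchange format for the analysis layer.
#'
#' @param x A [RemappingRun-class], archive list, or list of matrices.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the paths written.
#' @export
writeRateMapCsv <- function(x, dir, prefix = "ratemap") {
    maps <- if (is.list(x) && !is.null(x$environments)) archiveRates(x)
            else if (is(x, "RemappingRun")) archiveRates(x)
            else x
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(length(maps))
    for (k in seq_along(maps)) {
        paths[k] <- file.path(dir, sprintf("%s_env%02d.csv", prefix, k))
        utils::write.csv(as.data.frame(maps[[k]]), paths[k],
                         row.names = FALSE)
    }
    paths
}

#' Read rate-map CSV tables
#'
#' @param paths Character vector of CSV files (rows = neurons, columns =
#'   positions), one per environment.
#' @return List of numeric matrices.
#' @export
readRateMapCsv <- function(paths) {
    lapply(paths, function(p) {
        m <- as.matrix(utils::read.csv(p, check.names = FALSE))
        dimnames(m) <- NULL
        if (min(m) < 0) stop("rate maps must be nonnegative: ", p)
        m
    })
}

#' Write the per-pair statistics table and summary
#'
#' Emits a tidy CSV of per-pair overlap / spatial-correlation values and a
#' JSON summary (grand means, effects, tests, seeds).
#'
#' @param stats A [RemappingStats-class].
#' @param dir Output directory.
#' @return Invisibly, the two paths written (csv, json).
#' @export
writeStats <- function(stats, dir) {
    stopifnot(is(stats, "RemappingStats"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, "pairs.csv")
    utils::write.csv(statsTable(stats), csv, row.names = FALSE)
    js <- file.path(dir, "summary.json")
    jsonlite::write_json(statsSummary(stats), js, auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(c(csv = csv, json = js))
}

#' Seeded toy fixture runs
#'
#' Small, fast, fully reproducible runs at the toy scales used throughout
#' the documentation and tests: a 24-neuron multi-chart pair, a 24-neuron
#' two-module grid-realignment pair, a 32-neuron space-feature triple, and
#' the 48-neuron null-space threshold protocol.
#'
#' @param name One of "multichart_toy", "grid_toy", "space_feature_toy",
#'   "null_space_toy".
#' @param seed Master seed (default 1).
#' @param resolution Grid points (default 100).
#' @return A [RemappingRun-class].
#' @export
fixtureRun <- function(name = c("multichart_toy", "grid_toy",
                                "space_feature_toy", "null_space_toy"),
                       seed = 1L, resolution = 100L) {
    name <- match.arg(name)
    cfg <- switch(name,
        multichart_toy = experimentConfig("multichart_lowD", N = 24L,
            P = 1L, Y = 3L, K = 2L, resolution = resolution, seed = seed),
        grid_toy = experimentConfig("grid_realignment", N = 24L, P = 1L,
            m = 2L, frequencies = c(0L, 1L), K = 2L,
            resolution = resolution, seed = seed),
        space_feature_toy = experimentConfig("space_feature", N = 32L,
            P = 1L, C = 1L, K = 3L, resolution = resolution, seed = seed),
        null_space_toy = experimentConfig("null_space_suppress", N = 48L,
            P = 1L, Y = 8L, resolution = resolution, seed = seed))
    runExperiment(cfg)
}
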