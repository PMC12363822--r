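## Generics, accessors and show methods.

#' @rdname RateMap-class
#' @param object,x An object.
#' @param ... Further arguments.
#' @export
setGeneric("rates", function(x, ...) standardGeneric("rates"))

#' @rdname RateMap-class
#' @export
setGeneric("nullPart", function(x, ...) standardGeneric("nullPart"))

#' @rdname RateMap-class
#' @export
setGeneric("decodedEmbedding",
           function(x, ...) standardGeneric("decodedEmbedding"))

#' @rdname DecoderBank-class
#' @export
setGeneric("decoderMatrix", function(x, ...) standardGeneric("decoderMatrix"))

#' @rdname DecoderBank-class
#' @export
setGeneric("encoderMatrix", function(x, ...) standardGeneric("encoderMatrix"))

#' @rdname ThresholdVector-class
#' @export
setGeneric("thresholds", function(x, ...) standardGeneric("thresholds"))

#' @rdname ThresholdVector-class
#' @export
setGeneric("suppressedNeurons",
           function(x, ...) standardGeneric("suppressedNeurons"))

#' @rdname PositionGrid-class
#' @export
setGeneric("positionPoints",
           function(x, ...) standardGeneric("positionPoints"))

#' @rdname LatentTrajectory-class
#' @export
setGeneric("latentMatrix", function(x, ...) standardGeneric("latentMatrix"))

#' @rdname EmbeddingMap-class
#' @export
setGeneric("mapMatrix", function(x, ...) standardGeneric("mapMatrix"))

#' @rdname RemappingRun-class
#' @export
setGeneric("rateMaps", function(x, ...) standardGeneric("rateMaps"))

#' @rdname RemappingRun-class
#' @export
setGeneric("runConfig", function(x, ...) standardGeneric("runConfig"))

#' @rdname RemappingRun-class
#' @export
setGeneric("decoderBank", function(x, ...) standardGeneric("decoderBank"))

## ----- accessors ----------------------------------------------------------

#' @rdname RateMap-class
#' @export
setMethod("rates", "RateMap", function(x, ...) assay(x, "rates"))

#' @rdname RateMap-class
#' @export
setMethod("nullPart", "RateMap", function(x, ...) assay(x, "nullPart"))

#' @rdname RateMap-class
#' @export
setMethod("decodedEmbedding", "RateMap", function(x, ...) x@decoded)

#' @rdname DecoderBank-class
#' @export
setMethod("decoderMatrix", "DecoderBank", function(x, ...) x@D)

#' @rdname DecoderBank-class
#' @export
setMethod("encoderMatrix", "DecoderBank", function(x, ...) x@E)

#' @rdname ThresholdVector-class
#' @export
setMethod("thresholds", "ThresholdVector", function(x, ...) x@values)

#' @rdname ThresholdVector-class
#' @export
setMethod("suppressedNeurons", "ThresholdVector",
          function(x, ...) x@suppressed)

#' @rdname PositionGrid-class
#' @export
setMethod("positionPoints", "PositionGrid", function(x, ...) x@points)

#' @rdname LatentTrajectory-class
#' @export
setMethod("latentMatrix", "LatentTrajectory", function(x, ...) x@z)

#' @rdname EmbeddingMap-class
#' @export
setMethod("mapMatrix", "EmbeddingMap", function(x, ...) x@R)

#' @rdname RemappingRun-class
#' @export
setMethod("rateMaps", "RemappingRun",
          function(x, ...) lapply(x@environments, `[[`, "rateMap"))

#' @rdname RemappingRun-class
#' @export
setMethod("runConfig", "RemappingRun", function(x, ...) x@config)

#' @rdname RemappingRun-class
#' @export
setMethod("decoderBank", "RemappingRun", function(x, ...) x@decoder)

## ----- show methods -------------------------------------------------------

setMethod("show", "PositionGrid", function(object) {
    cat("PositionGrid:", nrow(object@points), "points,",
        object@dims, "dimension(s), resolution", object@resolution,
        sprintf("(spacing %.4g)\n", object@spacing))
})

setMethod("show", "GridModuleSpec", function(object) {
    cat("GridModuleSpec:", object@m, "module(s), frequency exponents:",
        paste(object@frequencies, collapse = ", "), "\n")
})

setMethod("show", "LatentTrajectory", function(object) {
    cat("LatentTrajectory: Z =", nrow(object@z), "over",
        ncol(object@z), "positions (P =", object@P,
        ", C =", object@C, ", m =", object@m, ")\n")
})

setMethod("show", "EmbeddingMap", function(object) {
    cat("EmbeddingMap (", object@scenario, "): ",
        nrow(object@R), " x ", ncol(object@R), "\n", sep = "")
})

setMethod("show", "DecoderBank", function(object) {
    cat("DecoderBank: D is", nrow(object@D), "x", ncol(object@D),
        "| code", object@code, "\n")
})

setMethod("show", "ThresholdVector", function(object) {
    cat("ThresholdVector:", length(object@values), "neurons,",
        length(object@suppressed), "suppressed (Tsuppr =",
        object@Tsuppr, ")\n")
})

setMethod("show", "RateMap", function(object) {
    cat("RateMap '", object@environment, "': ", nrow(object), " neurons x ",
        ncol(object), " positions; ",
        sum(rowSums(rates(object)) > 0), " active neurons; ",
        sprintf("max KKT residual %.2e\n",
                max(colData(object)$kkt)), sep = "")
})

setMethod("show", "ExperimentConfig", function(object) {
    cat("ExperimentConfig:", object@scenario,
        sprintf("| N=%d P=%d C=%d m=%d Y=%d K=%d res=%d code=%s seed=%d\n",
                object@N, object@P, object@C, object@m, object@Y, object@K,
                object@resolution, object@code, object@seed))
})

setMethod("show", "RemappingRun", function(object) {
    show(object@config)
    cat(" ", length(object@environments), "environment(s) solved\n")
})

setMethod("show", "RemappingStats", function(object) {
    fmt <- function(nm, s) {
        cat(sprintf("  %s: mean %.3f vs shuffle %.3f (effect %.2f, p %.3g%s)\n",
                    nm, s$mean, s$shuffleMean, s$effect, s$p,
                    if (isTRUE(s$significant)) ", significant" else ""))
    }
    cat("RemappingStats over", nrow(object@pairs), "environment pair(s),",
        object@nShuffles, "shuffles\n")
    fmt("overlap     ", object@overlap)
    fmt("spatial corr", object@spatialCorr)
})
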