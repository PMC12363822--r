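## Diagnostic visual maps: winner-take-all tuning-preference fields over a
## 2-d mesh in angle/variable space, and the gnomonic sphere projection.
## The computations are tested; rendering itself is minimal base graphics.

#' PreferenceField: winner-take-all tuning map over a 2-d mesh
#'
#' @slot grid Numeric matrix (n x 2) of mesh coordinates in [-1, 1]^2.
#' @slot winner Integer vector, index of the most active neuron per mesh
#'   point (-1 where all rates are zero).
#' @slot resolution Integer mesh resolution per axis.
#' @slot mode "solved" or "feedforward".
#' @export
setClass("PreferenceField",
    representation(grid = "matrix", winner = "integer",
                   resolution = "integer", mode = "character"))

setMethod("show", "PreferenceField", function(object) {
    cat("PreferenceField (", object@mode, "): ", object@resolution, " x ",
        object@resolution, " mesh, ",
        length(unique(object@winner[object@winner > 0L])),
        " winning neuron(s)\n", sep = "")
})

## default mesh encoder: both mesh coordinates angular-encoded and the two
## pairs part-normalised, i.e. the 4-d torus
.torusEncode <- function(pts) {
    z <- rbind(encodeAngular(pts[, 1L]), encodeAngular(pts[, 2L]))
    normalizeLatent(z, list(a = 1:2, b = 3:4))
}

#' Winner-take-all preference field
#'
#' Colours a mesh over \eqn{[-1, 1]^2} by the most active neuron. In
#' `feedforward` mode rates are approximated by \eqn{D^\top y}; in `solved`
#' mode the steady-state QP is solved per mesh point (requires
#' `thresholds`). Suppressed neurons' rates are zeroed before the argmax.
#' Ties break to the lowest neuron index; mesh points where every rate is
#' exactly zero get the sentinel -1.
#'
#' @param D A [DecoderBank-class] or decoder matrix.
#' @param resolution Mesh points per axis (default 200).
#' @param mode "feedforward" (default) or "solved".
#' @param thresholds [ThresholdVector-class] or numeric vector (solved
#'   mode).
#' @param suppressed Integer indices of suppressed neurons.
#' @param encode Function mapping the (n x 2) mesh matrix to embedding
#'   inputs (Y x n); default angular-encodes both coordinates on the torus.
#' @param rescaleExponent Embedding rescale exponent applied to the encoded
#'   mesh (default 1).
#' @return A [PreferenceField-class].
#' @export
argmaxField <- function(D, resolution = 200L,
                        mode = c("feedforward", "solved"),
                        thresholds = NULL, suppressed = integer(),
                        encode = .torusEncode, rescaleExponent = 1) {
    mode <- match.arg(mode)
    Dm <- if (is(D, "DecoderBank")) D@D else D
    resolution <- as.integer(resolution)
    axis <- seq(-1, 1, length.out = resolution)
    pts <- as.matrix(expand.grid(x = axis, y = axis))
    dimnames(pts) <- NULL
    y <- rescaleEmbedding(encode(pts), nrow(Dm), rescaleExponent)
    r <- if (mode == "feedforward") {
        feedforwardRates(y, Dm)
    } else {
        if (is.null(thresholds))
            stop("solved mode requires thresholds")
        Tv <- if (is(thresholds, "ThresholdVector"))
            thresholds@values else thresholds
        .nnqpSolve(Dm, y, Tv)$rates
    }
    if (length(suppressed)) r[suppressed, ] <- 0
    winner <- apply(r, 2L, function(col) {
        if (all(col == 0)) -1L else which.max(col)   # lowest-index tie-break
    })
    new("PreferenceField", grid = pts, winner = as.integer(winner),
        resolution = resolution, mode = mode)
}

#' Gnomonic projection onto the unit sphere
#'
#' Maps a plane point (x, y) to
#' \eqn{(2x, 2y, x^2 + y^2 - 1) / (x^2 + y^2 + 1)}, a unit vector; used to
#' visualise multi-chart embeddings on the sphere.
#'
#' @param x,y Numeric vectors.
#' @return Numeric matrix (3 x length(x)) of unit vectors.
#' @export
gnomonicProject <- function(x, y) {
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("inputs must be finite")
    s <- x^2 + y^2
    rbind(2 * x, 2 * y, s - 1) / rep(s + 1, each = 3L)
}

#' Plot a preference field
#'
#' Minimal image rendering of the winner map; colours are arbitrary but
#' consistent within the field.
#'
#' @param field A [PreferenceField-class].
#' @param ... Passed to [graphics::image].
#' @return Invisibly, the winner matrix.
#' @export
plotPreferenceField <- function(field, ...) {
    stopifnot(is(field, "PreferenceField"))
    w <- matrix(field@winner, field@resolution, field@resolution)
    ids <- sort(unique(as.vector(w)))
    pal <- c("grey90", grDevices::hcl.colors(max(length(ids) - 1L, 1L),
                                             "Spectral"))
    graphics::image(z = matrix(match(w, ids), nrow(w), ncol(w)),
                    col = pal[seq_along(ids)], axes = FALSE, asp = 1, ...)
    invisible(w)
}
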