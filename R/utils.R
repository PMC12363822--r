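## Internal helpers: seeded evaluation and seed derivation.

#' @useDynLib remapsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that library functions never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Derive a stream seed from a master seed and an index
#'
#' Deterministic counter scheme: each environment (or shuffle stream) gets an
#' independent, reproducible seed strictly below 2^31.
#'
#' @param master Integer master seed.
#' @param index Nonnegative integer stream index.
#' @return Integer seed in [1, 2^31 - 1].
#' @export
deriveSeed <- function(master, index) {
    stopifnot(is.numeric(master), length(master) == 1L,
              is.numeric(index), length(index) == 1L, index >= 0)
    m <- 2147483647          # 2^31 - 1 (prime)
    s <- (abs(as.numeric(master)) %% m)
    ## two rounds of a multiplicative congruential step keyed by the index
    s <- (s * 48271 + (index + 1) * 16807) %% m
    s <- (s * 69621 + 12345) %% m
    as.integer(s + 1)
}

## column-wise euclidean norms
colNorms <- function(x) sqrt(colSums(x^2))

## cosine similarity of two vectors; error on zero norm unless `flag` given
cosineSim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
        stop("cosine similarity undefined for a zero vector")
    sum(a * b) / (na * nb)
}
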