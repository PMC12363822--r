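## Remapping quantification: rate-map preprocessing, overlap and spatial
## correlation with shuffle controls, and significance testing.

#' Threshold small rates to zero
#'
#' Entries strictly below `threshold` (default 1e-3) are set to exact zero;
#' all analysis measures operate on preprocessed maps. Idempotent.
#'
#' @param rates Nonnegative numeric matrix (neurons x positions).
#' @param threshold Numeric cutoff.
#' @return Matrix of the same shape.
#' @export
preprocessRates <- function(rates, threshold = 1e-3) {
    if (min(rates) < 0) stop("rates must be nonnegative")
    rates[rates < threshold] <- 0
    rates
}

#' Overlap between two environments
#'
#' Cosine similarity between the environments' mean population rate vectors
#' (rates averaged over positions).
#'
#' @param ratesA,ratesB Nonnegative matrices (same N, any position count).
#' @return Numeric scalar in [0, 1] for nonnegative rates.
#' @export
overlapPair <- function(ratesA, ratesB) {
    if (nrow(ratesA) != nrow(ratesB))
        stop("rate maps must have the same number of neurons")
    cosineSim(rowMeans(ratesA), rowMeans(ratesB))
}

## all permutations of 1..n (n small), one per row
.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (k in seq_len(n)) {
        rows <- r + seq_len(nrow(sub))
        out[rows, 1L] <- k
        out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
        r <- r + nrow(sub)
    }
    out
}

## one shuffle realization stream: permutations of both mean vectors
.overlapShuffleValues <- function(mA, mB, nRealizations, seed) {
    N <- length(mA)
    withSeed(seed, vapply(seq_len(nRealizations), function(i) {
        cosineSim(mA[sample.int(N)], mB[sample.int(N)])
    }, numeric(1)))
}

#' Shuffled overlap control
#'
#' Mean over realizations of the cosine similarity between the two mean
#' rate vectors after independently permuting neuron identities in both.
#' Since only the relative permutation matters, when `nRealizations` is at
#' least N! the estimator switches to the exact enumeration over all N!
#' relative permutations.
#'
#' @param ratesA,ratesB Nonnegative matrices (same N).
#' @param nRealizations Number of shuffle realizations (default 20).
#' @param seed Integer seed.
#' @return Numeric scalar, with the individual realization values attached
#'   as attribute `"values"`.
#' @export
overlapShuffle <- function(ratesA, ratesB, nRealizations = 20L, seed = 1L) {
    if (nrow(ratesA) != nrow(ratesB))
        stop("rate maps must have the same number of neurons")
    mA <- rowMeans(ratesA); mB <- rowMeans(ratesB)
    N <- length(mA)
    v <- if (N <= 8L && nRealizations >= factorial(N)) {
        perms <- .allPerms(N)
        vapply(seq_len(nrow(perms)), function(k)
            cosineSim(mA, mB[perms[k, ]]), numeric(1))
    } else {
        .overlapShuffleValues(mA, mB, nRealizations, seed)
    }
    structure(mean(v), values = v)
}

#' Spatial correlation between two environments
#'
#' Mean over neurons active in both environments (nonzero mean rate after
#' preprocessing) of the cosine similarity between the neuron's rate
#' profiles across positions. Returns NA with `nActive` when no neuron is
#' co-active.
#'
#' @param ratesA,ratesB Nonnegative matrices (same N and positions).
#' @return List with `rho` (NA if no co-active neurons) and `nActive`.
#' @export
spatialCorrPair <- function(ratesA, ratesB) {
    if (!identical(dim(ratesA), dim(ratesB)))
        stop("rate maps must have identical dimensions")
    act <- which(rowMeans(ratesA) > 0 & rowMeans(ratesB) > 0)
    if (!length(act)) return(list(rho = NA_real_, nActive = 0L))
    vals <- vapply(act, function(i)
        cosineSim(ratesA[i, ], ratesB[i, ]), numeric(1))
    list(rho = mean(vals), nActive = length(act))
}

## all ordered co-active pairs (i != j) as a 2-column matrix
.coactivePairs <- function(act) {
    g <- expand.grid(i = act, j = act)
    as.matrix(g[g$i != g$j, , drop = FALSE])
}

#' Shuffled spatial-correlation control
#'
#' Mean cosine similarity between mismatched neuron pairs: neuron i's
#' profile in A against neuron j's in B (i != j), both co-active. Per
#' realization, `nPairs` distinct ordered pairs are drawn without
#' replacement; when `nPairs` covers all ordered pairs the estimator reduces
#' to the exact enumeration mean.
#'
#' @param ratesA,ratesB Nonnegative matrices (same shape).
#' @param nPairs Ordered pairs per realization (default 200, capped at the
#'   number available).
#' @param nRealizations Realizations (default 20).
#' @param seed Integer seed.
#' @return List with `rho` (NA if fewer than 2 co-active neurons),
#'   `values` per realization, and `nActive`.
#' @export
spatialCorrShuffle <- function(ratesA, ratesB, nPairs = 200L,
                               nRealizations = 20L, seed = 1L) {
    if (!identical(dim(ratesA), dim(ratesB)))
        stop("rate maps must have identical dimensions")
    act <- which(rowMeans(ratesA) > 0 & rowMeans(ratesB) > 0)
    if (length(act) < 2L)
        return(list(rho = NA_real_, values = numeric(), nActive = length(act)))
    pairs <- .coactivePairs(act)
    nAll <- nrow(pairs)
    exhaustive <- nPairs >= nAll
    pairCos <- function(idx) {
        mean(vapply(idx, function(r)
            cosineSim(ratesA[pairs[r, 1L], ], ratesB[pairs[r, 2L], ]),
            numeric(1)))
    }
    vals <- if (exhaustive) {
        rep(pairCos(seq_len(nAll)), nRealizations)
    } else {
        withSeed(seed, vapply(seq_len(nRealizations), function(k)
            pairCos(sample.int(nAll, nPairs)), numeric(1)))
    }
    list(rho = mean(vals), values = vals, nActive = length(act))
}

#' One-sample test of pairwise values against the shuffle grand mean
#'
#' One-sample t-test of the per-pair statistic distribution against the
#' shuffle grand mean treated as a known constant, with a Bonferroni-style
#' threshold 0.05 / nTests. Zero-variance inputs are flagged degenerate and
#' reported as an exact (in)equality instead of a t statistic.
#'
#' @param values Numeric vector of per-pair statistics (length >= 2).
#' @param shuffleMean Scalar shuffle grand mean.
#' @param nTests Bonferroni divisor (default 1).
#' @return List with `mean`, `t`, `p`, `significant`, `degenerate`.
#' @export
summarizeAndTest <- function(values, shuffleMean, nTests = 1L) {
    values <- values[is.finite(values)]
    if (length(values) < 2L)
        stop("need at least two pairwise values to test")
    if (stats::sd(values) == 0) {
        return(list(mean = mean(values), t = NA_real_, p = NA_real_,
                    significant = !isTRUE(all.equal(mean(values),
                                                    shuffleMean)),
                    degenerate = TRUE))
    }
    tt <- stats::t.test(values, mu = shuffleMean)
    list(mean = mean(values), t = unname(tt$statistic),
         p = tt$p.value, significant = tt$p.value < 0.05 / nTests,
         degenerate = FALSE)
}

#' Overlap and spatial-correlation statistics for a remapping run
#'
#' Preprocesses every rate map, computes all unordered pairwise overlap and
#' spatial-correlation values plus their shuffle controls, grand means,
#' standardized effect sizes (|grand mean - shuffle grand mean| / s.d. of
#' the pooled shuffle values), and one-sample t-tests against the shuffle
#' grand mean.
#'
#' @param x A [RemappingRun-class] or a list of nonnegative rate matrices
#'   (neurons x positions), one per environment.
#' @param nShuffles Shuffle realizations per pair (default 20).
#' @param nPairs Ordered neuron pairs per spatial-correlation realization.
#' @param seed Integer seed for the shuffle streams.
#' @param nTests Bonferroni divisor (default 1).
#' @param threshold Preprocessing cutoff (default 1e-3).
#' @return A [RemappingStats-class].
#' @export
remappingStats <- function(x, nShuffles = 20L, nPairs = 200L, seed = 1L,
                           nTests = 1L, threshold = 1e-3) {
    maps <- if (is(x, "RemappingRun"))
        lapply(rateMaps(x), rates) else x
    if (length(maps) < 2L)
        stop("need at least two environments")
    maps <- lapply(maps, preprocessRates, threshold = threshold)
    K <- length(maps)
    ij <- utils::combn(K, 2L)
    np <- ncol(ij)
    ov <- ovs <- sc <- scs <- numeric(np)
    nact <- integer(np)
    ovAll <- scAll <- list()
    for (q in seq_len(np)) {
        i <- ij[1L, q]; j <- ij[2L, q]
        A <- maps[[i]]; B <- maps[[j]]
        ov[q] <- overlapPair(A, B)
        o <- overlapShuffle(A, B, nShuffles, seed = deriveSeed(seed, q))
        ovs[q] <- as.numeric(o)
        ovAll[[q]] <- attr(o, "values")
        sp <- spatialCorrPair(A, B)
        sc[q] <- sp$rho
        nact[q] <- sp$nActive
        ss <- spatialCorrShuffle(A, B, nPairs, nShuffles,
                                 seed = deriveSeed(seed, np + q))
        scs[q] <- ss$rho
        scAll[[q]] <- ss$values
    }
    pairs <- data.frame(i = ij[1L, ], j = ij[2L, ], overlap = ov,
                        overlapShuffle = ovs, spatialCorr = sc,
                        spatialCorrShuffle = scs, nActive = nact)
    summar <- function(vals, shuffPooled) {
        keep <- is.finite(vals)
        gm <- mean(vals[keep])
        sm <- mean(shuffPooled)
        ssd <- stats::sd(shuffPooled)
        eff <- if (!is.finite(ssd) || ssd == 0) {
            if (isTRUE(all.equal(gm, sm))) 0 else Inf
        } else abs(gm - sm) / ssd
        test <- if (sum(keep) >= 2L) {
            summarizeAndTest(vals[keep], sm, nTests)
        } else {    # a single pair: no distribution to test
            list(mean = gm, t = NA_real_, p = NA_real_,
                 significant = NA, degenerate = TRUE)
        }
        c(list(shuffleMean = sm, shuffleSD = ssd, effect = eff), test)
    }
    new("RemappingStats", pairs = pairs,
        overlap = summar(ov, unlist(ovAll)),
        spatialCorr = summar(sc, unlist(scAll)),
        nShuffles = as.integer(nShuffles), nTests = as.integer(nTests),
        seed = as.integer(seed))
}

#' Tidy per-pair statistics table
#'
#' @param stats A [RemappingStats-class].
#' @return The per-pair data.frame.
#' @export
statsTable <- function(stats) {
    stopifnot(is(stats, "RemappingStats"))
    stats@pairs
}

#' Summary list of a RemappingStats object
#'
#' @param stats A [RemappingStats-class].
#' @return Named list with overlap and spatial-correlation summaries.
#' @export
statsSummary <- function(stats) {
    stopifnot(is(stats, "RemappingStats"))
    list(overlap = stats@overlap, spatialCorr = stats@spatialCorr,
         nShuffles = stats@nShuffles, nTests = stats@nTests,
         seed = stats@seed)
}
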