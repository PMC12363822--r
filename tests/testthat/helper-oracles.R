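# Independent oracles used to cross-check the package's solvers and shuffle
# estimators. These re-derive results by brute force (support enumeration,
# permutation enumeration) and never call the code paths they validate.

# Exhaustive active-set oracle for min ||y - D r||^2 + 2 T' r, r >= 0:
# enumerate every support pattern, solve the equality-constrained normal
# equations on the support, keep the feasible minimum. Exact for generic
# instances (optimal supports of size <= Y have nonsingular subproblems).
qpOracle <- function(D, y, T) {
    N <- ncol(D)
    obj <- function(r) sum((y - D %*% r)^2) + 2 * sum(T * r)
    best <- list(objective = obj(rep(0, N)), rates = rep(0, N))
    for (mask in seq_len(2^N - 1L)) {
        S <- which(bitwAnd(mask, 2^(seq_len(N) - 1L)) > 0L)
        DS <- D[, S, drop = FALSE]
        H <- crossprod(DS)
        rhs <- crossprod(DS, y) - T[S]
        rS <- tryCatch(solve(H, rhs), error = function(e) NULL)
        if (is.null(rS)) next
        if (any(rS < 0)) next
        r <- rep(0, N); r[S] <- rS
        o <- obj(r)
        if (o < best$objective - 1e-14) best <- list(objective = o, rates = r)
    }
    best
}

# KKT residual of a candidate solution, same scale as the package contract
kktResidual <- function(D, y, T, r) {
    g <- crossprod(D, D %*% r - y) + T
    max(ifelse(r > 0, abs(g), pmax(0, -g)))
}

# Exact shuffled-overlap mean: average cosine over all N! relative
# permutations of the second mean-rate vector.
overlapShuffleOracle <- function(ratesA, ratesB) {
    mA <- rowMeans(ratesA); mB <- rowMeans(ratesB)
    cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    perms <- function(v) {
        if (length(v) == 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
        out
    }
    mean(vapply(perms(seq_along(mB)), function(p) cosv(mA, mB[p]),
                numeric(1)))
}

# Exact shuffled spatial correlation: mean over all ordered co-active pairs
spatialCorrShuffleOracle <- function(ratesA, ratesB) {
    act <- which(rowMeans(ratesA) > 0 & rowMeans(ratesB) > 0)
    cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    vals <- c()
    for (i in act) for (j in act) if (i != j)
        vals <- c(vals, cosv(ratesA[i, ], ratesB[j, ]))
    mean(vals)
}

# small random QP instance generator
randomQpInstance <- function(N, Y, seed) {
    set.seed(seed)
    D <- matrix(rnorm(Y * N), Y, N)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    list(D = D, y = rnorm(Y, sd = 2), T = runif(N, 0.1, 1))
}
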