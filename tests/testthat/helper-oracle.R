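# Independent brute-force oracles: direct loop-by-loop transcriptions of the
# defining formulas, deliberately kept separate from the vectorized package
# implementation so the two can disagree if either is wrong.

oracleEuclidean <- function(X) {
    n <- nrow(X)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    D
}

oracleUCenter <- function(A) {
    n <- nrow(A)
    rs <- sapply(seq_len(n), function(i) sum(A[i, ]))
    cs <- sapply(seq_len(n), function(j) sum(A[, j]))
    gg <- sum(A)
    U <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        U[i, j] <- A[i, j] - (rs[i] + cs[j]) / (n - 2) + gg / ((n - 1) * (n - 2))
    diag(U) <- 0
    U
}

oracleInnerProduct <- function(U, V) {
    n <- nrow(U)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        if (i != j) s <- s + U[i, j] * V[i, j]
    s / (n * (n - 3))
}

oracleDCor <- function(X, Y) {
    U <- oracleUCenter(oracleEuclidean(X))
    V <- oracleUCenter(oracleEuclidean(Y))
    oracleInnerProduct(U, V) /
        sqrt(oracleInnerProduct(U, U) * oracleInnerProduct(V, V))
}

# Exhaustive enumeration of the censored event-time distance: loops over
# every pair and every unique event time.
oracleSurvivalDistance <- function(time, status) {
    u <- sort(unique(time[status == 1]))
    n <- length(time)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        s <- 0
        for (ul in u) {
            s <- s + (time[j] > ul && ul >= time[i]) * (status[i] == 1) +
                     (time[i] > ul && ul >= time[j]) * (status[j] == 1)
        }
        D[i, j] <- s
    }
    diag(D) <- 0
    D
}

oracleCommensurate <- function(X) {
    out <- X
    for (g in seq_len(ncol(X))) {
        s <- 0
        n <- nrow(X)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            s <- s + abs(X[i, g] - X[j, g])
        out[, g] <- (X[, g] - mean(X[, g])) / s
    }
    out
}

randomDistanceMatrix <- function(n) {
    A <- matrix(runif(n * n), n, n)
    A <- A + t(A)
    diag(A) <- 0
    A
}
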