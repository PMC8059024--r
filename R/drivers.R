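#' Backward elimination of gene-set genes
#'
#' Identifies the subset of a significant gene set's genes that empirically
#' drive the association. At each round the t-test p-value is computed for
#' the current subset with each gene excluded in turn; the gene whose
#' exclusion yields the smallest p-value is removed, and the procedure
#' repeats until one gene remains. The candidate pool is every subset
#' visited plus the intact full set, so the reported best subset can never
#' have a worse p-value than the unselected test. Ties in the leave-one-out
#' minimum remove the gene with the lowest column index; ties in the best
#' p-value across subset sizes prefer the smaller subset.
#'
#' The best-subset p-value is selection-biased — a subset-selection
#' criterion, not a Type I error rate, because the hypothesis was chosen by
#' looking at the data. [eliminateWithPermutation()] wraps the whole
#' procedure in a permutation test when a selection-adjusted significance
#' level is required.
#'
#' Distances are maintained incrementally: the per-gene squared-difference
#' matrices are precomputed once and leave-one-out squared distances are
#' obtained by summing the surviving columns, avoiding re-reading the raw
#' data. The accumulation order matches [euclideanDistanceMatrix()] exactly,
#' so incremental and from-scratch evaluation agree bit for bit.
#'
#' @param X expression matrix, subjects x genes.
#' @param geneSet [GeneSet-class] or character vector; at least 2 genes must
#'   match `colnames(X)`.
#' @param endpoint an [Endpoint-class].
#' @param transform per-gene transform applied once to the matched
#'   submatrix before elimination starts.
#' @return an [EliminationTrace-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
#' y <- quantitativeEndpoint(X[, 1] - X[, 2] + rnorm(50, sd = 0.5))
#' backwardEliminate(X, paste0("g", 1:6), y)
#' @export
backwardEliminate <- function(X, geneSet, endpoint,
                              transform = c("none", "zscore", "commensurate")) {
    transform <- match.arg(transform)
    sub <- matchGeneSet(X, geneSet)
    if (ncol(sub) < 2) stop("backward elimination requires at least 2 matched genes")
    sub <- applyTransform(sub, transform)
    n <- nrow(sub)
    if (endpointLength(endpoint) != n)
        stop("endpoint length does not match subject count")
    Yc <- uCenter(endpointDistance(endpoint))
    eliminationCore(sub, Yc, n)
}

# Core round structure, shared with the permutation wrapper (which reuses
# the precomputed per-gene squared-difference matrices across replicates).
eliminationCore <- function(sub, Yc, n, sq = NULL) {
    m <- ncol(sub)
    genes <- colnames(sub)
    if (is.null(genes)) genes <- paste0("gene", seq_len(m))
    if (is.null(sq)) sq <- perGeneSquaredDiffs(sub)
    pOf <- function(cols) {
        # accumulate in the same order and precision as
        # euclideanDistanceMatrix so results agree bit for bit
        d2 <- 0
        for (g in cols) d2 <- d2 + sq[, g]
        D <- sqrt(d2)
        dim(D) <- c(n, n)
        Xc <- uCenter(newDistanceMatrix(D))
        tryCatch(dCorTTest(dCor(Xc, Yc), n)@pT,
                 gsdistDegenerate = function(e) 1)
    }
    current <- seq_len(m)
    subsets <- list(genes[current])
    subsetP <- pOf(current)
    steps <- data.frame(step = integer(), removedGene = character(),
                        nRemaining = integer(), pT = numeric(),
                        stringsAsFactors = FALSE)
    step <- 0L
    while (length(current) > 1) {
        step <- step + 1L
        pLoo <- vapply(seq_along(current),
                       function(j) pOf(current[-j]), numeric(1))
        drop <- which.min(pLoo)   # first minimum = lowest column index on ties
        removed <- genes[current[drop]]
        current <- current[-drop]
        steps <- rbind(steps, data.frame(
            step = step, removedGene = removed,
            nRemaining = length(current), pT = pLoo[drop],
            stringsAsFactors = FALSE))
        subsets <- c(subsets, list(genes[current]))
        subsetP <- c(subsetP, pLoo[drop])
    }
    # smallest p wins; among ties prefer the smaller subset (later entry)
    sizes <- lengths(subsets)
    best <- which(subsetP == min(subsetP))
    best <- best[which.min(sizes[best])]
    new("EliminationTrace", steps = steps, subsets = subsets,
        subsetP = subsetP, bestSubset = subsets[[best]],
        bestP = subsetP[best])
}

perGeneSquaredDiffs <- function(sub) {
    n <- nrow(sub)
    m <- ncol(sub)
    sq <- matrix(0, n * n, m)
    for (g in seq_len(m)) {
        d <- sub[, g] - rep(sub[, g], each = n)
        sq[, g] <- d * d
    }
    sq
}

#' Backward elimination within a permutation framework
#'
#' Reruns the entire backward-elimination procedure on each of `B`
#' endpoint-permuted datasets and compares the observed best p-value with
#' the permutation distribution of best p-values:
#' `p = (1 + #[bestP_b <= bestP_obs]) / (B + 1)`. Because every replicate
#' repeats the full selection, the resulting p-value accounts for the
#' subset search and is a valid significance level for the selected subset.
#'
#' @inheritParams backwardEliminate
#' @param B number of permutation replicates (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return list with `trace` (the observed [EliminationTrace-class]) and
#'   `pPermBest`, the selection-adjusted permutation p-value.
#' @export
eliminateWithPermutation <- function(X, geneSet, endpoint,
                                     transform = c("none", "zscore", "commensurate"),
                                     B = 1000, seed = NULL) {
    transform <- match.arg(transform)
    B <- as.integer(B)
    if (is.na(B) || B < 1) stop("B must be a positive integer")
    sub <- matchGeneSet(X, geneSet)
    if (ncol(sub) < 2) stop("backward elimination requires at least 2 matched genes")
    sub <- applyTransform(sub, transform)
    n <- nrow(sub)
    if (endpointLength(endpoint) != n)
        stop("endpoint length does not match subject count")
    Yc <- uCenter(endpointDistance(endpoint))
    sq <- perGeneSquaredDiffs(sub)
    obs <- eliminationCore(sub, Yc, n, sq = sq)
    if (!is.null(seed)) {
        old <- globalenv()$.Random.seed
        on.exit(restoreRNG(old), add = TRUE)
        set.seed(as.integer(seed))
    }
    bestPerm <- numeric(B)
    Y <- Yc@.Data
    for (b in seq_len(B)) {
        p <- sample.int(n)
        Ycb <- new("UCenteredMatrix", Y[p, p], rawScale = Yc@rawScale)
        bestPerm[b] <- eliminationCore(sub, Ycb, n, sq = sq)@bestP
    }
    list(trace = obs, pPermBest = (1 + sum(bestPerm <= obs@bestP)) / (B + 1),
         B = B, bestPerm = bestPerm)
}
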