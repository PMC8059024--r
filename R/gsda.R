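#' Gene-set distance association test
#'
#' Tests the association between the expression of a gene set and an
#' endpoint. The gene-set submatrix is (optionally transformed and) reduced
#' to a Euclidean subject-distance matrix, the endpoint to its own distance
#' matrix; both are U-centered and compared with the bias-corrected distance
#' correlation t-test. The test is self-contained: the result depends only
#' on the member genes and the endpoint. With `permutations > 0` a
#' permutation follow-up re-estimates the p-value by permuting subjects of
#' the U-centered endpoint matrix.
#'
#' @param X numeric expression matrix, subjects in rows, genes in columns
#'   (column names are the gene identifiers).
#' @param geneSet a [GeneSet-class] or character vector of gene identifiers;
#'   matching against `colnames(X)` is case-sensitive and exact. A warning
#'   is issued when fewer than half of the set's genes are found.
#' @param endpoint an [Endpoint-class].
#' @param transform per-gene transform applied to the matched submatrix:
#'   `"none"` (default), `"zscore"`, or `"commensurate"`.
#' @param permutations number of permutation replicates (0 = t-test only).
#' @param seed integer seed for the permutation stream.
#' @return a [DCorResult-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' y <- quantitativeEndpoint(X[, 1] + rnorm(50))
#' gsdaTest(X, c("g1", "g2"), y)
#' @export
gsdaTest <- function(X, geneSet, endpoint,
                     transform = c("none", "zscore", "commensurate"),
                     permutations = 0, seed = NULL) {
    transform <- match.arg(transform)
    sub <- matchGeneSet(X, geneSet)
    n <- nrow(sub)
    if (endpointLength(endpoint) != n)
        stop("endpoint length (", endpointLength(endpoint),
             ") does not match subject count (", n, ")")
    Xc <- uCenter(euclideanDistanceMatrix(applyTransform(sub, transform)))
    Yc <- uCenter(endpointDistance(endpoint))
    res <- dCorTTest(dCor(Xc, Yc), n)
    res@nGenes <- ncol(sub)
    if (permutations > 0) {
        perm <- permutationTest(Xc, Yc, B = permutations, seed = seed)
        res@pPerm <- perm$pPerm
        res@nPerm <- perm$B
    }
    res
}

matchGeneSet <- function(X, geneSet) {
    X <- as.matrix(X)
    genes <- if (is(geneSet, "GeneSet")) geneSet@genes else as.character(geneSet)
    setName <- if (is(geneSet, "GeneSet")) geneSet@name else "gene set"
    if (anyDuplicated(genes)) {
        warning("duplicate gene identifiers in ", setName, "; deduplicated")
        genes <- unique(genes)
    }
    hit <- genes[genes %in% colnames(X)]
    if (length(hit) == 0)
        stop("no genes of ", setName, " are present in the expression matrix")
    if (length(hit) < length(genes) / 2)
        warning("fewer than 50% of the genes of ", setName,
                " are present in the expression matrix (",
                length(hit), "/", length(genes), ")")
    X[, hit, drop = FALSE]
}

#' Permutation verification of a distance correlation
#'
#' Re-estimates the significance of an observed distance correlation by
#' permuting subjects. Each replicate applies one random permutation
#' simultaneously to the rows and columns of the U-centered endpoint matrix
#' and recomputes only the inner products and their ratio — U-centering
#' commutes with simultaneous row/column permutation, so the centering step
#' need not be repeated. The permutation statistic is the correlation itself
#' (the t-statistic is a fixed monotone function of it at fixed n). The
#' p-value uses the add-one estimator `(1 + #[r_b >= r_obs]) / (B + 1)`,
#' which can never return zero. Intended as a follow-up for the smallest
#' t-test p-values, where the asymptotic t approximation is least reliable.
#'
#' @param Xc,Yc [UCenteredMatrix-class] objects for the gene set and the
#'   endpoint.
#' @param B number of permutation replicates (>= 1).
#' @param seed integer seed; the stream is restored-independent of the
#'   caller's RNG state.
#' @return list with `pPerm`, the observed `rd`, `B`, and the replicate
#'   correlations `rPerm`.
#' @export
permutationTest <- function(Xc, Yc, B = 10000, seed = NULL) {
    B <- as.integer(B)
    if (is.na(B) || B < 1) stop("B must be a positive integer")
    a <- Xc@.Data
    b <- Yc@.Data
    n <- nrow(a)
    if (nrow(b) != n) stop("U-centered matrices must have matching dimensions")
    aa <- innerProduct(Xc, Xc)
    bb <- innerProduct(Yc, Yc)
    if (aa <= degeneracyTol(Xc) || bb <= degeneracyTol(Yc))
        stop(degenerateError("degenerate self inner product; permutation test undefined"))
    denom <- sqrt(aa * bb)
    scale <- n * (n - 3)
    rObs <- sum(a * b) / scale / denom
    if (!is.null(seed)) {
        old <- globalenv()$.Random.seed
        on.exit(restoreRNG(old), add = TRUE)
        set.seed(as.integer(seed))
    }
    rPerm <- numeric(B)
    for (k in seq_len(B)) {
        p <- sample.int(n)
        rPerm[k] <- sum(a * b[p, p]) / scale / denom
    }
    list(pPerm = (1 + sum(rPerm >= rObs)) / (B + 1), rd = rObs, B = B,
         rPerm = rPerm)
}

restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}

#' Screen a collection of gene sets
#'
#' Runs [gsdaTest()] for every gene set in a collection against one
#' endpoint, adjusts the t-test p-values for multiplicity
#' (Benjamini-Hochberg by default), and optionally follows up the most
#' significant sets with a permutation test. The t-test screens the whole
#' collection quickly; permutation is triggered only for sets with
#' `p_t <= alpha` (the t approximation can overstate significance in the
#' extreme lower tail, so the smallest p-values deserve verification).
#' Degenerate sets — all matched genes constant, or no genes matched — are
#' reported with a status flag and `NA` statistics rather than aborting the
#' screen. Rows are ordered by permutation p-value where available, with the
#' t-test p-value breaking ties.
#'
#' @param X expression matrix, subjects x genes.
#' @param collection list of [GeneSet-class] objects (e.g. from
#'   [readGMT()]), or a named list of character vectors.
#' @param endpoint an [Endpoint-class].
#' @param transform per-gene transform, as in [gsdaTest()].
#' @param permutations permutation replicates for the follow-up (0 disables).
#' @param alpha t-test p-value threshold that triggers the follow-up.
#' @param fdrMethod multiplicity adjustment passed to [stats::p.adjust()].
#' @param seed master seed; each gene set gets a deterministic substream
#'   derived from (seed, set index), so results do not depend on execution
#'   order.
#' @return a [ScreenResult-class].
#' @export
gsdaScreen <- function(X, collection, endpoint,
                       transform = c("none", "zscore", "commensurate"),
                       permutations = 0, alpha = 0.05, fdrMethod = "BH",
                       seed = NULL) {
    transform <- match.arg(transform)
    collection <- asGeneSetList(collection)
    n <- nrow(X)
    Yc <- uCenter(endpointDistance(endpoint))
    rows <- lapply(seq_along(collection), function(k) {
        gs <- collection[[k]]
        out <- data.frame(set = gs@name, nGenesSet = length(gs@genes),
                          nGenesMatched = 0L, rd = NA_real_, td = NA_real_,
                          df = NA_real_, pT = NA_real_, pPerm = NA_real_,
                          status = "ok", stringsAsFactors = FALSE)
        res <- tryCatch({
            sub <- withCallingHandlers(
                matchGeneSet(X, gs),
                warning = function(w) invokeRestart("muffleWarning"))
            out$nGenesMatched <- ncol(sub)
            Xc <- uCenter(euclideanDistanceMatrix(applyTransform(sub, transform)))
            r <- dCorTTest(dCor(Xc, Yc), n)
            out$rd <- r@rd; out$td <- r@td; out$df <- r@df; out$pT <- r@pT
            if (permutations > 0 && r@pT <= alpha) {
                sub.seed <- if (is.null(seed)) NULL else
                    (as.integer(seed) + 7919L * k) %% 2147483647L
                out$pPerm <- permutationTest(Xc, Yc, B = permutations,
                                             seed = sub.seed)$pPerm
            }
            out
        },
        gsdistDegenerate = function(e) { out$status <- "degenerate"; out },
        error = function(e) { out$status <- conditionMessage(e); out })
        res
    })
    tab <- do.call(rbind, rows)
    ok <- !is.na(tab$pT)
    tab$q <- NA_real_
    tab$q[ok] <- stats::p.adjust(tab$pT[ok], method = fdrMethod)
    ord <- order(!ok, ifelse(is.na(tab$pPerm), tab$pT, tab$pPerm), tab$pT)
    new("ScreenResult", results = tab[ord, , drop = FALSE], alpha = alpha,
        fdrMethod = fdrMethod)
}

asGeneSetList <- function(collection) {
    if (is(collection, "GeneSet")) collection <- list(collection)
    if (!is.list(collection) || length(collection) == 0)
        stop("collection must be a nonempty list of gene sets")
    out <- lapply(seq_along(collection), function(k) {
        gs <- collection[[k]]
        if (is(gs, "GeneSet")) return(gs)
        nm <- names(collection)[k]
        if (is.null(nm) || !nzchar(nm)) nm <- paste0("set", k)
        new("GeneSet", name = nm, description = "", genes = unique(as.character(gs)))
    })
    out
}

#' Extract the per-set table from a screen
#' @param x a [ScreenResult-class].
#' @return data.frame, one row per gene set.
#' @export
resultsTable <- function(x) {
    stopifnot(is(x, "ScreenResult"))
    x@results
}
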