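#' Variance-equalizing expression transforms
#'
#' Optional per-gene transforms applied before distance calculation, so that
#' every gene contributes comparably to the Euclidean distance between
#' subjects. `zscoreTransform` centers each gene and divides by its sample
#' standard deviation. `commensurateTransform` centers each gene and divides
#' by the sum of absolute differences over all unordered subject pairs, after
#' which each gene's pairwise-distance total is exactly 1. Neither transform
#' is ever applied silently: equalizing variance is advisable when lowly and
#' highly expressed genes are equally informative and counterproductive when
#' expression magnitude itself carries the biology.
#'
#' @param X numeric matrix, subjects x genes.
#' @return a transformed matrix of the same shape and dimnames.
#' @examples
#' X <- matrix(rnorm(40), nrow = 10)
#' colMeans(zscoreTransform(X))        # ~0
#' apply(zscoreTransform(X), 2, sd)    # 1
#' @export
zscoreTransform <- function(X) {
    X <- as.matrix(X)
    sds <- apply(X, 2, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad))
        stop("zero-variance gene(s): ",
             paste(colnamesOrIndex(X, bad), collapse = ", "))
    scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' @rdname zscoreTransform
#' @export
commensurateTransform <- function(X) {
    X <- as.matrix(X)
    n <- nrow(X)
    out <- X
    for (g in seq_len(ncol(X))) {
        x <- X[, g]
        # sum of |x_i - x_j| over unordered pairs, via the sorted-order identity
        xs <- sort(x)
        s <- sum((2 * seq_len(n) - n - 1) * xs)
        if (s == 0)
            stop("constant gene(s) cannot be commensurated: ",
                 colnamesOrIndex(X, g))
        out[, g] <- (x - mean(x)) / s
    }
    out
}

colnamesOrIndex <- function(X, idx) {
    if (is.null(colnames(X))) paste0("column ", idx) else colnames(X)[idx]
}

applyTransform <- function(X, transform = c("none", "zscore", "commensurate")) {
    transform <- match.arg(transform)
    switch(transform,
        none = X,
        zscore = zscoreTransform(X),
        commensurate = commensurateTransform(X))
}
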