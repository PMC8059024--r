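#' Euclidean distance matrix between subjects
#'
#' Computes the n x n matrix of Euclidean distances between the rows of a
#' subjects x genes expression matrix. Squared distances are accumulated
#' gene by gene, which lets the driver-selection routines update distances
#' after removing a gene without revisiting the raw data.
#'
#' @param X numeric matrix, subjects in rows, genes in columns; no missing
#'   values; at least 4 rows (the bias-corrected inner product requires
#'   n > 3).
#' @return a [DistanceMatrix-class].
#' @examples
#' X <- matrix(rnorm(20), nrow = 5)
#' euclideanDistanceMatrix(X)
#' @export
euclideanDistanceMatrix <- function(X) {
    X <- as.matrix(X)
    if (!is.numeric(X)) stop("expression values must be numeric")
    if (anyNA(X)) stop("expression matrix must not contain missing values")
    if (ncol(X) < 1) stop("expression matrix must have at least one gene")
    if (nrow(X) < 4) stop("at least 4 subjects are required (n > 3)")
    D <- sqrt(pairwiseSquaredDistances(X))
    newDistanceMatrix(D, rownames(X))
}

# Sum over genes of per-gene squared difference matrices, accumulated in
# column order. Shared by the plain and the incremental (leave-one-out)
# distance paths so the two agree bit-for-bit.
pairwiseSquaredDistances <- function(X) {
    n <- nrow(X)
    acc <- matrix(0, n, n)
    for (g in seq_len(ncol(X))) {
        d <- X[, g] - rep(X[, g], each = n)
        dim(d) <- c(n, n)
        acc <- acc + d * d
    }
    diag(acc) <- 0
    acc
}

newDistanceMatrix <- function(D, ids = NULL) {
    D <- unname(as.matrix(D))
    D[D < 0] <- 0
    diag(D) <- 0
    D <- (D + t(D)) / 2   # enforce exact symmetry against rounding
    if (!is.null(ids)) dimnames(D) <- list(ids, ids)
    new("DistanceMatrix", D)
}

#' U-center a distance matrix
#'
#' Applies the unbiased double-centering that subtracts the scaled row and
#' column sums and adds back the scaled grand sum:
#' \deqn{\tilde a_{ij} = a^*_{ij} - \frac{a^*_{i\cdot} + a^*_{\cdot j}}{n-2}
#'   + \frac{a^*_{\cdot\cdot}}{(n-1)(n-2)},}
#' with the diagonal stored as zero. For a symmetric zero-diagonal input
#' every off-diagonal row sum of the result is zero, an algebraic identity
#' used as a property test.
#'
#' @param D a [DistanceMatrix-class] (or plain symmetric zero-diagonal
#'   matrix), n >= 4.
#' @return a [UCenteredMatrix-class]; its `rawScale` slot records the mean
#'   squared off-diagonal raw distance, the scale reference for degeneracy
#'   flagging in [dCor()].
#' @export
uCenter <- function(D) {
    if (!is(D, "DistanceMatrix")) D <- newDistanceMatrix(D)
    A <- D@.Data
    n <- nrow(A)
    if (n < 4) stop("at least 4 subjects are required (n > 3)")
    rs <- rowSums(A)
    cs <- colSums(A)
    gs <- sum(rs)
    U <- A - outer(rs, cs, `+`) / (n - 2) + gs / ((n - 1) * (n - 2))
    diag(U) <- 0
    new("UCenteredMatrix", unname(U),
        rawScale = sum(A * A) / (n * (n - 1)))
}

#' Bias-corrected inner product of two U-centered matrices
#'
#' \deqn{(\tilde A \cdot \tilde B) = \frac{1}{n(n-3)} \sum_{i \ne j}
#'   \tilde a_{ij} \tilde b_{ij}.}
#' The diagonal never enters the sum (it is stored as zero). The self inner
#' product is an unbiased estimator of the squared distance covariance and
#' is nonnegative for U-centered Euclidean distance matrices.
#'
#' @param A,B [UCenteredMatrix-class] objects of matching dimension.
#' @return a single numeric value.
#' @export
innerProduct <- function(A, B) {
    a <- if (is(A, "UCenteredMatrix")) A@.Data else as.matrix(A)
    b <- if (is(B, "UCenteredMatrix")) B@.Data else as.matrix(B)
    n <- nrow(a)
    if (nrow(b) != n || ncol(a) != n || ncol(b) != n)
        stop("U-centered matrices must have matching dimensions")
    sum(a * b) / (n * (n - 3))
}

#' Bias-corrected distance correlation
#'
#' The ratio of the inner product of the two U-centered distance matrices to
#' the geometric mean of their self inner products. Gene sets (or endpoints)
#' whose distances are all zero have a zero self inner product and no
#' defined correlation; these are flagged with a `"degenerate"` classed
#' error rather than dividing by zero. Degeneracy is declared when a self
#' inner product falls below `1e-12 * (rawScale + 1e-300)`, a scale-aware
#' guard tied to the raw distance magnitudes.
#'
#' @param A,B [UCenteredMatrix-class] objects of matching dimension.
#' @return the distance correlation, a number in [-1, 1].
#' @export
dCor <- function(A, B) {
    aa <- innerProduct(A, A)
    bb <- innerProduct(B, B)
    tolA <- degeneracyTol(A)
    tolB <- degeneracyTol(B)
    if (aa <= tolA)
        stop(degenerateError("first matrix has (near-)zero self inner product; all distances are (near) zero"))
    if (bb <= tolB)
        stop(degenerateError("second matrix has (near-)zero self inner product; all distances are (near) zero"))
    r <- innerProduct(A, B) / sqrt(aa * bb)
    max(-1, min(1, r))
}

degeneracyTol <- function(A) {
    sc <- if (is(A, "UCenteredMatrix") && is.finite(A@rawScale)) A@rawScale else 0
    1e-12 * (sc + 1e-300)
}

degenerateError <- function(msg) {
    structure(class = c("gsdistDegenerate", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
}

#' Distance correlation t-test
#'
#' Converts a bias-corrected distance correlation into a t-statistic,
#' \deqn{t_d = \frac{r_d}{\sqrt{1 - r_d^2}} \sqrt{n(n-3)/2 - 1},}
#' referred to the t distribution on `n(n-3)/2 - 1` degrees of freedom.
#' The p-value is the upper-tail probability: under dependence the
#' bias-corrected correlation is inflated upward, so the test is one-sided
#' and a negative correlation yields p > 0.5. A correlation at or beyond
#' +/-1 (possible only through rounding) is clamped to +/-(1 - 1e-15) so the
#' statistic stays finite while preserving extreme significance.
#'
#' @param rd distance correlation, as from [dCor()].
#' @param n number of subjects (>= 4).
#' @return a [DCorResult-class] with `rd`, `td`, `df`, and `pT` filled in.
#' @examples
#' dCorTTest(0.5, 20)
#' @export
dCorTTest <- function(rd, n) {
    if (length(rd) != 1 || !is.finite(rd)) stop("rd must be a single finite number")
    n <- as.integer(n)
    if (n < 4) stop("at least 4 subjects are required (df >= 1 needs n > 3)")
    df <- n * (n - 3) / 2 - 1
    r <- max(-(1 - 1e-15), min(1 - 1e-15, rd))
    td <- r / sqrt(1 - r * r) * sqrt(df)
    pT <- stats::pt(td, df = df, lower.tail = FALSE)
    # extreme statistics can underflow the t tail to exactly 0; keep p > 0
    pT <- max(pT, .Machine$double.xmin)
    new("DCorResult", rd = rd, td = td, df = df, pT = pT, n = n)
}
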