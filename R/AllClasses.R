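#' @import methods
NULL

#' Pairwise subject distance matrix
#'
#' An n x n matrix of pairwise distances between subjects, as produced by
#' [euclideanDistanceMatrix()] or [endpointDistance()]. Validity requires
#' symmetry, a zero diagonal, and nonnegative entries; subject identifiers
#' are carried in the dimnames.
#'
#' @slot .Data numeric matrix of distances.
#' @export
setClass("DistanceMatrix", contains = "matrix", validity = function(object) {
    m <- object@.Data
    if (!is.numeric(m)) return("distance entries must be numeric")
    if (nrow(m) != ncol(m)) return("distance matrix must be square")
    if (anyNA(m)) return("distance matrix must not contain missing values")
    if (any(m < 0)) return("distances must be nonnegative")
    if (any(diag(m) != 0)) return("distance matrix must have a zero diagonal")
    if (!isSymmetric(unname(m))) return("distance matrix must be symmetric")
    TRUE
})

#' U-centered distance matrix
#'
#' The unbiased double-centering of a [DistanceMatrix-class] produced by
#' [uCenter()]. Off-diagonal entries are the centered distances; the diagonal
#' is stored as zero by convention and never enters the inner product. The
#' `rawScale` slot records the mean squared off-diagonal entry of the raw
#' distance matrix, used as the scale reference when flagging degenerate
#' (all-zero-distance) gene sets.
#'
#' @slot .Data numeric matrix of U-centered entries.
#' @slot rawScale numeric(1), mean squared off-diagonal raw distance.
#' @export
setClass("UCenteredMatrix", contains = "matrix",
    representation(rawScale = "numeric"),
    prototype(rawScale = NA_real_),
    validity = function(object) {
        m <- object@.Data
        if (!is.numeric(m)) return("entries must be numeric")
        if (nrow(m) != ncol(m)) return("U-centered matrix must be square")
        if (nrow(m) < 4) return("U-centered matrix requires n >= 4")
        if (any(diag(m) != 0)) return("diagonal must be stored as zero")
        TRUE
    })

#' Distance correlation t-test result
#'
#' Holds the bias-corrected distance correlation `rd`, the t-statistic `td`
#' on `df = n(n-3)/2 - 1` degrees of freedom, the upper-tail t-test p-value
#' `pT`, and (when a permutation follow-up was run) the permutation p-value
#' `pPerm` with its replicate count `nPerm`.
#'
#' @slot rd distance correlation in [-1, 1].
#' @slot td t-statistic.
#' @slot df degrees of freedom, n(n-3)/2 - 1.
#' @slot pT upper-tail t-test p-value.
#' @slot pPerm permutation p-value, `NA` unless permutation was requested.
#' @slot nPerm number of permutation replicates, `NA` unless requested.
#' @slot n number of subjects.
#' @slot nGenes number of matched genes entering the expression distance.
#' @export
setClass("DCorResult", representation(
    rd = "numeric", td = "numeric", df = "numeric", pT = "numeric",
    pPerm = "numeric", nPerm = "numeric", n = "integer", nGenes = "integer"),
    prototype(pPerm = NA_real_, nPerm = NA_real_, n = NA_integer_,
              nGenes = NA_integer_),
    validity = function(object) {
        if (length(object@rd) != 1 || is.na(object@rd))
            return("rd must be a single number")
        if (abs(object@rd) > 1) return("rd must lie in [-1, 1]")
        if (object@df < 1) return("degrees of freedom must be >= 1")
        if (object@pT <= 0 || object@pT > 1) return("pT must be in (0, 1]")
        TRUE
    })

#' Endpoint variable for association testing
#'
#' Virtual parent of the three endpoint variants: quantitative
#' ([QuantitativeEndpoint-class]), categorical ([CategoricalEndpoint-class]),
#' and right-censored event time ([SurvivalEndpoint-class]). Construct with
#' [quantitativeEndpoint()], [categoricalEndpoint()], or
#' [survivalEndpoint()].
#'
#' @slot subjectIds optional subject identifiers.
#' @export
setClass("Endpoint", representation("VIRTUAL", subjectIds = "character"))

#' @rdname Endpoint-class
#' @slot values numeric endpoint values.
#' @export
setClass("QuantitativeEndpoint", contains = "Endpoint",
    representation(values = "numeric"),
    validity = function(object) {
        if (length(object@values) < 4) return("endpoint requires n >= 4")
        if (!all(is.finite(object@values)))
            return("quantitative endpoint values must be finite")
        TRUE
    })

#' @rdname Endpoint-class
#' @slot labels character category labels, compared by exact token equality.
#' @export
setClass("CategoricalEndpoint", contains = "Endpoint",
    representation(labels = "character"),
    validity = function(object) {
        if (length(object@labels) < 4) return("endpoint requires n >= 4")
        if (anyNA(object@labels)) return("labels must not be missing")
        TRUE
    })

#' @rdname Endpoint-class
#' @slot time positive observation times.
#' @slot status event indicators: 1 = event at `time`, 0 = censored.
#' @export
setClass("SurvivalEndpoint", contains = "Endpoint",
    representation(time = "numeric", status = "integer"),
    validity = function(object) {
        if (length(object@time) < 4) return("endpoint requires n >= 4")
        if (length(object@time) != length(object@status))
            return("time and status must have equal length")
        if (!all(is.finite(object@time)) || any(object@time <= 0))
            return("observation times must be finite and positive")
        if (!all(object@status %in% c(0L, 1L)))
            return("status must be coded 0 (censored) / 1 (event)")
        TRUE
    })

#' Named gene set
#'
#' @slot name set identifier.
#' @slot description free-text description (second GMT column).
#' @slot genes ordered, deduplicated gene identifiers.
#' @export
setClass("GeneSet", representation(
    name = "character", description = "character", genes = "character"),
    validity = function(object) {
        if (length(object@genes) == 0) return("gene set must be nonempty")
        if (anyDuplicated(object@genes)) return("gene identifiers must be unique")
        TRUE
    })

#' Gene-set collection screen result
#'
#' One row per gene set with the matched gene count, distance correlation,
#' t-statistic, degrees of freedom, t-test p-value, optional permutation
#' p-value, and Benjamini-Hochberg q-value. Rows are ordered by
#' (`p_perm` when present, then `p_t`); degenerate sets carry a status flag
#' and `NA` statistics. Retrieve the table with [resultsTable()].
#'
#' @slot results the per-set results `data.frame`.
#' @slot alpha permutation follow-up trigger threshold used.
#' @slot fdrMethod multiplicity adjustment method name.
#' @export
setClass("ScreenResult", representation(
    results = "data.frame", alpha = "numeric", fdrMethod = "character"))

#' Backward-elimination trace
#'
#' Records each elimination round (which gene was removed and the t-test
#' p-value of the remaining subset), every candidate subset evaluated
#' (including the intact full set), and the best-p subset. The best-subset
#' p-value is selection-biased: it is a subset-selection criterion, not a
#' Type I error rate; use [eliminateWithPermutation()] for a
#' selection-adjusted significance level.
#'
#' @slot steps data.frame with columns `step`, `removedGene`, `nRemaining`,
#'   `pT`: round-by-round removals.
#' @slot subsets list of character vectors: the surviving subset after each
#'   step, preceded by the full set (element 1).
#' @slot subsetP numeric: the t-test p-value of each element of `subsets`.
#' @slot bestSubset gene identifiers of the best-p subset.
#' @slot bestP its (selection-biased) t-test p-value.
#' @export
setClass("EliminationTrace", representation(
    steps = "data.frame", subsets = "list", subsetP = "numeric",
    bestSubset = "character", bestP = "numeric"))

#' Simulation configuration
#'
#' Study conditions for the level/power harness: gene-set collection layout
#' (`"A"`: 100 genes in 60 sets of 8-10, 10 sets harbouring associated genes;
#' `"B"`: 1000 genes in 100 sets of 10-100, 20 associated sets), endpoint
#' type, association structure (`"null"`, `"simple"`, `"complex"`), sample
#' size (`n` is per group for the categorical endpoint, total otherwise),
#' association coefficient `beta`, residual scale `noiseSd`, target censoring
#' fraction, replicate count, and master seed.
#'
#' @export
setClass("SimulationConfig", representation(
    collection = "character", endpoint = "character", association = "character",
    n = "integer", beta = "numeric", noiseSd = "numeric",
    censorFrac = "numeric", reps = "integer", seed = "integer"),
    validity = function(object) {
        if (!object@collection %in% c("A", "B"))
            return("collection must be \"A\" or \"B\"")
        if (!object@endpoint %in% c("quantitative", "categorical", "survival"))
            return("endpoint must be quantitative, categorical, or survival")
        if (!object@association %in% c("null", "simple", "complex"))
            return("association must be null, simple, or complex")
        if (object@n < 4) return("n must be >= 4")
        if (object@reps < 1) return("reps must be >= 1")
        if (object@censorFrac < 0 || object@censorFrac >= 1)
            return("censorFrac must be in [0, 1)")
        TRUE
    })
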