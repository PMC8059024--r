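#' Endpoint constructors
#'
#' Build a typed endpoint from raw vectors. `quantitativeEndpoint` wraps a
#' finite numeric vector; `categoricalEndpoint` wraps category labels
#' (compared by exact token equality — merge groups yourself before calling
#' if coarser categories are wanted); `survivalEndpoint` wraps right-censored
#' observation time / status pairs with status coded 1 = event, 0 = censored.
#'
#' @param y numeric values (quantitative) or labels (categorical).
#' @param subjectIds optional subject identifiers, recycled onto names.
#' @return an [Endpoint-class] subclass instance.
#' @examples
#' quantitativeEndpoint(c(1.2, 0.4, -0.3, 2.2))
#' categoricalEndpoint(c("A", "A", "B", "B"))
#' survivalEndpoint(c(1, 3, 2, 5), c(1, 0, 1, 0))
#' @export
quantitativeEndpoint <- function(y, subjectIds = character()) {
    if (!is.null(names(y)) && length(subjectIds) == 0) subjectIds <- names(y)
    new("QuantitativeEndpoint", values = as.numeric(y), subjectIds = subjectIds)
}

#' @rdname quantitativeEndpoint
#' @export
categoricalEndpoint <- function(y, subjectIds = character()) {
    if (!is.null(names(y)) && length(subjectIds) == 0) subjectIds <- names(y)
    new("CategoricalEndpoint", labels = as.character(y), subjectIds = subjectIds)
}

#' @rdname quantitativeEndpoint
#' @param time positive observation times.
#' @param status 0/1 event indicators aligned with `time`.
#' @export
survivalEndpoint <- function(time, status, subjectIds = character()) {
    if (!is.null(names(time)) && length(subjectIds) == 0) subjectIds <- names(time)
    new("SurvivalEndpoint", time = as.numeric(time),
        status = as.integer(status), subjectIds = subjectIds)
}

#' Number of subjects in an endpoint
#' @param ep an [Endpoint-class].
#' @return integer subject count.
#' @export
setGeneric("endpointLength", function(ep) standardGeneric("endpointLength"))

#' @rdname endpointLength
setMethod("endpointLength", "QuantitativeEndpoint", function(ep) length(ep@values))
#' @rdname endpointLength
setMethod("endpointLength", "CategoricalEndpoint", function(ep) length(ep@labels))
#' @rdname endpointLength
setMethod("endpointLength", "SurvivalEndpoint", function(ep) length(ep@time))

#' Subset an endpoint to selected subjects
#' @param ep an [Endpoint-class].
#' @param idx integer or logical subject index.
#' @return an endpoint of the same variant.
#' @export
setGeneric("subsetEndpoint", function(ep, idx) standardGeneric("subsetEndpoint"))

#' @rdname subsetEndpoint
setMethod("subsetEndpoint", "QuantitativeEndpoint", function(ep, idx)
    new("QuantitativeEndpoint", values = ep@values[idx],
        subjectIds = if (length(ep@subjectIds)) ep@subjectIds[idx] else character()))
#' @rdname subsetEndpoint
setMethod("subsetEndpoint", "CategoricalEndpoint", function(ep, idx)
    new("CategoricalEndpoint", labels = ep@labels[idx],
        subjectIds = if (length(ep@subjectIds)) ep@subjectIds[idx] else character()))
#' @rdname subsetEndpoint
setMethod("subsetEndpoint", "SurvivalEndpoint", function(ep, idx)
    new("SurvivalEndpoint", time = ep@time[idx], status = ep@status[idx],
        subjectIds = if (length(ep@subjectIds)) ep@subjectIds[idx] else character()))

#' Endpoint distance matrix
#'
#' Builds the subject-by-subject distance matrix for an endpoint:
#' \itemize{
#'   \item quantitative: absolute difference `|y_i - y_j|` (the
#'     one-dimensional Euclidean distance);
#'   \item categorical: the indicator distance, 1 when the labels differ and
#'     0 when they agree;
#'   \item censored event time: the event-grid count distance of
#'     [survivalDistanceMatrix()].
#' }
#' A categorical endpoint with a single observed label has an identically
#' zero distance matrix and no definable association; that case raises a
#' `"degenerate"` classed error.
#'
#' @param ep an [Endpoint-class].
#' @return a [DistanceMatrix-class].
#' @export
setGeneric("endpointDistance", function(ep) standardGeneric("endpointDistance"))

#' @rdname endpointDistance
setMethod("endpointDistance", "QuantitativeEndpoint", function(ep) {
    D <- abs(outer(ep@values, ep@values, `-`))
    newDistanceMatrix(D, if (length(ep@subjectIds)) ep@subjectIds else NULL)
})

#' @rdname endpointDistance
setMethod("endpointDistance", "CategoricalEndpoint", function(ep) {
    if (length(unique(ep@labels)) < 2)
        stop(degenerateError("categorical endpoint has a single label; no association is definable"))
    D <- 1 * outer(ep@labels, ep@labels, `!=`)
    newDistanceMatrix(D, if (length(ep@subjectIds)) ep@subjectIds else NULL)
})

#' @rdname endpointDistance
setMethod("endpointDistance", "SurvivalEndpoint", function(ep)
    survivalDistanceMatrix(ep@time, ep@status,
        if (length(ep@subjectIds)) ep@subjectIds else NULL))

#' Censored event-time distance
#'
#' Rank-style distance between right-censored observations. With
#' `u_1 < ... < u_s` the unique times at which events occurred, the distance
#' between subjects i and j is
#' \deqn{\sum_{l} I(o_j > u_l \ge o_i) I(s_i = 1)
#'   + I(o_i > u_l \ge o_j) I(s_j = 1):}
#' the number of distinct event times separating the pair's observation
#' windows, counted only from the side whose subject actually had the event.
#' Two censored subjects are at distance zero. Because only the ordering of
#' times enters, the matrix is invariant under any strictly increasing
#' transformation of the observation times. Inequalities are applied exactly
#' as written (strict `>` on the later observation, `>=` on the earlier), so
#' a subject observed exactly at an event time contributes through the
#' `u_l >= o_i` side only.
#'
#' @param time positive observation times.
#' @param status 0/1 event indicators; at least one event is required.
#' @param subjectIds optional identifiers for the dimnames.
#' @return a [DistanceMatrix-class] of integer-valued distances.
#' @examples
#' survivalDistanceMatrix(c(1, 3, 2, 5), c(1, 0, 1, 0))
#' @export
survivalDistanceMatrix <- function(time, status, subjectIds = NULL) {
    time <- as.numeric(time)
    status <- as.integer(status)
    n <- length(time)
    if (n < 4) stop("at least 4 subjects are required (n > 3)")
    if (length(status) != n) stop("time and status must have equal length")
    if (!all(status %in% c(0L, 1L))) stop("status must be coded 0/1")
    if (any(!is.finite(time) | time <= 0))
        stop("observation times must be finite and positive")
    u <- sort(unique(time[status == 1L]))
    if (length(u) == 0)
        stop(degenerateError("no events observed; the event-time distance is identically zero"))
    # cnt[i] = number of unique event times u_l with u_l >= time[i],
    # counted downward; below[i] = number with u_l < time[i].
    below <- findInterval(time, u, left.open = TRUE)  # below[i] = #{l: u_l < o_i}
    # For s_i = 1: #{l : o_j > u_l >= o_i} = #{u_l < o_j} - #{u_l < o_i},
    # nonzero only when o_j > o_i.
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
        # contribution from subject i's event side
        if (status[i] == 1L) {
            cnt <- below - below[i]          # #{l: u_l < o_j} - #{l: u_l < o_i}
            cnt[time <= time[i]] <- 0        # requires o_j > u_l >= o_i, so o_j > o_i
            D[i, ] <- D[i, ] + cnt
            D[, i] <- D[, i] + cnt
        }
    }
    diag(D) <- 0
    newDistanceMatrix(D, subjectIds)
}
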