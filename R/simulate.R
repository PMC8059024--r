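#' Build a simulation configuration
#'
#' Study conditions for the level/power harness. Collection `"A"` has 100
#' genes (10 associated under non-null configurations, 90 null) partitioned
#' across 60 gene sets of 8-10 genes, 10 of which contain at least one
#' associated gene; collection `"B"` has 1000 genes (10 associated) across
#' 100 sets of 10-100 genes, 20 of which contain at least one associated
#' gene. Null genes are iid standard normal. Associated genes are driven by
#' a latent standard-normal subject variable `L`: under a simple association
#' gene g is `beta * L + noise`, under a complex association a per-subject
#' random sign vector `Z` (one draw shared by all associated genes) flips
#' the coefficient, `Z * beta * L + noise`, producing differential
#' correlation between associated genes with no mean shift. Endpoints derive
#' from the same `L`: quantitative `y = L + N(0,1)`; categorical = two
#' equal groups split at the median of `L + N(0,1)` (`n` is the per-group
#' size); survival has event times `Exp(rate = exp(L))` with independent
#' `Uniform(0, c)` censoring, `c` solved so the expected censoring fraction
#' matches `censorFrac`. Under `association = "null"` the endpoint is
#' independent of all genes.
#'
#' @param collection `"A"` or `"B"`.
#' @param endpoint `"quantitative"`, `"categorical"`, or `"survival"`.
#' @param association `"null"`, `"simple"`, or `"complex"`.
#' @param n subjects (per group for categorical endpoints).
#' @param beta association coefficient for the latent variable (default 1,
#'   a 1:1 signal-to-noise ratio).
#' @param noiseSd residual standard deviation of associated genes.
#' @param censorFrac target expected censoring fraction (survival only).
#' @param reps replicate count for the harness.
#' @param seed master seed; gene-set membership is drawn once from it, and
#'   replicate r uses the derived substream seed
#'   `(seed + 1000003 * r) mod (2^31 - 1)`.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(collection = "A", endpoint = "quantitative",
                             association = "null", n = 50L, beta = 1,
                             noiseSd = 1, censorFrac = 0.3, reps = 500L,
                             seed = 1L) {
    new("SimulationConfig", collection = collection, endpoint = endpoint,
        association = association, n = as.integer(n), beta = beta,
        noiseSd = noiseSd, censorFrac = censorFrac, reps = as.integer(reps),
        seed = as.integer(seed))
}

collectionLayout <- function(collection) {
    switch(collection,
        A = list(nGenes = 100L, nAssoc = 10L, nSets = 60L, sizeRange = c(8L, 10L),
                 nAssocSets = 10L),
        B = list(nGenes = 1000L, nAssoc = 10L, nSets = 100L, sizeRange = c(10L, 100L),
                 nAssocSets = 20L),
        stop("collection must be \"A\" or \"B\""))
}

#' Gene-set membership for a simulated collection
#'
#' Draws the fixed gene-set structure used across all replicates of one
#' configuration: set sizes uniform within the collection's range, the
#' stated number of associated sets each seeded with at least one associated
#' gene (associated gene k anchors associated set k, cycling, plus each
#' other associated gene independently with probability 0.1), and remaining
#' members sampled from the null genes so that exactly the stated number of
#' sets contain associated genes.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with `sets` (named list of [GeneSet-class]), `associatedGenes`,
#'   `associatedSets`, and `nullSets` (set names).
#' @export
simulateCollection <- function(cfg) {
    lay <- collectionLayout(cfg@collection)
    withSeed(cfg@seed, {
        geneIds <- sprintf("g%04d", seq_len(lay$nGenes))
        assocGenes <- geneIds[seq_len(lay$nAssoc)]
        nullGenes <- setdiff(geneIds, assocGenes)
        sizes <- sample(seq(lay$sizeRange[1], lay$sizeRange[2]),
                        lay$nSets, replace = TRUE)
        assocSetIdx <- seq_len(lay$nAssocSets)
        sets <- vector("list", lay$nSets)
        for (k in seq_len(lay$nSets)) {
            if (k %in% assocSetIdx) {
                anchor <- assocGenes[((k - 1) %% lay$nAssoc) + 1]
                extra <- assocGenes[stats::runif(lay$nAssoc) < 0.1]
                a <- unique(c(anchor, extra))
                a <- a[seq_len(min(length(a), sizes[k] - 1))]
                fill <- sample(nullGenes, sizes[k] - length(a))
                members <- c(a, fill)
            } else {
                members <- sample(nullGenes, sizes[k])
            }
            nm <- sprintf("set%03d", k)
            sets[[k]] <- new("GeneSet", name = nm,
                             description = if (k %in% assocSetIdx) "associated" else "null",
                             genes = members)
        }
        names(sets) <- vapply(sets, function(s) s@name, character(1))
        list(sets = sets,
             associatedGenes = assocGenes,
             associatedSets = names(sets)[assocSetIdx],
             nullSets = names(sets)[-assocSetIdx])
    })
}

withSeed <- function(seed, expr) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(as.integer(seed))
    expr
}

repSeed <- function(seed, repIndex) {
    (as.integer(seed) + 1000003L * as.integer(repIndex)) %% 2147483647L
}

#' Generate one simulated dataset
#'
#' Draws one replicate of the configured study: the expression matrix
#' (subjects x genes), the endpoint, and the ground truth. The same
#' `(cfg, repIndex)` always yields a bit-identical dataset. Under
#' `association = "null"` every gene is iid N(0,1) independent of the
#' endpoint but the endpoint is still generated from its latent variable,
#' so null-configuration rejection rates estimate the empirical level.
#'
#' @param cfg a [SimulationConfig-class].
#' @param repIndex replicate number, 1-based.
#' @param membership optional precomputed [simulateCollection()] result
#'   (computed from `cfg` when omitted).
#' @return list with `expression`, `endpoint`, `truth` (latent `L`, sign
#'   flips `Z`, associated genes/sets), and `membership`.
#' @export
generateDataset <- function(cfg, repIndex = 1L, membership = NULL) {
    lay <- collectionLayout(cfg@collection)
    if (is.null(membership)) membership <- simulateCollection(cfg)
    nSubj <- if (cfg@endpoint == "categorical") 2L * cfg@n else cfg@n
    withSeed(repSeed(cfg@seed, repIndex), {
        L <- stats::rnorm(nSubj)
        X <- matrix(stats::rnorm(nSubj * lay$nGenes), nSubj, lay$nGenes,
                    dimnames = list(sprintf("s%04d", seq_len(nSubj)),
                                    sprintf("g%04d", seq_len(lay$nGenes))))
        Z <- NULL
        if (cfg@association != "null") {
            assocIdx <- match(membership$associatedGenes, colnames(X))
            coef <- matrix(cfg@beta, nSubj, length(assocIdx))
            if (cfg@association == "complex") {
                Z <- sample(c(-1, 1), nSubj, replace = TRUE)
                coef <- coef * Z
            }
            X[, assocIdx] <- coef * L +
                matrix(stats::rnorm(nSubj * length(assocIdx), sd = cfg@noiseSd),
                       nSubj, length(assocIdx))
        }
        ep <- switch(cfg@endpoint,
            quantitative = quantitativeEndpoint(L + stats::rnorm(nSubj),
                                                subjectIds = rownames(X)),
            categorical = {
                score <- L + stats::rnorm(nSubj)
                grp <- ifelse(rank(score, ties.method = "first") <= nSubj / 2,
                              "low", "high")
                categoricalEndpoint(grp, subjectIds = rownames(X))
            },
            survival = {
                rate <- exp(L)
                tEvent <- stats::rexp(nSubj, rate = rate)
                if (cfg@censorFrac > 0) {
                    cc <- censorBound(rate, cfg@censorFrac)
                    tCens <- stats::runif(nSubj, 0, cc)
                } else {
                    tCens <- rep(Inf, nSubj)
                }
                survivalEndpoint(pmin(tEvent, tCens),
                                 as.integer(tEvent <= tCens),
                                 subjectIds = rownames(X))
            })
        list(expression = X, endpoint = ep,
             truth = list(L = L, Z = Z,
                          associatedGenes = if (cfg@association == "null")
                              character() else membership$associatedGenes,
                          associatedSets = if (cfg@association == "null")
                              character() else membership$associatedSets),
             membership = membership)
    })
}

# Upper censoring bound c such that the mean over subjects of
# P(C < T | rate_i) = mean (1 - exp(-rate_i c)) / (rate_i c)
# equals the target fraction; decreasing in c, solved by uniroot.
censorBound <- function(rate, frac) {
    f <- function(cc) mean((1 - exp(-rate * cc)) / (rate * cc)) - frac
    stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-8)$root
}

#' Estimate empirical level and power over a gene-set collection
#'
#' Runs the full screen design: for each of `cfg@reps` replicates a dataset
#' is generated and the distance-correlation t-test applied to every gene
#' set; a set's rejection rate is the fraction of replicates with
#' `p_t < alpha`. The average rate over the layout's null sets (those
#' containing no associated genes) estimates the empirical level; the
#' average over the associated sets estimates power for non-null
#' configurations. A warning is issued when `reps` is too small for the Monte-Carlo
#' standard error of a rate near `alpha` to stay below `alpha / 2`.
#'
#' @param cfg a [SimulationConfig-class].
#' @param alpha nominal significance threshold (default 0.05).
#' @param collectPValues also return the full reps x sets p-value matrix.
#' @return list with `perSet` (data.frame: set, truth label, rejection
#'   rate), `level` (mean rate over null sets), `power` (mean over
#'   associated sets, `NA` for null configurations), `alpha`, `reps`, and
#'   optionally `pValues`.
#' @export
estimateLevelPower <- function(cfg, alpha = 0.05, collectPValues = FALSE) {
    mcse <- sqrt(alpha * (1 - alpha) / cfg@reps)
    if (mcse >= alpha / 2)
        warning("reps = ", cfg@reps, " gives Monte-Carlo SE ",
                signif(mcse, 3), " >= alpha/2; rates will be noisy")
    membership <- simulateCollection(cfg)
    setNames_ <- names(membership$sets)
    P <- matrix(NA_real_, cfg@reps, length(setNames_),
                dimnames = list(NULL, setNames_))
    for (r in seq_len(cfg@reps)) {
        dat <- generateDataset(cfg, r, membership)
        Yc <- uCenter(endpointDistance(dat$endpoint))
        n <- nrow(dat$expression)
        for (k in seq_along(membership$sets)) {
            sub <- dat$expression[, membership$sets[[k]]@genes, drop = FALSE]
            Xc <- uCenter(euclideanDistanceMatrix(sub))
            P[r, k] <- tryCatch(dCorTTest(dCor(Xc, Yc), n)@pT,
                                gsdistDegenerate = function(e) NA_real_)
        }
    }
    rate <- colMeans(P < alpha, na.rm = TRUE)
    # truth labels follow the collection layout; under a null configuration
    # the layout's "associated" sets carry no signal either, so the level is
    # averaged over the layout's null sets and power is undefined
    inAssocLayout <- setNames_ %in% membership$associatedSets
    truth <- ifelse(inAssocLayout & cfg@association != "null",
                    "associated", "null")
    perSet <- data.frame(set = setNames_, truth = truth,
                         rejectionRate = as.numeric(rate),
                         stringsAsFactors = FALSE)
    out <- list(perSet = perSet,
                level = mean(rate[!inAssocLayout]),
                power = if (any(truth == "associated"))
                    mean(rate[inAssocLayout]) else NA_real_,
                alpha = alpha, reps = cfg@reps)
    if (collectPValues) out$pValues <- P
    out
}

#' Two-gene differential-correlation example generator
#'
#' Generates the illustrative complex association: two genes whose
#' correlation is positive in one group and negative in the other, with
#' equal group means — invisible to per-gene location tests, visible to the
#' distance-correlation test. Gene 1 is `L + e1`; gene 2 is `Z * L + e2`
#' where `Z` is +1 in group 1 and -1 in group 2.
#'
#' @param nPerGroup subjects per group.
#' @param beta latent coefficient (default 1).
#' @param noiseSd residual standard deviation (default 0.5, matching the
#'   visibly X-shaped patterns the method is designed to catch).
#' @param seed integer seed.
#' @return list with `expression` (2 columns), `endpoint` (categorical),
#'   and `group`.
#' @export
simulateDifferentialCorrelation <- function(nPerGroup = 100, beta = 1,
                                            noiseSd = 0.5, seed = 1L) {
    withSeed(seed, {
        n <- 2L * as.integer(nPerGroup)
        grp <- rep(c("g1", "g2"), each = nPerGroup)
        Z <- ifelse(grp == "g1", 1, -1)
        L <- stats::rnorm(n)
        X <- cbind(gene1 = beta * L + stats::rnorm(n, sd = noiseSd),
                   gene2 = Z * beta * L + stats::rnorm(n, sd = noiseSd))
        rownames(X) <- sprintf("s%03d", seq_len(n))
        list(expression = X,
             endpoint = categoricalEndpoint(grp, subjectIds = rownames(X)),
             group = grp)
    })
}
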