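makeExpr <- function(n, genes, seed = 1) {
    set.seed(seed)
    matrix(rnorm(n * length(genes)), n, length(genes),
           dimnames = list(sprintf("s%02d", 1:n), genes))
}

test_that("a single gene identical to the endpoint gives perfect correlation", {
    set.seed(10)
    y <- rnorm(30)
    X <- cbind(gA = y, gB = rnorm(30))
    res <- gsdaTest(X, "gA", quantitativeEndpoint(y))
    expect_equal(res@rd, 1)
    expect_equal(res@pT, .Machine$double.xmin)  # clamped extreme
    expect_equal(res@nGenes, 1L)
})

test_that("gsdaTest for a quantitative endpoint equals the base two-matrix test", {
    set.seed(14)
    X <- makeExpr(25, paste0("g", 1:5), seed = 14)
    y <- rnorm(25)
    res <- gsdaTest(X, paste0("g", 1:5), quantitativeEndpoint(y))
    Xc <- uCenter(euclideanDistanceMatrix(X))
    Yc <- uCenter(euclideanDistanceMatrix(matrix(y, ncol = 1)))
    base <- dCorTTest(dCor(Xc, Yc), 25)
    expect_equal(res@rd, base@rd)
    expect_equal(res@td, base@td)
    expect_equal(res@pT, base@pT)
})

test_that("null gene sets give approximately uniform p-values", {
    set.seed(15)
    ps <- replicate(400, {
        X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
        gsdaTest(X, paste0("g", 1:4), quantitativeEndpoint(rnorm(50)))@pT
    })
    expect_gt(mean(ps), 0.4)
    expect_lt(mean(ps), 0.6)
    expect_gt(mean(ps < 0.25), 0.15)
})

test_that("gene matching is exact, warns below 50%, and errors on no match", {
    X <- makeExpr(10, c("gA", "gB", "gC"))
    ep <- quantitativeEndpoint(rnorm(10))
    expect_error(gsdaTest(X, c("nope1", "nope2"), ep), "no genes")
    expect_warning(gsdaTest(X, c("gA", "x1", "x2", "x3"), ep), "50%")
    expect_warning(gsdaTest(X, c("gA", "gA", "gB"), ep), "duplicate")
    # case sensitivity
    expect_error(suppressWarnings(gsdaTest(X, c("GA", "GB"), ep)), "no genes")
})

test_that("permutation p-value hits its lower bound when observed tops all replicates", {
    set.seed(16)
    y <- rnorm(40)
    X <- cbind(g1 = y + rnorm(40, sd = 0.05), g2 = y + rnorm(40, sd = 0.05))
    res <- gsdaTest(X, c("g1", "g2"), quantitativeEndpoint(y),
                    permutations = 199, seed = 5)
    expect_equal(res@pPerm, 1 / 200)
    expect_equal(res@nPerm, 199)
})

test_that("identity permutation ties with the observed statistic and is counted", {
    set.seed(18)
    X <- makeExpr(12, paste0("g", 1:3), seed = 18)
    Xc <- uCenter(euclideanDistanceMatrix(X))
    Yc <- uCenter(endpointDistance(quantitativeEndpoint(rnorm(12))))
    out <- permutationTest(Xc, Yc, B = 50, seed = 3)
    rObs <- dCor(Xc, Yc)
    # manually append an identity replicate: it must tie and enter the tally
    expect_equal(sum(c(out$rPerm, rObs) >= rObs), sum(out$rPerm >= rObs) + 1)
    expect_error(permutationTest(Xc, Yc, B = 0), "positive")
})

test_that("permutation results are reproducible for a fixed seed", {
    set.seed(19)
    X <- makeExpr(20, paste0("g", 1:4), seed = 19)
    ep <- quantitativeEndpoint(rnorm(20))
    a <- gsdaTest(X, paste0("g", 1:4), ep, permutations = 100, seed = 7)
    b <- gsdaTest(X, paste0("g", 1:4), ep, permutations = 100, seed = 7)
    expect_identical(a@pPerm, b@pPerm)
})

test_that("U-centering commutes with simultaneous row/column permutation", {
    set.seed(20)
    for (rep in 1:20) {
        n <- sample(4:15, 1)
        A <- randomDistanceMatrix(n)
        p <- sample(n)
        expect_equal(uCenter(A[p, p])@.Data, uCenter(A)@.Data[p, p],
                     tolerance = 1e-12)
    }
})

test_that("jointly permuting subjects of X and Y leaves the correlation unchanged", {
    set.seed(22)
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
    p <- sample(15)
    r1 <- dCor(uCenter(euclideanDistanceMatrix(X)),
               uCenter(euclideanDistanceMatrix(matrix(y, ncol = 1))))
    r2 <- dCor(uCenter(euclideanDistanceMatrix(X[p, ])),
               uCenter(euclideanDistanceMatrix(matrix(y[p], ncol = 1))))
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("screen reports every set, flags degenerate ones, and orders by p", {
    set.seed(23)
    n <- 40
    y <- rnorm(n)
    X <- cbind(makeExpr(n, paste0("null", 1:6), seed = 23),
               hitA = y + rnorm(n, sd = 0.3),
               hitB = y + rnorm(n, sd = 0.3),
               flat = rep(1, n))
    coll <- list(planted = c("hitA", "hitB"),
                 nullset = paste0("null", 1:3),
                 broken = c("flat"),
                 unmatched = c("zz1", "zz2"))
    scr <- gsdaScreen(X, coll, quantitativeEndpoint(y),
                      permutations = 99, seed = 11)
    tab <- resultsTable(scr)
    expect_equal(nrow(tab), 4)
    expect_equal(tab$set[1], "planted")      # smallest p first
    expect_equal(tab$status[tab$set == "broken"], "degenerate")
    expect_match(tab$status[tab$set == "unmatched"], "no genes")
    expect_true(is.na(tab$q[tab$set == "broken"]))
    # permutation follow-up triggered exactly for sets at or below alpha
    expect_false(is.na(tab$pPerm[tab$set == "planted"]))
    ok <- tab$status == "ok"
    expect_equal(!is.na(tab$pPerm[ok]), tab$pT[ok] <= scr@alpha)
})

test_that("screen q-values reproduce textbook Benjamini-Hochberg arithmetic", {
    # p-values engineered: the BH identity on (0.01, 0.02, 0.5) is (0.03, 0.03, 0.5)
    expect_equal(p.adjust(c(0.01, 0.02, 0.5), method = "BH"),
                 c(0.03, 0.03, 0.5))
    set.seed(24)
    n <- 30
    X <- makeExpr(n, paste0("g", 1:9), seed = 24)
    coll <- list(s1 = paste0("g", 1:3), s2 = paste0("g", 4:6),
                 s3 = paste0("g", 7:9))
    scr <- gsdaScreen(X, coll, quantitativeEndpoint(rnorm(n)))
    tab <- resultsTable(scr)
    expect_equal(tab$q, p.adjust(tab$pT, method = "BH"))
})

test_that("screen results are reproducible and order-independent given a seed", {
    set.seed(25)
    n <- 40
    y <- rnorm(n)
    X <- cbind(a1 = y + rnorm(n, sd = 0.2), a2 = y + rnorm(n, sd = 0.2),
               b1 = y + rnorm(n, sd = 0.2), b2 = y + rnorm(n, sd = 0.2))
    collA <- list(sa = c("a1", "a2"), sb = c("b1", "b2"))
    collB <- rev(collA)
    s1 <- resultsTable(gsdaScreen(X, collA, quantitativeEndpoint(y),
                                  permutations = 99, seed = 4))
    s2 <- resultsTable(gsdaScreen(X, collB, quantitativeEndpoint(y),
                                  permutations = 99, seed = 4))
    expect_equal(s1$pPerm[match(c("sa", "sb"), s1$set)],
                 s2$pPerm[match(c("sa", "sb"), s2$set)])
})

test_that("a planted associated set attains the smallest screen p-value", {
    set.seed(26)
    wins <- replicate(20, {
        n <- 100
        y <- rnorm(n)
        X <- matrix(rnorm(n * 27), n, 27,
                    dimnames = list(NULL, paste0("g", 1:27)))
        X[, 1:3] <- y + matrix(rnorm(n * 3), n, 3)
        coll <- c(list(planted = paste0("g", 1:3)),
                  setNames(lapply(1:9, function(k) paste0("g", 3 * k + 1:3)),
                           paste0("null", 1:9)))
        tab <- resultsTable(gsdaScreen(X, coll, quantitativeEndpoint(y)))
        tab$set[1] == "planted"
    })
    expect_gt(mean(wins), 0.8)
})
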