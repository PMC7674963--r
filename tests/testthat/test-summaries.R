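test_that("variance trajectories evaluate z'Gz exactly", {
    b <- legendreBasis(3)
    G <- matrix(0, 4, 4); G[1, 1] <- 2          # only the constant term
    P <- diag(c(2, 1, 1, 1))
    comp <- VarianceComponents(G + diag(1e-10, 4), P, 1)
    tr <- varianceTrajectory(comp, basis = b)
    expect_equal(tr$Vg, rep(1, 301), tolerance = 1e-6)   # z0^2 = 1/2
    # h2 and repeatability are plain variance ratios
    i <- which(tr$dim == 155)
    expect_equal(tr$h2[i], tr$Vg[i] / (tr$Vg[i] + tr$Vpe[i] + tr$Ve[i]))
    expect_equal(tr$rep[i],
                 (tr$Vg[i] + tr$Vpe[i]) / (tr$Vg[i] + tr$Vpe[i] + tr$Ve[i]))

    # quadratic identity: z'Gz equals the explicit double sum
    set.seed(31)
    A <- crossprod(matrix(rnorm(16), 4))
    comp2 <- VarianceComponents(A, P, 1)
    tr2 <- varianceTrajectory(comp2, basis = b)
    Zm <- basisMatrix(b)
    for (d in c(5L, 100L, 305L)) {
        z <- Zm[as.character(d), ]
        manual <- sum(outer(z, z) * A)
        expect_equal(tr2$Vg[tr2$dim == d], manual, tolerance = 1e-12)
    }
})

test_that("identity G gives edge-maximal genetic variance", {
    b <- legendreBasis(3)
    comp <- VarianceComponents(diag(4), diag(4), 1)
    tr <- varianceTrajectory(comp, basis = b)
    expect_equal(max(tr$Vg), tr$Vg[1L])
    expect_equal(tr$Vg[301L], tr$Vg[1L], tolerance = 1e-10)
    z <- basisMatrix(b)["155", ]
    expect_equal(tr$Vg[tr$dim == 155], sum(z^2), tolerance = 1e-12)
})

test_that("h2(t) <= rep(t) < 1 whenever residual variance is positive", {
    set.seed(33)
    b <- legendreBasis(2)
    for (i in 1:20) {
        G <- crossprod(matrix(rnorm(9), 3)) + diag(0.1, 3)
        P <- crossprod(matrix(rnorm(9), 3)) + diag(0.1, 3)
        tr <- varianceTrajectory(VarianceComponents(G, P, runif(1, 1, 20)),
                                 basis = b)
        expect_true(all(tr$h2 <= tr$rep))
        expect_true(all(tr$rep < 1))
        expect_true(all(tr$Vg >= 0 & tr$Vpe >= 0))
    }
})

test_that("305-day aggregation uses the summed covariate vector", {
    b <- legendreBasis(3)
    u0 <- 301 / sqrt(2)
    expect_equal(ebv305(c(1, 0, 0, 0), basis = b), u0, tolerance = 1e-10)
    expect_equal(u0, 212.8391, tolerance = 1e-6)
    expect_equal(ebv305(c(0, 0, 0, 0), basis = b), 0)
    # linearity
    set.seed(35)
    a1 <- rnorm(4); a2 <- rnorm(4)
    expect_equal(ebv305(a1 + a2, basis = b),
                 ebv305(a1, basis = b) + ebv305(a2, basis = b),
                 tolerance = 1e-10)
    # equals the brute-force sum of 301 daily values
    Zm <- basisMatrix(b)
    expect_equal(ebv305(a1, basis = b), sum(Zm %*% a1), tolerance = 1e-9)
    # matrix method labels animals
    m <- rbind(x = a1, y = a2)
    e <- ebv305(m, basis = b)
    expect_named(e, c("x", "y"))
    expect_equal(unname(e["x"]), ebv305(a1, basis = b))
})

test_that("305-day heritability follows the variance-of-the-sum definition", {
    b <- legendreBasis(2)
    g <- 3
    G <- diag(c(g, 1e-12, 1e-12))
    P <- diag(c(2, 1e-12, 1e-12))
    comp <- VarianceComponents(G + diag(1e-12, 3), P + diag(1e-12, 3), 1e-8)
    u <- colSums(basisMatrix(b))
    h <- lactationH2(comp, basis = b)
    expect_equal(unname(h["h2"]), unname(u[1L]^2 * g / (u[1L]^2 * (g + 2))),
                 tolerance = 1e-4)
    # u' G u with only the constant term is (301 / sqrt(2))^2 g
    expect_equal(unname(u[1L]^2 * g), (301 / sqrt(2))^2 * g)
    # with pe and residual at zero h2 = 1
    h1 <- lactationH2(VarianceComponents(diag(3), diag(1e-14, 3), 1e-14),
                      basis = b)
    expect_equal(unname(h1["h2"]), 1, tolerance = 1e-6)
    # scale invariance
    comp2 <- VarianceComponents(5 * diag(c(2, 1, 1)), 5 * diag(c(3, 1, 1)),
                                5 * 7)
    comp1 <- VarianceComponents(diag(c(2, 1, 1)), diag(c(3, 1, 1)), 7)
    expect_equal(lactationH2(comp2, basis = b), lactationH2(comp1, basis = b),
                 tolerance = 1e-10)
})

test_that("covariance-parameter counts follow the triangular-number rule", {
    nA <- vapply(1:5, function(k) countParameters(k)$nA, numeric(1))
    expect_equal(nA, c(3, 6, 10, 15, 21))
    expect_equal(vapply(1:5, function(k) countParameters(k)$nPE, numeric(1)),
                 c(3, 6, 10, 15, 21))
    expect_identical(countParameters(1)$p, 7)
    expect_identical(countParameters(5)$p, 43)
    expect_identical(countParameters(3, residual = "heterogeneous")$nR, 10L)
    expect_identical(countParameters(rrModelSpec(3))$nA, 10)
})

test_that("AIC and BIC use the printed formulas with natural logs", {
    fitStub <- new("RRMFit", spec = rrModelSpec(1),
                   components = defaultTrueComponents(1, "homogeneous"),
                   fixed = data.frame(), a = matrix(0, 1, 2),
                   pe = matrix(0, 1, 2), logLik = -100, nIter = 1L,
                   converged = TRUE, rankX = 24L, nRecords = 1024L,
                   residuals = numeric(0), residualClass = integer(0),
                   edfModel = 0, vClassTable = data.frame(),
                   history = data.frame())
    sc <- modelScores(fitStub)
    expect_equal(sc$minus2logL, 200)
    expect_equal(sc$AIC, 200 + 2 * 7)
    expect_equal(sc$n, 1000)
    expect_equal(sc$BIC, 200 + 7 * log(1000))
    expect_equal(sc$BIC, 248.357, tolerance = 1e-3)
    sc2 <- modelScores(fitStub, includeFixed = TRUE)
    expect_equal(sc2$p, 7 + 24)
})
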