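test_that("design rows carry the Legendre covariates of the record's DIM", {
    sim <- tinyHerd(seed = 2L)
    spec <- rrModelSpec(1)
    design <- buildDesign(sim$records, sim$pedigree, spec)
    df <- records(sim$records)
    i <- 1L
    z <- basisVector(spec@basis, df$dim[i])
    aPos <- match(df$cow_id[i], design@animals)
    row <- design@Za[i, (aPos - 1L) * 2L + 1:2]
    expect_equal(as.numeric(row), z, tolerance = 1e-12)
    expect_equal(z[1L], 1 / sqrt(2), tolerance = 1e-12)
    # two records of one cow share the pe block with different covariates
    cid <- df$cow_id[i]
    rows <- which(df$cow_id == cid)[1:2]
    cPos <- match(cid, design@cows)
    zp <- as.matrix(design@Zp[rows, (cPos - 1L) * 2L + 1:2])
    expect_false(all(zp[1L, ] == zp[2L, ]))
    expect_equal(zp[, 1L], rep(1 / sqrt(2), 2L), tolerance = 1e-12)
})

test_that("records of cows missing from the pedigree are rejected", {
    sim <- tinyHerd(seed = 2L)
    df <- records(sim$records)
    df$cow_id[1L] <- "GHOST"
    tdd <- classifyRecords(testDayData(df))
    expect_error(buildDesign(tdd, sim$pedigree, rrModelSpec(1)), "GHOST")
})

test_that("rank detection drops confounded indicator columns", {
    expect_identical(designRank(matrix(1, 10, 1)), 1L)
    # two effects with full dummies: one confounding
    h <- rep(1:2, each = 4L)
    a <- rep(1:2, 4L)
    X <- cbind(h == 1, h == 2, a == 1, a == 2) * 1
    expect_identical(designRank(X), 3L)
    expect_identical(designRank(cbind(X, X[, 1L])), 3L)
    sim <- tinyHerd(seed = 2L)
    design <- buildDesign(sim$records, sim$pedigree, rrModelSpec(1))
    expect_identical(rankFixedEffects(design), ncol(design@X))
    # at least the last age and last DIM level are constrained out
    expect_true(any(design@dropped$effect == "age"))
    expect_true(any(design@dropped$effect == "dim"))
})

test_that("MME solutions equal dense GLS/BLUP on random tiny instances", {
    set.seed(123)
    nOk <- 0L
    for (rep in 1:25) {
        ord <- sample(1:2, 1L)
        sim <- tinyHerd(seed = 1000L + rep, nCows = sample(4:6, 1L),
                        nSires = 2L, nDams = 6L, order = ord, nHerds = 1L,
                        years = 2012L)
        spec <- rrModelSpec(ord)
        design <- buildDesign(sim$records, sim$pedigree, spec)
        G <- defaultTrueComponents(ord, "homogeneous")@G
        P <- defaultTrueComponents(ord, "homogeneous")@P
        v <- 10 + rep %% 5
        mme <- assembleMME(design, G, P, v, makeAInverse(sim$pedigree))
        sol <- solveMME(mme, design)
        oracle <- denseOracle(design, sim$pedigree, G, P, v)
        expect_lt(max(abs(sol$solution[mme$blocks$fixed] - oracle$beta)), 1e-6)
        expect_lt(max(abs(sol$solution[mme$blocks$a] - oracle$a)), 1e-6)
        expect_lt(max(abs(sol$solution[mme$blocks$pe] - oracle$pe)), 1e-6)
        nOk <- nOk + 1L
    }
    expect_identical(nOk, 25L)
})

test_that("solutions are invariant to record order and to scaling G, P, v", {
    sim <- tinyHerd(seed = 4L, nCows = 8L)
    spec <- rrModelSpec(1)
    design <- buildDesign(sim$records, sim$pedigree, spec)
    ainv <- makeAInverse(sim$pedigree)
    G <- defaultTrueComponents(1, "homogeneous")@G
    P <- defaultTrueComponents(1, "homogeneous")@P
    s1 <- solveMME(assembleMME(design, G, P, 12, ainv), design)
    s2 <- solveMME(assembleMME(design, 2 * G, 2 * P, 24, ainv), design)
    expect_equal(s1$solution, s2$solution, tolerance = 1e-9)

    df <- records(sim$records)
    perm <- sample(nrow(df))
    tddP <- classifyRecords(testDayData(df[perm, ]))
    dP <- buildDesign(tddP, sim$pedigree, spec)
    sP <- solveMME(assembleMME(dP, G, P, 12, makeAInverse(sim$pedigree)), dP)
    expect_equal(sP$a, s1$a, tolerance = 1e-9)

    # zero response gives zero random-effect solutions
    df0 <- records(sim$records)
    df0$milk_kg <- 0
    d0 <- buildDesign(classifyRecords(testDayData(df0)), sim$pedigree, spec)
    s0 <- solveMME(assembleMME(d0, G, P, 12, ainv), d0)
    expect_lt(max(abs(s0$a)), 1e-10)
    expect_lt(max(abs(s0$pe)), 1e-10)
})

test_that("random-effect solutions shrink to zero as G and P vanish", {
    sim <- tinyHerd(seed = 6L, nCows = 8L)
    design <- buildDesign(sim$records, sim$pedigree, rrModelSpec(1))
    ainv <- makeAInverse(sim$pedigree)
    G <- defaultTrueComponents(1, "homogeneous")@G
    P <- defaultTrueComponents(1, "homogeneous")@P
    sizes <- vapply(c(1, 1e-2, 1e-4, 1e-6), function(eps) {
        s <- solveMME(assembleMME(design, eps * G, eps * P, 12, ainv), design)
        max(abs(c(s$a, s$pe)))
    }, numeric(1))
    expect_true(all(diff(sizes) < 0))
    expect_lt(sizes[4L], 1e-4)
})

test_that("iterative and direct solvers agree", {
    sim <- tinyHerd(seed = 8L, nCows = 10L)
    design <- buildDesign(sim$records, sim$pedigree, rrModelSpec(1))
    mme <- assembleMME(design, defaultTrueComponents(1, "homogeneous")@G,
                       defaultTrueComponents(1, "homogeneous")@P, 12,
                       makeAInverse(sim$pedigree))
    sd <- solveMME(mme, design, method = "direct")
    si <- solveMME(mme, design, method = "iterative", tol = 1e-12)
    expect_equal(si$solution, sd$solution, tolerance = 1e-6)
})

test_that("assembly rejects invalid components", {
    sim <- tinyHerd(seed = 2L)
    design <- buildDesign(sim$records, sim$pedigree, rrModelSpec(1))
    ainv <- makeAInverse(sim$pedigree)
    Gbad <- matrix(c(1, 2, 2, 1), 2)       # indefinite
    P <- defaultTrueComponents(1, "homogeneous")@P
    expect_error(assembleMME(design, Gbad, P, 10, ainv), "G")
    expect_error(assembleMME(design, P[1:2, 1:2], Gbad, 10, ainv), "P")
    expect_error(assembleMME(design, P[1:2, 1:2], P[1:2, 1:2], -1, ainv),
                 "positive")
})
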