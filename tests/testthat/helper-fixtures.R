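# Shared fixtures: tiny herds and dense oracles used across tests.

# small simulated herd; defaults give ~20 cows / ~170 records in < 1 s
tinyHerd <- function(seed = 1L, nCows = 20L, order = 1L, nSires = 4L,
                     nDams = 25L, nHerds = 2L, years = 2012:2013,
                     residual = "homogeneous", nGenerations = 1L) {
    cfg <- simConfig(nSires = nSires, nDams = nDams,
                     nGenerations = nGenerations, nCows = nCows,
                     nHerds = nHerds, years = years, order = order,
                     components = defaultTrueComponents(order, residual),
                     seed = seed)
    sim <- simulateHerd(cfg)
    sim$records <- classifyRecords(applyFilters(sim$records))
    sim$config <- cfg
    sim
}

# random pedigree with nAnimal rows: founders plus random valid matings
randomPedigree <- function(nAnimals, pFounder = 0.3) {
    animal <- sprintf("A%03d", seq_len(nAnimals))
    sire <- dam <- rep(NA_character_, nAnimals)
    for (i in seq_len(nAnimals)) {
        if (i >= 3L && runif(1) > pFounder) {
            pick <- sample(i - 1L, 2L)
            sire[i] <- animal[pick[1L]]
            dam[i] <- animal[pick[2L]]
        }
    }
    sortPedigree(pedigree(animal, sire, dam))
}

# dense GLS/BLUP oracle for a built design at given components
denseOracle <- function(design, ped, G, P, v) {
    A <- makeA(ped)
    nc <- length(design@cows)
    Za <- as.matrix(design@Za)
    Zp <- as.matrix(design@Zp)
    X <- as.matrix(design@X)
    y <- design@y
    n <- length(y)
    Sa <- kronecker(A, G)
    Sp <- kronecker(diag(nc), P)
    V <- Za %*% Sa %*% t(Za) + Zp %*% Sp %*% t(Zp) + diag(v, n)
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    beta <- solve(XtVi %*% X, XtVi %*% y)
    Py <- Vi %*% (y - X %*% beta)
    list(beta = as.numeric(beta),
         a = as.numeric(Sa %*% t(Za) %*% Py),
         pe = as.numeric(Sp %*% t(Zp) %*% Py),
         logL = -0.5 * as.numeric((n - ncol(X)) * log(2 * pi) +
             determinant(V)$modulus + determinant(XtVi %*% X)$modulus +
             t(y) %*% Py))
}

# raw records data.frame for parser/filter tests
rawRecords <- function() {
    data.frame(
        cow_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c3", "c3"),
        herd_id = "h1",
        calving_date = "2012-03-10",
        test_date = as.character(as.Date("2012-03-10") +
                                 c(10, 40, 70, 15, 45, 75, 20, 50)),
        milk_kg = c(25, 28, 26, 22, 4, 24, 30, 29),
        age_at_calving_months = c(25, 25, 25, 30, 30, 30, 19, 19),
        stringsAsFactors = FALSE)
}
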