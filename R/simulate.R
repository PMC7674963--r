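# Synthetic herd generator: the generative counterpart of the test-day
# model.  Pedigree by discrete-generation random mating, regression
# coefficients drawn with the exact pedigree covariance (Mendelian-sampling
# recursion), and records built as mean curve + herd-year-season + age
# effects + z'a + z'pe + class-specific residual.

#' Reference residual-variance estimates by DIM class
#'
#' Published REML estimates of the residual variance (kg^2) in the ten DIM
#' classes for first-lactation Chinese Holstein cows, one column per
#' Legendre order (LP1..LP5) of the heterogeneous-residual test-day model,
#' together with the published per-column means ("total" row).  The LP3
#' column is the default residual shape of the simulator (elevated in early
#' lactation).
#'
#' @return list with `classes` (data.frame: `from`, `to`, `lp1`..`lp5`) and
#'   `total` (named numeric of the published column means).
#' @export
referenceResidualVariances <- function() {
    path <- system.file("extdata", "residual_variance_reference.csv",
                        package = "milkRRM", mustWork = TRUE)
    tab <- read.csv(path)
    list(classes = tab[tab$from != -1, ],
         total = unlist(tab[tab$from == -1, paste0("lp", 1:5)]))
}

#' True covariance components used by the simulator
#'
#' Diagonal-dominant G and P on a Legendre basis of the given order, with a
#' negative intercept-slope genetic covariance, scaled so that the daily
#' heritability is about 0.25 and the daily repeatability about 0.7 across
#' the lactation; the residual follows the reference DIM-class pattern
#' (see [referenceResidualVariances()]).
#'
#' @param order Legendre order of the true covariance functions (1..5).
#' @param residual `"heterogeneous"` (default: the ten-class reference
#'   pattern) or `"homogeneous"` (its mean).
#' @return a [VarianceComponents-class].
#' @export
defaultTrueComponents <- function(order = 3L,
                                  residual = c("heterogeneous", "homogeneous")) {
    residual <- match.arg(residual)
    r <- order + 1L
    G <- diag(c(18, 4, 2.5, 1.5, 1.0, 0.7)[seq_len(r)], r)
    G[1L, 2L] <- G[2L, 1L] <- -2
    P <- diag(c(36, 8, 5, 3, 2, 1.5)[seq_len(r)], r)
    P[1L, 2L] <- P[2L, 1L] <- -4
    vref <- referenceResidualVariances()$classes$lp3
    v <- if (residual == "heterogeneous") vref else mean(vref)
    VarianceComponents(G = G, P = P, residual = v)
}

#' Configure the synthetic herd
#'
#' Defaults emulate a regional first-lactation Holstein data set at desk
#' scale: 2,000 recorded cows in 10 herds over 5 calving years in two
#' cohorts (daughters of 100 artificial-insemination sires; later-cohort
#' cows have recorded dams), roughly monthly tests (about 8 per cow, so
#' about 16,000 records), a Wilmink-type lactation mean curve peaking near
#' 26 kg, and true covariance functions from [defaultTrueComponents()].
#'
#' @param nSires,nDams male/female count per founder and intermediate
#'   generation.
#' @param nGenerations descendant generations (last = recorded cows).
#' @param nCows recorded cows.
#' @param nHerds number of herds; `years` calving years.
#' @param seasonWeights monthly calving probabilities (length 12).
#' @param order Legendre order of the true covariance functions.
#' @param components optional [VarianceComponents-class] overriding
#'   [defaultTrueComponents()].
#' @param meanCurve function DIM -> mean daily yield (kg).
#' @param hysSD standard deviation of herd-year-season effects (kg).
#' @param ageEffects fixed effects of the four age classes (kg).
#' @param testInterval mean days between tests; `missRate` probability a
#'   scheduled test is skipped.
#' @param dimMin,dimMax basis range.
#' @param seed integer seed used by [simulateHerd()].
#' @return a [HerdSimConfig-class].
#' @export
simConfig <- function(nSires = 100L, nDams = 1000L, nGenerations = 2L,
                      nCows = 2000L, nHerds = 10L, years = 2010:2014,
                      seasonWeights = rep(1 / 12, 12L),
                      order = 3L, components = NULL,
                      meanCurve = function(dim)
                          27.8 - 8 * exp(-0.05 * dim) - 0.02 * dim,
                      hysSD = 2, ageEffects = c(-1.2, -0.3, 0.4, 1.1),
                      testInterval = 30L, missRate = 0.1,
                      dimMin = 5L, dimMax = 305L, seed = 20260101L) {
    if (is.null(components)) components <- defaultTrueComponents(order)
    order <- ncol(components@G) - 1L
    new("HerdSimConfig", nSires = as.integer(nSires), nDams = as.integer(nDams),
        nGenerations = as.integer(nGenerations), nCows = as.integer(nCows),
        nHerds = as.integer(nHerds), years = as.integer(years),
        seasonWeights = seasonWeights,
        trueG = components@G, trueP = components@P,
        trueResidual = components@residual,
        meanCurve = meanCurve, hysSD = hysSD, ageEffects = ageEffects,
        testInterval = as.integer(testInterval), missRate = missRate,
        basis = legendreBasis(order, dimMin, dimMax),
        seed = as.integer(seed))
}

setMethod("show", "HerdSimConfig", function(object) {
    cat(sprintf("HerdSimConfig: %d cows, %d herds, years %d-%d, LP%d truth, seed %d\n",
                object@nCows, object@nHerds, min(object@years),
                max(object@years), object@basis@order, object@seed))
})

#' Simulate a random-mating pedigree
#'
#' Discrete generations without selection.  Founders are `nSires` males and
#' `nDams` females with unknown parents.  Each descendant generation g
#' consists of `nSires` young males plus `nCows / nGenerations` females --
#' the recorded cows, ids prefixed `"COW<g>_"` -- with sires drawn uniformly
#' from the previous generation's males and dams assigned round-robin from
#' the previous generation's females (so later-cohort cows have recorded
#' dams, as in multi-cohort test-day data).  Call inside [simulateHerd()] or
#' after setting a seed.
#'
#' @param config a [HerdSimConfig-class].
#' @return a [Pedigree-class] already in parents-first order.
#' @export
simulatePedigree <- function(config) {
    males <- sprintf("F_S%03d", seq_len(config@nSires))
    females <- sprintf("F_D%04d", seq_len(config@nDams))
    animal <- c(males, females)
    sire <- dam <- rep(NA_character_, length(animal))
    perGen <- ceiling(config@nCows / config@nGenerations)
    for (g in seq_len(config@nGenerations)) {
        nF <- if (g == config@nGenerations)
            config@nCows - perGen * (config@nGenerations - 1L) else perGen
        ids <- c(sprintf("G%d_S%03d", g, seq_len(config@nSires)),
                 sprintf("COW%d_%04d", g, seq_len(nF)))
        nOff <- length(ids)
        s <- sample(males, nOff, replace = TRUE)
        d <- sample(rep_len(sample(females), nOff))
        animal <- c(animal, ids)
        sire <- c(sire, s)
        dam <- c(dam, d)
        males <- ids[seq_len(config@nSires)]
        females <- ids[config@nSires + seq_len(nF)]
    }
    pedigree(animal, sire, dam)
}

#' Simulate genetic regression coefficients over a pedigree
#'
#' Founders draw `a ~ N(0, G)`; non-founders take the parent average plus a
#' Mendelian-sampling deviation `m ~ N(0, d_i G)` with
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F with one unknown parent, 1
#' with both unknown), which reproduces the `A (x) G` covariance exactly.
#'
#' @param ped a [SortedPedigree-class].
#' @param G true coefficient covariance matrix.
#' @return matrix (animals x coefficients), rownames = animal ids.
#' @export
simulateGeneticCoefficients <- function(ped, G) {
    n <- length(ped@animal)
    r <- ncol(G)
    cholG <- chol(G)
    Fv <- ped@inbreeding
    si <- ped@sireIdx
    di <- ped@damIdx
    a <- matrix(rnorm(n * r), n, r) %*% cholG   # scaled per animal below
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        if (is.na(s) && is.na(d)) next           # founder: N(0, G) as drawn
        mp <- (if (is.na(s)) 0 else a[s, ] / 2) +
              (if (is.na(d)) 0 else a[d, ] / 2)
        dd <- if (is.na(s)) 0.75 - 0.25 * Fv[d] else
              if (is.na(d)) 0.75 - 0.25 * Fv[s] else
              0.5 - 0.25 * (Fv[s] + Fv[d])
        a[i, ] <- mp + sqrt(dd) * a[i, ]
    }
    rownames(a) <- ped@animal
    a
}

# record-level simulation given coefficients; returns TestDayData + truth
.simulateRecords <- function(ped, aMat, config) {
    cows <- grep("^COW", ped@animal, value = TRUE)
    nc <- length(cows)
    r <- config@basis@order + 1L
    pe <- matrix(rnorm(nc * r), nc, r) %*% chol(config@trueP)
    rownames(pe) <- cows
    herd <- sample(config@nHerds, nc, replace = TRUE)
    # calving years by cohort: generation g calves in the g-th block of the
    # year range, so dams calve before their daughters
    gen <- as.integer(sub("^COW(\\d+)_.*", "\\1", cows))
    nGen <- max(gen)
    yearBlock <- if (nGen == 1L) list(config@years) else
        split(config@years, cut(seq_along(config@years), nGen, labels = FALSE))
    year <- vapply(gen, function(g) {
        blk <- yearBlock[[min(g, length(yearBlock))]]
        blk[sample.int(length(blk), 1L)]
    }, integer(1))
    month <- sample(12L, nc, replace = TRUE, prob = config@seasonWeights)
    day <- sample(28L, nc, replace = TRUE)
    age <- sample(21:36, nc, replace = TRUE)
    hysEff <- rnorm(config@nHerds * length(config@years) * 3L, sd = config@hysSD)
    dim(hysEff) <- c(config@nHerds, length(config@years), 3L)
    bounds <- dimClassBounds()
    vClass <- if (length(config@trueResidual) == 1L)
        rep(config@trueResidual, nrow(bounds)) else config@trueResidual
    rows <- vector("list", nc)
    nTrunc <- 0L
    for (c in seq_len(nc)) {
        dims <- config@basis@dimMin - 1L + sample(5:35, 1L)
        while (TRUE) {
            nxt <- dims[length(dims)] + config@testInterval + sample(-3:3, 1L)
            if (nxt > config@basis@dimMax) break
            dims <- c(dims, nxt)
        }
        dims <- dims[runif(length(dims)) > config@missRate]
        if (!length(dims)) next
        z <- basisVector(config@basis, dims)
        if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
        cls <- assignResidualClass(dims, bounds)
        season <- calvingSeason(month[c])
        y <- config@meanCurve(dims) +
            hysEff[herd[c], match(year[c], config@years), season] +
            config@ageEffects[assignAgeClass(age[c])] +
            as.numeric(z %*% aMat[cows[c], ]) +
            as.numeric(z %*% pe[c, ]) +
            rnorm(length(dims), sd = sqrt(vClass[cls]))
        keep <- y >= 5 & y <= 80
        nTrunc <- nTrunc + sum(!keep)
        if (!any(keep)) next
        cd <- as.Date(sprintf("%d-%02d-%02d", year[c], month[c], day[c]))
        rows[[c]] <- data.frame(
            cow_id = cows[c], herd_id = sprintf("H%02d", herd[c]),
            calving_date = cd, test_date = cd + dims[keep],
            dim = dims[keep], milk_kg = round(y[keep], 1),
            age_at_calving_months = age[c], stringsAsFactors = FALSE)
    }
    tdd <- testDayData(do.call(rbind, rows))
    attr(tdd, "truncated") <- nTrunc
    list(records = tdd, pe = pe)
}

#' Simulate a complete herd data set
#'
#' Runs [simulatePedigree()], [simulateGeneticCoefficients()] and the
#' record generator under the configured seed.
#'
#' @param config a [HerdSimConfig-class].
#' @return list with `pedigree` (a [SortedPedigree-class]), `records` (a
#'   [TestDayData-class]), and `truth` (list: `components`, the coefficient
#'   matrices `a` and `pe`, and `ebv305`, the true 305-day breeding values
#'   computed with the same basis code as the estimator).
#' @export
simulateHerd <- function(config) {
    set.seed(config@seed)
    ped <- sortPedigree(simulatePedigree(config))
    aMat <- simulateGeneticCoefficients(ped, config@trueG)
    sim <- .simulateRecords(ped, aMat, config)
    truth <- list(components = VarianceComponents(config@trueG, config@trueP,
                                                  config@trueResidual),
                  a = aMat, pe = sim$pe,
                  ebv305 = ebv305(aMat, basis = config@basis))
    list(pedigree = ped, records = sim$records, truth = truth,
         truncated = attr(sim$records, "truncated"))
}

#' Write a simulated data set to disk
#'
#' Writes `pedigree.csv`, `records.csv` and truth files (`truth_G.csv`,
#' `truth_P.csv`, `truth_residual.csv`, `truth_ebv305.csv`) into `dir`.
#'
#' @param config a [HerdSimConfig-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the list from [simulateHerd()] with a `files` element.
#' @export
generateDataset <- function(config, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- simulateHerd(config)
    files <- c(pedigree = file.path(dir, "pedigree.csv"),
               records = file.path(dir, "records.csv"),
               G = file.path(dir, "truth_G.csv"),
               P = file.path(dir, "truth_P.csv"),
               residual = file.path(dir, "truth_residual.csv"),
               ebv = file.path(dir, "truth_ebv305.csv"))
    writePedigree(sim$pedigree, files["pedigree"])
    writeTestDayRecords(sim$records, files["records"])
    write.csv(as.data.frame(sim$truth$components@G), files["G"], row.names = FALSE)
    write.csv(as.data.frame(sim$truth$components@P), files["P"], row.names = FALSE)
    write.csv(data.frame(class = seq_along(sim$truth$components@residual),
                         v = sim$truth$components@residual),
              files["residual"], row.names = FALSE)
    write.csv(data.frame(animal = names(sim$truth$ebv305),
                         ebv305 = as.numeric(sim$truth$ebv305)),
              files["ebv"], row.names = FALSE)
    sim$files <- files
    invisible(sim)
}
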