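#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal Cholesky crossprod t diag
#'   forceSymmetric solve update bdiag writeMM invPerm
#' @importMethodsFrom Matrix determinant
#' @importFrom stats rnorm runif var cor sd setNames optim
#' @importFrom utils read.csv write.csv head
#' @useDynLib milkRRM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("DateOrNULL", c("Date", "NULL"))

#' Pedigree of animals with sire and dam links
#'
#' Holds one row per animal with its sire and dam identifiers.  Unknown
#' parents are stored as `NA`.  A `Pedigree` makes no ordering guarantee;
#' [sortPedigree()] produces a [SortedPedigree-class] with parents before
#' offspring and per-animal inbreeding coefficients.
#'
#' @slot animal character vector of unique animal identifiers.
#' @slot sire,dam character vectors of parent identifiers (`NA` = unknown).
#' @slot birthDate optional `Date` vector parallel to `animal`.
#'
#' @seealso [pedigree()], [readPedigree()], [sortPedigree()]
#' @export
setClass("Pedigree",
         representation(animal = "character",
                        sire = "character",
                        dam = "character",
                        birthDate = "DateOrNULL"))

setValidity("Pedigree", function(object) {
    n <- length(object@animal)
    msg <- character(0)
    if (length(object@sire) != n || length(object@dam) != n)
        msg <- c(msg, "animal, sire and dam must have equal length")
    if (anyDuplicated(object@animal))
        msg <- c(msg, sprintf("duplicate animal id: %s",
                              object@animal[duplicated(object@animal)][1L]))
    if (any(is.na(object@animal)) || any(object@animal == ""))
        msg <- c(msg, "animal ids must be non-missing")
    self <- !is.na(object@sire) & object@sire == object@animal |
            !is.na(object@dam) & object@dam == object@animal
    if (any(self))
        msg <- c(msg, sprintf("self-parent: animal %s listed as its own parent",
                              object@animal[self][1L]))
    if (!is.null(object@birthDate) && length(object@birthDate) != n)
        msg <- c(msg, "birthDate must match the number of animals")
    if (length(msg)) msg else TRUE
})

#' Pedigree sorted parents-before-offspring with inbreeding
#'
#' Produced by [sortPedigree()].  Animals referenced only as parents have been
#' inserted as founders; `sireIdx`/`damIdx` are row indices into the sorted
#' order (`NA` = unknown parent) and `inbreeding` holds the coefficient F of
#' each animal (0 for founders and animals with an unknown parent).
#'
#' @slot sireIdx,damIdx integer row index of each animal's parents.
#' @slot inbreeding numeric vector of inbreeding coefficients.
#' @export
setClass("SortedPedigree", contains = "Pedigree",
         representation(sireIdx = "integer",
                        damIdx = "integer",
                        inbreeding = "numeric"))

setValidity("SortedPedigree", function(object) {
    n <- length(object@animal)
    msg <- character(0)
    if (length(object@sireIdx) != n || length(object@damIdx) != n ||
        length(object@inbreeding) != n)
        msg <- c(msg, "index and inbreeding slots must match animal count")
    bad <- which(!is.na(object@sireIdx) & object@sireIdx >= seq_len(n) |
                 !is.na(object@damIdx) & object@damIdx >= seq_len(n))
    if (length(bad))
        msg <- c(msg, sprintf("parent does not precede offspring at row %d", bad[1L]))
    if (any(object@inbreeding < 0 | object@inbreeding >= 1))
        msg <- c(msg, "inbreeding coefficients must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Test-day milk records
#'
#' One row per test-day observation.  Required columns: `cow_id`, `herd_id`,
#' `calving_date`, `test_date`, `dim`, `milk_kg`, `age_at_calving_months`.
#' After [classifyRecords()] the table also carries `hys_class`, `age_class`,
#' `dim_class` and `residual_class`, and the `hysMap` slot records the dense
#' herd-year-season coding.
#'
#' @slot records data.frame of records.
#' @slot hysMap data.frame mapping (herd, year, season) to the dense class
#'   index, or a zero-row data.frame before classification.
#' @seealso [testDayData()], [readTestDayRecords()], [applyFilters()],
#'   [classifyRecords()]
#' @export
setClass("TestDayData",
         representation(records = "data.frame", hysMap = "data.frame"))

.tddRequired <- c("cow_id", "herd_id", "calving_date", "test_date",
                  "dim", "milk_kg", "age_at_calving_months")

setValidity("TestDayData", function(object) {
    miss <- setdiff(.tddRequired, names(object@records))
    if (length(miss))
        return(sprintf("missing record columns: %s", paste(miss, collapse = ", ")))
    TRUE
})

#' Normalized Legendre polynomial basis over a days-in-milk range
#'
#' Describes a basis of `order + 1` normalized Legendre polynomials evaluated
#' on days in milk standardized to `[-1, 1]` over `[dimMin, dimMax]`.
#'
#' @slot order integer, highest polynomial index (the basis has `order + 1`
#'   terms, k = 0..order).
#' @slot dimMin,dimMax integer bounds of the days-in-milk range.
#' @seealso [legendreBasis()], [basisVector()], [basisMatrix()]
#' @export
setClass("LegendreBasis",
         representation(order = "integer", dimMin = "integer", dimMax = "integer"))

setValidity("LegendreBasis", function(object) {
    if (object@order < 1L) return("order must be at least 1")
    if (object@dimMin >= object@dimMax) return("dimMin must be below dimMax")
    TRUE
})

#' Random regression model specification
#'
#' @slot nr,np integer orders of the Legendre regressions for the additive
#'   genetic and permanent-environment effects.
#' @slot residualMode `"homogeneous"` or `"heterogeneous"` residual variance.
#' @slot basis the [LegendreBasis-class] shared by both regressions.
#' @slot dimClassBounds 10 x 2 integer matrix of residual-class DIM intervals
#'   (inclusive bounds).
#' @seealso [rrModelSpec()]
#' @export
setClass("RRModelSpec",
         representation(nr = "integer", np = "integer",
                        residualMode = "character",
                        basis = "LegendreBasis",
                        dimClassBounds = "matrix"))

setValidity("RRModelSpec", function(object) {
    msg <- character(0)
    if (object@nr < 1L || object@nr > 5L || object@np < 1L || object@np > 5L)
        msg <- c(msg, "regression orders must lie in 1..5")
    if (!object@residualMode %in% c("homogeneous", "heterogeneous"))
        msg <- c(msg, "residualMode must be 'homogeneous' or 'heterogeneous'")
    b <- object@dimClassBounds
    if (ncol(b) != 2L || any(b[, 1L] > b[, 2L]))
        msg <- c(msg, "dimClassBounds must be a k x 2 matrix of intervals")
    if (length(msg)) msg else TRUE
})

#' Variance components of a random regression model
#'
#' @slot G,P symmetric positive definite covariance matrices (kg^2) of the
#'   genetic and permanent-environment regression coefficients.
#' @slot residual residual variance(s) in kg^2: length 1 (homogeneous) or one
#'   per DIM class (heterogeneous).
#' @slot weights residual weights, one per DIM class
#'   (`w_i = mean(v) / v_i`; all 1 under homogeneity).
#' @seealso [varianceComponents()], [residualWeights()]
#' @export
setClass("VarianceComponents",
         representation(G = "matrix", P = "matrix",
                        residual = "numeric", weights = "numeric"))

setValidity("VarianceComponents", function(object) {
    msg <- character(0)
    for (nm in c("G", "P")) {
        m <- slot(object, nm)
        if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
            msg <- c(msg, sprintf("%s must be symmetric", nm))
        else if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
            msg <- c(msg, sprintf("%s must be positive definite", nm))
    }
    if (any(object@residual <= 0)) msg <- c(msg, "residual variances must be positive")
    if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
    if (length(msg)) msg else TRUE
})

#' Fitted random regression test-day model
#'
#' Returned by [fitRRM()].  Holds the REML variance-component estimates, the
#' mixed-model-equation solutions at the optimum, the restricted
#' log-likelihood and bookkeeping needed for model scores and summaries.
#'
#' @slot spec the [RRModelSpec-class] fitted.
#' @slot components the [VarianceComponents-class] REML estimates.
#' @slot fixed data.frame of fixed-effect solutions (`effect`, `level`,
#'   `estimate`, `constrained`).
#' @slot a matrix of genetic regression coefficients, one row per pedigree
#'   animal (rownames = animal ids).
#' @slot pe matrix of permanent-environment coefficients, one row per
#'   recorded cow.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot nIter number of REML iterations; `converged` logical flag.
#' @slot rankX numerical rank of the fixed-effects design matrix.
#' @slot nRecords number of records used.
#' @slot residuals per-record residuals at the solution.
#' @slot residualClass integer residual class of each record.
#' @slot edfModel effective model degrees of freedom (trace of the hat
#'   matrix).
#' @slot leverage per-record model leverages `x_j' C^-1 x_j` used by
#'   [residualClassVariances()].
#' @slot vClassTable data.frame of per-class residual variances and weights
#'   (heterogeneous fits; zero-row otherwise).
#' @slot history data.frame of the iteration path (iteration, logL, step
#'   type, max parameter change).
#' @export
setClass("RRMFit",
         representation(spec = "RRModelSpec",
                        components = "VarianceComponents",
                        fixed = "data.frame",
                        a = "matrix",
                        pe = "matrix",
                        logLik = "numeric",
                        nIter = "integer",
                        converged = "logical",
                        rankX = "integer",
                        nRecords = "integer",
                        residuals = "numeric",
                        residualClass = "integer",
                        edfModel = "numeric",
                        leverage = "numeric",
                        vClassTable = "data.frame",
                        history = "data.frame"))

#' Synthetic herd simulation settings
#'
#' Configuration of the generative counterpart of the random regression model:
#' a shallow random-mating pedigree, herd-year-season structure, regression
#' coefficients drawn with the exact pedigree covariance, and test-day records
#' built from a lactation mean curve plus genetic, permanent-environment and
#' class-specific residual terms.
#'
#' @slot nSires,nDams number of male/female founders and of males/females
#'   bred per intermediate generation.
#' @slot nGenerations number of descendant generations (the last one is the
#'   recorded cows).
#' @slot nCows number of recorded cows (females of the last generation).
#' @slot nHerds number of herds; `years` integer calving years.
#' @slot seasonWeights monthly calving probabilities (length 12).
#' @slot trueG,trueP true coefficient covariance matrices.
#' @slot trueResidual residual variance(s): scalar or one per DIM class.
#' @slot meanCurve function mapping DIM to the fixed lactation mean (kg).
#' @slot hysSD standard deviation (kg) of herd-year-season effects.
#' @slot ageEffects fixed effects (kg) of the four calving-age classes.
#' @slot testInterval mean days between consecutive tests.
#' @slot missRate probability that a scheduled test is missed.
#' @slot basis the [LegendreBasis-class] of the true covariance functions.
#' @slot seed integer seed used by [simulateHerd()] / [generateDataset()].
#' @seealso [simConfig()], [simulateHerd()]
#' @export
setClass("HerdSimConfig",
         representation(nSires = "integer", nDams = "integer",
                        nGenerations = "integer", nCows = "integer",
                        nHerds = "integer", years = "integer",
                        seasonWeights = "numeric",
                        trueG = "matrix", trueP = "matrix",
                        trueResidual = "numeric",
                        meanCurve = "function",
                        hysSD = "numeric", ageEffects = "numeric",
                        testInterval = "integer", missRate = "numeric",
                        basis = "LegendreBasis",
                        seed = "integer"))
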