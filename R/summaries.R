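# Reported quantities: variance/heritability/repeatability trajectories,
# daily and 305-day breeding values, information criteria.

# residual variance by DIM for a component set (heterogeneous: class value)
.residualByDim <- function(components, basis, bounds) {
    dims <- basis@dimMin:basis@dimMax
    if (length(components@residual) == 1L)
        rep(components@residual, length(dims))
    else
        components@residual[assignResidualClass(dims, bounds)]
}

#' @rdname varianceTrajectory
#' @param basis a [LegendreBasis-class] (components method).
#' @param bounds residual-class intervals (components method).
setMethod("varianceTrajectory", "VarianceComponents",
          function(object, basis, bounds = dimClassBounds()) {
    Zm <- basisMatrix(basis)
    ra <- ncol(object@G)
    rp <- ncol(object@P)
    Vg <- rowSums((Zm[, seq_len(ra), drop = FALSE] %*% object@G) *
                  Zm[, seq_len(ra), drop = FALSE])
    Vpe <- rowSums((Zm[, seq_len(rp), drop = FALSE] %*% object@P) *
                   Zm[, seq_len(rp), drop = FALSE])
    Ve <- .residualByDim(object, basis, bounds)
    tot <- Vg + Vpe + Ve
    data.frame(dim = basis@dimMin:basis@dimMax,
               Vg = Vg, Vpe = Vpe, Ve = Ve,
               h2 = Vg / tot, rep = (Vg + Vpe) / tot)
})

#' @rdname varianceTrajectory
setMethod("varianceTrajectory", "RRMFit", function(object, ...) {
    varianceTrajectory(object@components, basis = object@spec@basis,
                       bounds = object@spec@dimClassBounds)
})

# covariate sum over the lactation, u = sum_t z_t
.basisColSums <- function(basis) colSums(basisMatrix(basis))

#' Heritability and repeatability of 305-day yield
#'
#' Treats the 305-day yield as the sum of the daily yields over DIM
#' `dimMin..dimMax`: with `u = sum_t z_t`, the genetic variance of the sum
#' is `u' G u`, the permanent-environment variance `u' P u`, and the
#' residual variance the sum of the daily residual variances (daily
#' residuals independent).  `h2_305` and `rep_305` are the corresponding
#' variance ratios.
#'
#' @param components a [VarianceComponents-class] (or an [RRMFit-class]).
#' @param basis a [LegendreBasis-class]; taken from the fit when
#'   `components` is an [RRMFit-class].
#' @param bounds residual-class intervals.
#' @return named numeric: `h2` and `rep` for the 305-day yield.
#' @export
lactationH2 <- function(components, basis = NULL, bounds = dimClassBounds()) {
    if (is(components, "RRMFit")) {
        basis <- components@spec@basis
        bounds <- components@spec@dimClassBounds
        components <- components@components
    }
    u <- .basisColSums(basis)
    ra <- ncol(components@G)
    rp <- ncol(components@P)
    vG <- drop(u[seq_len(ra)] %*% components@G %*% u[seq_len(ra)])
    vP <- drop(u[seq_len(rp)] %*% components@P %*% u[seq_len(rp)])
    vE <- sum(.residualByDim(components, basis, bounds))
    c(h2 = vG / (vG + vP + vE), rep = (vG + vP) / (vG + vP + vE))
}

#' @rdname ebv305
setMethod("ebv305", "RRMFit", function(object, ...) {
    ebv305(object@a, basis = object@spec@basis)
})

#' @rdname ebv305
#' @param basis a [LegendreBasis-class].
setMethod("ebv305", "matrix", function(object, basis, ...) {
    u <- .basisColSums(basis)
    if (ncol(object) > length(u)) stop("coefficient count exceeds basis order + 1")
    setNames(as.numeric(object %*% u[seq_len(ncol(object))]), rownames(object))
})

#' @rdname ebv305
setMethod("ebv305", "numeric", function(object, basis, ...) {
    u <- .basisColSums(basis)
    if (length(object) > length(u)) stop("coefficient count exceeds basis order + 1")
    sum(object * u[seq_along(object)])
})

#' Daily estimated breeding values
#'
#' `EBV(t) = z_t' a` for each DIM on the basis grid.
#'
#' @param fit an [RRMFit-class].
#' @param animals animal ids (default: all pedigree animals).
#' @return matrix of daily EBVs, DIM in rows, animals in columns.
#' @export
ebvTrajectory <- function(fit, animals = rownames(fit@a)) {
    Zm <- basisMatrix(fit@spec@basis)
    ra <- fit@spec@nr + 1L
    Zm[, seq_len(ra), drop = FALSE] %*% t(fit@a[animals, , drop = FALSE])
}

#' Model comparison scores
#'
#' `AIC = -2 logL + 2 p` and `BIC = -2 logL + p log(n)` (natural log), with
#' `p` the number of estimated covariance parameters (see
#' [countParameters()]) and `n` the number of test-day records minus the
#' rank of the fixed-effects design matrix.
#'
#' @param fit an [RRMFit-class].
#' @param includeFixed also count the fixed-effect parameters in `p`
#'   (default `FALSE`: covariance parameters only).
#' @return data.frame with `order`, `mode`, `nA`, `nPE`, `nR`, `p`, `n`,
#'   `minus2logL`, `AIC`, `BIC`.
#' @export
modelScores <- function(fit, includeFixed = FALSE) {
    cp <- countParameters(fit@spec)
    p <- cp$p + if (includeFixed) fit@rankX else 0L
    n <- fit@nRecords - fit@rankX
    if (n <= 0) stop("no residual degrees of freedom")
    m2 <- -2 * fit@logLik
    data.frame(order = fit@spec@nr,
               mode = if (fit@spec@residualMode == "heterogeneous") "HE" else "HO",
               nA = cp$nA, nPE = cp$nPE, nR = cp$nR, p = p, n = n,
               minus2logL = m2, AIC = m2 + 2 * p, BIC = m2 + p * log(n))
}

#' Write EBVs and trajectories
#'
#' `writeEBV` writes a CSV of animal ids and 305-day EBVs;
#' `writeTrajectory` the daily variance/heritability table of
#' [varianceTrajectory()] in long-friendly wide format.
#'
#' @param fit an [RRMFit-class].
#' @param path output CSV path.
#' @export
writeEBV <- function(fit, path) {
    e <- ebv305(fit)
    write.csv(data.frame(animal = names(e), ebv305 = as.numeric(e)),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeEBV
#' @export
writeTrajectory <- function(fit, path) {
    write.csv(varianceTrajectory(fit), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
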