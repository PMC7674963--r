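#' @rdname TestDayData-class
#' @param object,x a package object.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SortedPedigree-class
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))

#' Evaluate the Legendre covariate vector at one DIM
#'
#' @param basis a [LegendreBasis-class].
#' @param dim integer days in milk within the basis range.
#' @return numeric vector of length `order + 1`; element k + 1 is the
#'   normalized Legendre polynomial of index k at the standardized DIM.
#' @export
setGeneric("basisVector", function(basis, dim) standardGeneric("basisVector"))

#' Covariate matrix over the whole DIM grid
#'
#' @param basis a [LegendreBasis-class].
#' @return matrix with one row per integer DIM in `dimMin..dimMax` and
#'   `order + 1` columns.
#' @export
setGeneric("basisMatrix", function(basis) standardGeneric("basisMatrix"))

#' 305-day estimated breeding values
#'
#' Sums the daily genetic effect `z(t)' a` over DIM `dimMin..dimMax`
#' (5 to 305 by default), equal to `(sum_t z_t)' a`.
#'
#' @param object a fitted model, a coefficient matrix (animals x
#'   coefficients) or a single coefficient vector.
#' @param ... further arguments; `basis` (a [LegendreBasis-class]) when
#'   `object` is not a fit.
#' @return named numeric vector of 305-day EBVs (kg).
#' @export
setGeneric("ebv305", function(object, ...) standardGeneric("ebv305"))

#' Daily variance, heritability and repeatability trajectories
#'
#' Evaluates `sigma2_g(t) = z_t' G z_t`, `sigma2_pe(t) = z_t' P z_t` and the
#' residual variance of the DIM class of `t` for each day of lactation, with
#' `h2(t) = sigma2_g / (sigma2_g + sigma2_pe + sigma2_e)` and
#' `rep(t) = (sigma2_g + sigma2_pe) / (sigma2_g + sigma2_pe + sigma2_e)`.
#'
#' @param object an [RRMFit-class] or [VarianceComponents-class].
#' @param ... `basis` and `dimClassBounds` when `object` is a
#'   [VarianceComponents-class].
#' @return data.frame with columns `dim`, `Vg`, `Vpe`, `Ve`, `h2`, `rep`.
#' @export
setGeneric("varianceTrajectory", function(object, ...)
    standardGeneric("varianceTrajectory"))

#' REML variance-component estimates of a fit
#' @rdname RRMFit-class
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
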