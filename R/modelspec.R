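#' Specify a random regression test-day model
#'
#' @param nr order of the Legendre regression for the additive genetic
#'   effect (1..5).
#' @param np order for the permanent-environment effect; defaults to `nr`.
#' @param residual `"homogeneous"` (one residual variance) or
#'   `"heterogeneous"` (one per DIM class, handled by residual weighting).
#' @param dimMin,dimMax days-in-milk range of the basis (defaults 5, 305).
#' @param bounds residual-class intervals, see [dimClassBounds()].
#' @return an [RRModelSpec-class].
#' @examples
#' rrModelSpec(3, residual = "heterogeneous")
#' @export
rrModelSpec <- function(nr, np = nr,
                        residual = c("homogeneous", "heterogeneous"),
                        dimMin = 5L, dimMax = 305L, bounds = dimClassBounds()) {
    residual <- match.arg(residual)
    new("RRModelSpec", nr = as.integer(nr), np = as.integer(np),
        residualMode = residual,
        basis = legendreBasis(max(nr, np), dimMin, dimMax),
        dimClassBounds = bounds)
}

setMethod("show", "RRModelSpec", function(object) {
    cat(sprintf("RRModelSpec: LP%d genetic / LP%d permanent-environment, %s residual\n",
                object@nr, object@np, object@residualMode))
    cat(sprintf("  DIM %d..%d, %d residual classes\n", object@basis@dimMin,
                object@basis@dimMax, nrow(object@dimClassBounds)))
})

#' Construct a variance-component set
#'
#' @param G,P symmetric positive definite coefficient covariance matrices
#'   (kg^2).
#' @param residual residual variance(s) in kg^2 (scalar, or one per DIM
#'   class).
#' @param weights optional per-class weights; computed as
#'   `mean(residual) / residual` when `residual` has one entry per class.
#' @return a [VarianceComponents-class].
#' @export
VarianceComponents <- function(G, P, residual, weights = NULL) {
    if (is.null(weights))
        weights <- if (length(residual) > 1L) residualWeights(residual) else 1
    new("VarianceComponents", G = as.matrix(G), P = as.matrix(P),
        residual = residual, weights = weights)
}

setMethod("show", "VarianceComponents", function(object) {
    cat(sprintf("VarianceComponents: G %dx%d, P %dx%d\n",
                nrow(object@G), ncol(object@G), nrow(object@P), ncol(object@P)))
    cat("  diag(G):", paste(signif(diag(object@G), 4), collapse = " "), "\n")
    cat("  diag(P):", paste(signif(diag(object@P), 4), collapse = " "), "\n")
    if (length(object@residual) == 1L)
        cat("  residual:", signif(object@residual, 4), "(homogeneous)\n")
    else
        cat("  residual by DIM class:",
            paste(signif(object@residual, 4), collapse = " "), "\n")
})

#' Residual weights from class variances
#'
#' `w_i = mean(v) / v_i`, so that `w_i * v_i` equals the mean residual
#' variance for every class.
#'
#' @param v vector of per-class residual variances (all positive).
#' @return vector of weights, same length as `v`.
#' @export
residualWeights <- function(v) {
    if (any(v <= 0)) stop("residual variances must be positive")
    mean(v) / v
}

#' Counts of estimated covariance parameters
#'
#' For regression orders `nr` and `np` the genetic and permanent-environment
#' covariance matrices contribute `(nr + 1)(nr + 2) / 2` and
#' `(np + 1)(np + 2) / 2` parameters; the residual adds 1 (homogeneous) or
#' one per DIM class (heterogeneous).
#'
#' @param spec an [RRModelSpec-class], or an integer order (with `np`,
#'   `residual` as in [rrModelSpec()]).
#' @param np,residual used when `spec` is given as an integer order.
#' @return list with `nA`, `nPE`, `nR` and the total `p`.
#' @export
countParameters <- function(spec, np = NULL,
                            residual = c("homogeneous", "heterogeneous")) {
    if (!is(spec, "RRModelSpec")) {
        residual <- match.arg(residual)
        spec <- rrModelSpec(spec, if (is.null(np)) spec else np, residual)
    }
    nA <- (spec@nr + 1L) * (spec@nr + 2L) / 2L
    nPE <- (spec@np + 1L) * (spec@np + 2L) / 2L
    nR <- if (spec@residualMode == "heterogeneous")
        nrow(spec@dimClassBounds) else 1L
    list(nA = nA, nPE = nPE, nR = nR, p = nA + nPE + nR)
}
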