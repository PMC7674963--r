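# Normalized Legendre polynomials on standardized days in milk.
#
# The basis functions are LP_k(x) = sqrt((2k+1)/2) P_k(x) with P_k the
# classical Legendre polynomial, so that the LP_k are orthonormal under the
# uniform measure on [-1, 1].  Days in milk are mapped affinely onto [-1, 1].

#' Construct a Legendre basis specification
#'
#' @param order integer in 1..5 for the model orders used here; higher orders
#'   are supported through the three-term recurrence.
#' @param dimMin,dimMax integer days-in-milk range (defaults 5 and 305).
#' @return a [LegendreBasis-class].
#' @examples
#' b <- legendreBasis(3)
#' basisVector(b, 155)
#' @export
legendreBasis <- function(order, dimMin = 5L, dimMax = 305L) {
    new("LegendreBasis", order = as.integer(order),
        dimMin = as.integer(dimMin), dimMax = as.integer(dimMax))
}

#' Standardize days in milk to the unit interval
#'
#' `x = 2 (DIM - DIM_min) / (DIM_max - DIM_min) - 1`.
#'
#' @param dim integer vector of days in milk.
#' @param dimMin,dimMax range bounds (inclusive).
#' @return numeric vector in `[-1, 1]`.
#' @export
standardizeDIM <- function(dim, dimMin = 5L, dimMax = 305L) {
    if (any(dim < dimMin | dim > dimMax))
        stop("dim outside [", dimMin, ", ", dimMax, "]")
    2 * (dim - dimMin) / (dimMax - dimMin) - 1
}

# exact monomial forms for k <= 5; dyadic-rational coefficients times sqrt
.lpClosed <- list(
    function(x) rep_len(1 / sqrt(2), length(x)),
    function(x) sqrt(3 / 2) * x,
    function(x) sqrt(5 / 2) * (1.5 * x^2 - 0.5),
    function(x) sqrt(7 / 2) * (2.5 * x^3 - 1.5 * x),
    function(x) sqrt(9 / 2) * (35 / 8 * x^4 - 30 / 8 * x^2 + 3 / 8),
    function(x) sqrt(11 / 2) * (63 / 8 * x^5 - 70 / 8 * x^3 + 15 / 8 * x)
)

#' Normalized Legendre polynomial value
#'
#' @param k integer polynomial index (0 or larger).
#' @param x numeric vector in `[-1, 1]`.
#' @param method `"closed"` uses the explicit monomial forms (k <= 5),
#'   `"recurrence"` the Bonnet three-term recurrence (any k).  The default
#'   picks the closed form when available.
#' @return numeric vector, `sqrt((2k+1)/2)` times the classical Legendre
#'   polynomial of degree k.
#' @export
legendreValue <- function(k, x, method = c("auto", "closed", "recurrence")) {
    method <- match.arg(method)
    stopifnot(length(k) == 1L, k >= 0)
    if (method == "closed" && k > 5L)
        stop("closed forms are available for k <= 5 only")
    if (k <= 5L && method != "recurrence")
        return(.lpClosed[[k + 1L]](x))
    # Bonnet recurrence on the classical polynomials, normalized at the end
    pkm1 <- rep_len(1, length(x))
    if (k == 0L) return(sqrt(1 / 2) * pkm1)
    pk <- x
    if (k > 1L) for (j in 2:k) {
        pkp1 <- ((2 * j - 1) * x * pk - (j - 1) * pkm1) / j
        pkm1 <- pk
        pk <- pkp1
    }
    sqrt((2 * k + 1) / 2) * pk
}

#' @rdname basisVector
setMethod("basisVector", "LegendreBasis", function(basis, dim) {
    x <- standardizeDIM(dim, basis@dimMin, basis@dimMax)
    vapply(0:basis@order, legendreValue, numeric(length(x)), x = x)
})

#' @rdname basisMatrix
setMethod("basisMatrix", "LegendreBasis", function(basis) {
    dims <- basis@dimMin:basis@dimMax
    x <- standardizeDIM(dims, basis@dimMin, basis@dimMax)
    m <- vapply(0:basis@order, legendreValue, numeric(length(x)), x = x)
    dimnames(m) <- list(dims, paste0("k", 0:basis@order))
    m
})

setMethod("show", "LegendreBasis", function(object) {
    cat(sprintf("LegendreBasis: order %d (%d terms), DIM %d..%d\n",
                object@order, object@order + 1L, object@dimMin, object@dimMax))
})
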