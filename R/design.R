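# Design matrices and Henderson's mixed-model equations for the test-day
# model: y = HYS + AGE + DIM + sum_k z_k a_k + sum_k z_k pe_k + e.

#' Design components of the random regression model
#'
#' Built by [buildDesign()].  The fixed-effect matrix `X` contains indicator
#' columns for the observed herd-year-season, age-class and DIM levels;
#' linearly dependent columns (at least the last age and last observed DIM
#' level, which are confounded with the other effects) are constrained to
#' zero and removed, so `X` has full column rank.  `Za` and `Zp` carry the
#' Legendre covariates in animal-major blocks: all `nr + 1` genetic
#' coefficients of an animal are adjacent, over every pedigree animal;
#' permanent-environment blocks exist for recorded cows only.
#'
#' @slot y numeric response (daily milk, kg).
#' @slot X,Za,Zp sparse design blocks; `W` their column binding.
#' @slot fixedInfo data.frame describing the kept columns of `X`
#'   (`effect`, `level`); `dropped` the zero-constrained levels.
#' @slot rankX rank of the full fixed-effects design matrix (= `ncol(X)`).
#' @slot animals pedigree animal ids (order of the genetic blocks).
#' @slot cows recorded cow ids (order of the pe blocks).
#' @slot residualClass integer DIM class of each record.
#' @slot nr,np regression orders.
#' @export
setClass("RRMDesign",
         representation(y = "numeric", X = "ANY", Za = "ANY", Zp = "ANY",
                        W = "ANY", fixedInfo = "data.frame",
                        dropped = "data.frame", rankX = "integer",
                        animals = "character", cows = "character",
                        residualClass = "integer",
                        nr = "integer", np = "integer"))

# sequential greedy rank detection on X'X: keeps a column when its pivot in
# an incremental Cholesky exceeds tol * largest diagonal, so dependent
# columns encountered later (e.g. the last level of a confounded effect) are
# the ones dropped.
.greedyKeep <- function(XtX, tol = 1e-9) {
    nf <- ncol(XtX)
    dmax <- max(diag(XtX))
    keep <- integer(0)
    R <- matrix(0, 0L, 0L)
    for (j in seq_len(nf)) {
        if (length(keep)) {
            z <- backsolve(R, XtX[keep, j], transpose = TRUE)
            piv <- XtX[j, j] - sum(z * z)
        } else {
            z <- numeric(0)
            piv <- XtX[j, j]
        }
        if (piv > tol * dmax) {
            keep <- c(keep, j)
            R <- rbind(cbind(R, z), c(rep(0, length(z)), sqrt(piv)))
        }
    }
    keep
}

#' Numerical rank of a design matrix
#'
#' @param m a dense or sparse matrix.
#' @param tol relative pivot tolerance.
#' @return integer rank of `m`.
#' @export
designRank <- function(m, tol = 1e-9) {
    length(.greedyKeep(as.matrix(crossprod(m)), tol))
}

#' Build the model design from classified records
#'
#' @param tdd a classified [TestDayData-class] (see [classifyRecords()]).
#' @param ped a [SortedPedigree-class] containing every recorded cow.
#' @param spec an [RRModelSpec-class].
#' @return an [RRMDesign-class].
#' @export
buildDesign <- function(tdd, ped, spec) {
    df <- tdd@records
    if (is.null(df$hys_class)) stop("records must be classified first")
    n <- nrow(df)
    animals <- ped@animal
    aPos <- match(df$cow_id, animals)
    if (anyNA(aPos))
        stop("record for cow absent from pedigree: ",
             df$cow_id[which(is.na(aPos))[1L]])

    # fixed part: indicators for observed levels, ordered HYS, AGE, DIM
    hysLev <- sort(unique(df$hys_class))
    ageLev <- sort(unique(df$age_class))
    dimLev <- sort(unique(df$dim_class))
    cols <- list(
        data.frame(effect = "hys", level = hysLev),
        data.frame(effect = "age", level = ageLev),
        data.frame(effect = "dim", level = dimLev))
    fixedInfo <- do.call(rbind, cols)
    nf <- nrow(fixedInfo)
    off <- c(0L, length(hysLev), length(hysLev) + length(ageLev))
    jFix <- c(match(df$hys_class, hysLev),
              off[2L] + match(df$age_class, ageLev),
              off[3L] + match(df$dim_class, dimLev))
    Xfull <- sparseMatrix(i = rep(seq_len(n), 3L), j = jFix, x = 1,
                          dims = c(n, nf))
    keep <- .greedyKeep(as.matrix(crossprod(Xfull)))
    X <- Xfull[, keep, drop = FALSE]
    dropped <- fixedInfo[-keep, , drop = FALSE]
    fixedInfo <- fixedInfo[keep, , drop = FALSE]

    # random regressions on the Legendre covariates
    zr <- basisVector(spec@basis, df$dim)      # n x (max order + 1) pieces
    ra <- spec@nr + 1L
    rp <- spec@np + 1L
    q <- length(animals)
    cows <- animals[sort(unique(aPos))]
    cPos <- match(df$cow_id, cows)
    Za <- sparseMatrix(i = rep(seq_len(n), ra),
                       j = as.vector(vapply(seq_len(ra), function(k)
                           (aPos - 1L) * ra + k, integer(n))),
                       x = as.vector(zr[, seq_len(ra)]),
                       dims = c(n, q * ra))
    Zp <- sparseMatrix(i = rep(seq_len(n), rp),
                       j = as.vector(vapply(seq_len(rp), function(k)
                           (cPos - 1L) * rp + k, integer(n))),
                       x = as.vector(zr[, seq_len(rp)]),
                       dims = c(n, length(cows) * rp))

    new("RRMDesign", y = df$milk_kg, X = X, Za = Za, Zp = Zp,
        W = cbind(X, Za, Zp), fixedInfo = fixedInfo, dropped = dropped,
        rankX = length(keep), animals = animals, cows = cows,
        residualClass = as.integer(df$residual_class),
        nr = spec@nr, np = spec@np)
}

#' Rank of the fixed-effects design
#'
#' @param design an [RRMDesign-class].
#' @return integer rank (number of estimable fixed-effect columns).
#' @export
rankFixedEffects <- function(design) design@rankX

.recordWeights <- function(design, weights) {
    if (is.null(weights) || length(weights) == 1L) rep(1, length(design@y))
    else weights[design@residualClass]
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the symmetric coefficient matrix `C = W' R^-1 W + D` and right-hand
#' side `W' R^-1 y`, where `W = [X Za Zp]`, `R = v * diag(1/w)` with
#' per-record weights `w` taken from the residual class, and `D` adds
#' `Ainv (x) G^-1` on the genetic block and `I (x) P^-1` on the
#' permanent-environment block.
#'
#' @param design an [RRMDesign-class].
#' @param G,P coefficient covariance matrices (orders matching the design).
#' @param v residual variance (scalar, on the weighted scale).
#' @param ainv sparse A-inverse from [makeAInverse()] (same animal order as
#'   the design).
#' @param weights optional per-class residual weights (heterogeneous mode).
#' @return list with elements `C` (sparse symmetric), `rhs`, `blocks`
#'   (index ranges of the fixed, genetic and pe blocks) and `w` (per-record
#'   weights).
#' @export
assembleMME <- function(design, G, P, v, ainv, weights = NULL) {
    for (nm in list(list(G, "G"), list(P, "P"))) {
        ev <- eigen(nm[[1L]], symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 0)
            stop("covariance matrix ", nm[[2L]], " is not positive definite")
    }
    if (v <= 0) stop("residual variance must be positive")
    w <- .recordWeights(design, weights)
    Ws <- Diagonal(x = sqrt(w)) %*% design@W
    M <- forceSymmetric(crossprod(Ws))
    nf <- ncol(design@X)
    ra <- design@nr + 1L
    rp <- design@np + 1L
    q <- length(design@animals)
    nc <- length(design@cows)
    prec <- bdiag(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nf, nf)),
                  kronecker(ainv, solve(G)),
                  kronecker(Diagonal(nc), solve(P)))
    C <- forceSymmetric(M / v + prec)
    rhs <- as.numeric(crossprod(design@W, w * design@y)) / v
    blocks <- list(fixed = seq_len(nf),
                   a = nf + seq_len(q * ra),
                   pe = nf + q * ra + seq_len(nc * rp))
    list(C = C, rhs = rhs, blocks = blocks, w = w, v = v)
}

#' Solve the mixed-model equations
#'
#' @param mme system from [assembleMME()].
#' @param design the matching [RRMDesign-class] (for labelling).
#' @param method `"direct"` sparse Cholesky (default) or `"iterative"`
#'   Jacobi-preconditioned conjugate gradients.
#' @param tol relative residual tolerance of the iterative solver.
#' @param maxIter iteration cap of the iterative solver.
#' @return list with `fixed` (data.frame effect/level/estimate/constrained,
#'   zero-constrained levels included), `a` (animals x coefficients matrix),
#'   `pe` (cows x coefficients) and `solution` (the raw vector).
#' @export
solveMME <- function(mme, design, method = c("direct", "iterative"),
                     tol = 1e-10, maxIter = 2000L) {
    method <- match.arg(method)
    if (method == "direct") {
        ch <- Cholesky(mme$C, LDL = FALSE, super = FALSE, perm = TRUE)
        sol <- as.numeric(solve(ch, mme$rhs))
    } else {
        sol <- .pcg(mme$C, mme$rhs, tol = tol, maxIter = maxIter)
    }
    .labelSolutions(sol, mme, design)
}

.pcg <- function(C, b, tol = 1e-10, maxIter = 2000L) {
    x <- numeric(length(b))
    r <- b
    Minv <- 1 / diag(C)
    z <- Minv * r
    p <- z
    rz <- sum(r * z)
    b2 <- sqrt(sum(b * b))
    for (it in seq_len(maxIter)) {
        Cp <- as.numeric(C %*% p)
        alpha <- rz / sum(p * Cp)
        x <- x + alpha * p
        r <- r - alpha * Cp
        if (sqrt(sum(r * r)) <= tol * b2) return(x)
        z <- Minv * r
        rzNew <- sum(r * z)
        p <- z + (rzNew / rz) * p
        rz <- rzNew
    }
    warning("conjugate-gradient solver did not reach tolerance ", tol,
            " in ", maxIter, " iterations")
    x
}

.labelSolutions <- function(sol, mme, design) {
    nf <- ncol(design@X)
    ra <- design@nr + 1L
    rp <- design@np + 1L
    fixed <- design@fixedInfo
    fixed$estimate <- sol[seq_len(nf)]
    fixed$constrained <- FALSE
    if (nrow(design@dropped)) {
        drp <- design@dropped
        drp$estimate <- 0
        drp$constrained <- TRUE
        fixed <- rbind(fixed, drp)
        fixed <- fixed[order(match(fixed$effect, c("hys", "age", "dim")),
                             fixed$level), ]
    }
    rownames(fixed) <- NULL
    a <- matrix(sol[mme$blocks$a], ncol = ra, byrow = TRUE,
                dimnames = list(design@animals, paste0("k", 0:design@nr)))
    pe <- matrix(sol[mme$blocks$pe], ncol = rp, byrow = TRUE,
                 dimnames = list(design@cows, paste0("k", 0:design@np)))
    list(fixed = fixed, a = a, pe = pe, solution = sol)
}
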