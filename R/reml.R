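# Restricted maximum likelihood for the random regression test-day model.
#
# The engine works on Henderson's mixed-model equations scaled by R^-1:
#   C = W' R^-1 W + blockdiag(0, Ainv x Ginv, I x Pinv),  R = v * diag(1/w),
# so that C^-1 is the prediction-error covariance of the solutions.  One
# iteration factorizes C (sparse Cholesky), solves for the BLUE/BLUP
# solutions, computes the selected inverse of C on the pattern of the factor
# (Takahashi equations, compiled kernel) and from it the exact first
# derivatives of the restricted log-likelihood and the EM updates.  After a
# short EM burn-in, average-information (AI) steps are taken: the AI matrix
# is built from one extra MME solve per parameter, and a step is accepted
# only if it does not decrease the restricted log-likelihood (with step
# halving and an EM fallback), so the likelihood path is monotone.

#' REML control settings
#'
#' @param tol convergence tolerance on `max |delta| / (|theta| + 1)` over
#'   the variance parameters.
#' @param maxIter maximum REML iterations.
#' @param burnin number of initial plain EM iterations before switching to
#'   average-information steps.
#' @param maxDamping number of Levenberg-style damping escalations of a
#'   rejected average-information step before falling back to the EM update.
#' @param floorRel relative eigenvalue floor keeping G and P positive
#'   definite (times the matrix trace).
#' @param hetPasses maximum outer passes of the heterogeneous-residual
#'   weight iteration (1 = single pass).
#' @param hetTol relative-change tolerance on the class variances that stops
#'   the weight iteration.
#' @param verbose print the iteration path.
#' @return list of settings for [fitRRM()].
#' @export
remlControl <- function(tol = 1e-6, maxIter = 200L, burnin = 3L,
                        maxDamping = 5L, floorRel = 1e-8,
                        hetPasses = 6L, hetTol = 0.01, verbose = FALSE) {
    list(tol = tol, maxIter = as.integer(maxIter), burnin = as.integer(burnin),
         maxDamping = as.integer(maxDamping), floorRel = floorRel,
         hetPasses = as.integer(hetPasses), hetTol = hetTol, verbose = verbose)
}

.zeroSp <- function(n) sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(n, n))

.logdetSym <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)

# eigenvalue flooring; returns matrix unchanged when already well-conditioned
.floorPD <- function(m, rel = 1e-8) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    floorVal <- rel * max(sum(abs(diag(m))), .Machine$double.eps)
    if (all(e$values >= floorVal)) return((m + t(m)) / 2)
    v <- pmax(e$values, floorVal)
    e$vectors %*% (v * t(e$vectors))
}

.vech <- function(m) m[upper.tri(m, diag = TRUE)]
.unvech <- function(x, r) {
    m <- matrix(0, r, r)
    m[upper.tri(m, diag = TRUE)] <- x
    m + t(m) - diag(diag(m), r)
}

# persistent pieces of the REML problem that do not change with theta
.remlWorkspace <- function(design, ainv, weights = NULL) {
    w <- .recordWeights(design, weights)
    W <- design@W
    n <- length(design@y)
    nf <- ncol(design@X)
    ra <- design@nr + 1L
    rp <- design@np + 1L
    q <- length(design@animals)
    nc <- length(design@cows)
    Ws <- Diagonal(x = sqrt(w)) %*% W
    M <- forceSymmetric(crossprod(Ws))
    list(design = design, ainv = ainv,
         logdetA = attr(ainv, "logdet"),
         w = w, n = n, nf = nf, ra = ra, rp = rp, q = q, nc = nc,
         aIdx = nf + seq_len(q * ra),
         pIdx = nf + q * ra + seq_len(nc * rp),
         M = M, Mg = as(M, "generalMatrix"),
         Wt = as(as(Matrix::t(W), "CsparseMatrix"), "generalMatrix"),
         Wty = as.numeric(crossprod(W, w * design@y)),
         yty = sum(w * design@y^2),
         sumLogW = sum(log(w)),
         ainvG = as(as(ainv, "generalMatrix"), "CsparseMatrix"),
         IcowG = as(as(Diagonal(nc), "CsparseMatrix"), "generalMatrix"),
         chA = Cholesky(ainv, LDL = FALSE, super = FALSE, perm = TRUE))
}

# factorize + solve + restricted log-likelihood at (G, P, v)
.lightFit <- function(ws, G, P, v) {
    prec <- bdiag(.zeroSp(ws$nf),
                  kronecker(ws$ainv, solve(G)),
                  kronecker(Diagonal(ws$nc), solve(P)))
    C <- forceSymmetric(ws$M / v + prec)
    ch <- Cholesky(C, LDL = FALSE, super = FALSE, perm = TRUE)
    sol <- as.numeric(solve(ch, ws$Wty / v))
    logdetC <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
    yPy <- (ws$yty - sum(sol * ws$Wty)) / v
    logL <- -0.5 * ((ws$n - ws$nf) * log(2 * pi) +
                    logdetC + ws$n * log(v) - ws$sumLogW +
                    ws$ra * ws$logdetA + ws$q * .logdetSym(G) +
                    ws$nc * .logdetSym(P) + yPy)
    list(ch = ch, sol = sol, logL = logL)
}

# selected inverse of C mapped back to the original equation order
.selectedInverse <- function(ch) {
    L <- as(ch, "sparseMatrix")
    m <- nrow(L)
    zx <- .takahashi_inverse(L@p, L@i, L@x, m)
    Zl <- sparseMatrix(i = L@i + 1L, p = L@p, x = zx, dims = c(m, m))
    Zs <- Zl + t(Zl) - Diagonal(x = diag(Zl))
    ip <- invPerm(ch@perm + 1L)
    as(Zs[ip, ip], "CsparseMatrix")
}

# EM statistics, gradients and trace terms at the current fit
.remlStats <- function(ws, fit, G, P, v) {
    Z <- .selectedInverse(fit$ch)
    design <- ws$design
    ra <- ws$ra; rp <- ws$rp
    Ua <- matrix(fit$sol[ws$aIdx], ncol = ra, byrow = TRUE)
    Up <- matrix(fit$sol[ws$pIdx], ncol = rp, byrow = TRUE)
    Su <- as.matrix(crossprod(Ua, ws$ainv %*% Ua))
    Sp <- crossprod(Up)
    Ta <- matrix(0, ra, ra)
    for (a in seq_len(ra)) for (b in a:ra) {
        Ta[a, b] <- Ta[b, a] <- .block_trace_sum(
            ws$ainvG@p, ws$ainvG@i, ws$ainvG@x, Z@p, Z@i, Z@x,
            ws$nf, ra, a - 1L, b - 1L)
    }
    Tp <- matrix(0, rp, rp)
    for (a in seq_len(rp)) for (b in a:rp) {
        Tp[a, b] <- Tp[b, a] <- .block_trace_sum(
            ws$IcowG@p, ws$IcowG@i, ws$IcowG@x, Z@p, Z@i, Z@x,
            ws$nf + ws$q * ra, rp, a - 1L, b - 1L)
    }
    resid <- ws$design@y - as.numeric(design@W %*% fit$sol)
    eOe <- sum(ws$w * resid^2)
    trWCW <- sum(ws$Mg * Z)
    lev <- .row_quadform(ws$Wt@p, ws$Wt@i, ws$Wt@x, Z@p, Z@i, Z@x)

    SG <- Su + Ta
    SP <- Sp + Tp
    Ginv <- solve(G)
    Pinv <- solve(P)
    Hg <- Ginv %*% (SG - ws$q * G) %*% Ginv
    Hp <- Pinv %*% (SP - ws$nc * P) %*% Pinv
    scoreMat <- function(H) {
        s <- H
        diag(s) <- diag(H) / 2
        .vech(s)
    }
    list(resid = resid, eOe = eOe, trWCW = trWCW, leverage = lev,
         Gem = SG / ws$q, Pem = SP / ws$nc,
         vem = (eOe + trWCW) / ws$n,
         score = c(scoreMat(Hg), scoreMat(Hp),
                   0.5 * ((eOe + trWCW) / v^2 - ws$n / v)),
         edf = trWCW / v)
}

# average-information matrix: one MME solve per variance parameter
.aiMatrix <- function(ws, fit, stats, v) {
    design <- ws$design
    ra <- ws$ra; rp <- ws$rp
    Py <- ws$w * stats$resid / v
    TaM <- matrix(as.numeric(crossprod(design@Za, Py)), nrow = ra)
    TpM <- matrix(as.numeric(crossprod(design@Zp, Py)), nrow = rp)
    cols <- list()
    # parameter order must match .vech (upper triangle, column-major)
    for (k in seq_len(ra)) for (j in seq_len(k)) {
        E <- matrix(0, ra, ra); E[j, k] <- E[k, j] <- 1
        Y <- E %*% TaM
        YA <- t(as.matrix(solve(ws$chA, t(Y))))   # apply A across animals
        cols[[length(cols) + 1L]] <- as.numeric(design@Za %*% as.vector(YA))
    }
    for (k in seq_len(rp)) for (j in seq_len(k)) {
        E <- matrix(0, rp, rp); E[j, k] <- E[k, j] <- 1
        cols[[length(cols) + 1L]] <- as.numeric(design@Zp %*% as.vector(E %*% TpM))
    }
    cols[[length(cols) + 1L]] <- stats$resid / v   # d V / d v = Omega^-1
    F <- do.call(cbind, cols)
    G1 <- as.matrix(crossprod(design@W, ws$w * F)) / v
    H <- as.matrix(solve(fit$ch, G1))
    PF <- (ws$w * F - ws$w * as.matrix(design@W %*% H)) / v
    AI <- 0.5 * crossprod(F, PF)
    (AI + t(AI)) / 2
}

.packTheta <- function(G, P, v) c(.vech(G), .vech(P), v)

# factorization with a fallback ladder: when the coefficient matrix cannot
# be factorized (G or P numerically singular at the flooring level), retry
# with a progressively larger eigenvalue floor
.safeLightFit <- function(ws, G, P, v) {
    for (rel in c(NA, 1e-6, 1e-4)) {
        if (!is.na(rel)) {
            G <- .floorPD(G, rel)
            P <- .floorPD(P, rel)
        }
        fit <- tryCatch(suppressWarnings(.lightFit(ws, G, P, v)),
                        error = function(e) NULL)
        if (!is.null(fit) && is.finite(fit$logL))
            return(list(fit = fit, G = G, P = P))
    }
    stop("mixed-model equations could not be factorized; variance components ",
         "appear degenerate")
}

# core iteration; init is a list(G, P, v)
.remlEngine <- function(ws, init, control) {
    ra <- ws$ra; rp <- ws$rp
    G <- init$G; P <- init$P; v <- init$v
    nG <- ra * (ra + 1L) / 2L
    nP <- rp * (rp + 1L) / 2L
    sf0 <- .safeLightFit(ws, G, P, v)
    fit <- sf0$fit
    G <- sf0$G
    P <- sf0$P
    history <- data.frame(iter = integer(0), logL = numeric(0),
                          step = character(0), maxChange = numeric(0))
    converged <- FALSE
    iter <- 0L
    floored <- FALSE
    repeat {
        iter <- iter + 1L
        stats <- .remlStats(ws, fit, G, P, v)
        theta <- .packTheta(G, P, v)
        useAI <- iter > control$burnin
        stepType <- "EM"
        Gn <- stats$Gem; Pn <- stats$Pem; vn <- stats$vem
        fitNew <- NULL
        if (useAI) {
            AI <- .aiMatrix(ws, fit, stats, v)
            dAI <- diag(AI)
            # Levenberg-style damping: undamped Newton-type step first, then
            # progressively damped steps bending toward scaled gradient ascent
            lambdas <- c(0, 10^seq(-1, control$maxDamping - 2L))
            for (h in seq_along(lambdas)) {
                delta <- tryCatch(
                    solve(AI + lambdas[h] * diag(dAI, length(dAI)), stats$score),
                    error = function(e) NULL)
                if (is.null(delta)) next
                cand <- theta + delta
                Gc <- .floorPD(.unvech(cand[seq_len(nG)], ra), control$floorRel)
                Pc <- .floorPD(.unvech(cand[nG + seq_len(nP)], rp), control$floorRel)
                vc <- cand[nG + nP + 1L]
                if (vc <= 0) vc <- v / 2
                fc <- tryCatch(.lightFit(ws, Gc, Pc, vc),
                               error = function(e) NULL)
                if (!is.null(fc) && is.finite(fc$logL) &&
                    fc$logL >= fit$logL - 1e-8) {
                    Gn <- Gc; Pn <- Pc; vn <- vc
                    fitNew <- fc
                    stepType <- if (h == 1L) "AI" else sprintf("AI+%g", lambdas[h])
                    break
                }
            }
        }
        GnF <- .floorPD(Gn, control$floorRel)
        PnF <- .floorPD(Pn, control$floorRel)
        if (max(abs(GnF - Gn)) > 0 || max(abs(PnF - Pn)) > 0) floored <- TRUE
        Gn <- GnF; Pn <- PnF
        thetaNew <- .packTheta(Gn, Pn, vn)
        maxChange <- max(abs(thetaNew - theta) / (abs(theta) + 1))
        if (is.null(fitNew)) {
            sf <- .safeLightFit(ws, Gn, Pn, vn)
            fitNew <- sf$fit
            Gn <- sf$G
            Pn <- sf$P
        }
        history <- rbind(history,
                         data.frame(iter = iter, logL = fitNew$logL,
                                    step = stepType, maxChange = maxChange))
        if (control$verbose)
            message(sprintf("  iter %3d  logL %.4f  %-5s  max change %.2e",
                            iter, fitNew$logL, stepType, maxChange))
        G <- Gn; P <- Pn; v <- vn
        fit <- fitNew
        if (maxChange < control$tol) { converged <- TRUE; break }
        if (iter >= control$maxIter) break
    }
    stats <- .remlStats(ws, fit, G, P, v)
    list(G = G, P = P, v = v, fit = fit, stats = stats,
         logL = fit$logL, nIter = iter, converged = converged,
         floored = floored, history = history)
}

.defaultInit <- function(design) {
    vy <- var(design@y)
    ra <- design@nr + 1L
    rp <- design@np + 1L
    shr <- c(1, 0.3, 0.15, 0.08, 0.05, 0.03)
    list(G = diag(vy * 0.6 * shr[seq_len(ra)], ra),
         P = diag(vy * 0.9 * shr[seq_len(rp)], rp),
         v = vy * 0.4)
}

#' Restricted log-likelihood of the test-day model
#'
#' Evaluates the REML log-likelihood (including the constant
#' `-(n - rank(X))/2 log 2 pi`) at given variance components via the
#' mixed-model-equation factorization:
#' `-2 logL = (n - rank X) log 2pi + log|C| + log|R| + log|A x G| +
#' log|I x P| + y' P y`.
#'
#' @param design an [RRMDesign-class].
#' @param components a [VarianceComponents-class] (its `weights` are applied
#'   when it carries per-class residuals).
#' @param ainv sparse A-inverse from [makeAInverse()].
#' @return the restricted log-likelihood (scalar).
#' @export
remlLogLik <- function(design, components, ainv) {
    weights <- if (length(components@residual) > 1L) components@weights else NULL
    ws <- .remlWorkspace(design, ainv, weights)
    v <- if (length(components@residual) > 1L)
        mean(components@residual) else components@residual
    .lightFit(ws, components@G, components@P, v)$logL
}

#' Per-class residual variances from a fit
#'
#' Splits the residual variance over the DIM classes with the
#' leverage-exact moment estimator
#' `v_i = (sum_{records in class i} e^2 + sum h_j) / n_i`, where
#' `h_j = x_j' C^-1 x_j` is the model leverage of record j on the
#' residual-scaled mixed-model equations (so that `E[e_hat_j^2] = v_j - h_j`
#' and the estimator is unbiased at the fixed point).
#'
#' @param fit an [RRMFit-class].
#' @return numeric vector of class variances (kg^2), one per DIM class.
#' @export
residualClassVariances <- function(fit) {
    cls <- fit@residualClass
    nCls <- nrow(fit@spec@dimClassBounds)
    miss <- setdiff(seq_len(nCls), unique(cls))
    if (length(miss))
        stop("empty residual class: ", paste(miss, collapse = ", "))
    ni <- tabulate(cls, nCls)
    vapply(seq_len(nCls), function(i) {
        j <- cls == i
        (sum(fit@residuals[j]^2) + sum(fit@leverage[j])) / ni[i]
    }, numeric(1))
}

#' Fit a random regression test-day model by REML
#'
#' Estimates the coefficient covariance matrices G and P and the residual
#' variance by average-information REML with EM safeguards, and returns the
#' mixed-model solutions (fixed effects, genetic and permanent-environment
#' regression coefficients) at the optimum.  Under
#' `residual = "heterogeneous"` the fit alternates weighted REML with
#' re-estimation of the ten DIM-class residual variances and of the weights
#' `w_i = mean(v) / v_i` until the class variances stabilize.
#'
#' @param tdd a [TestDayData-class]; classified with [classifyRecords()]
#'   first (done automatically when the class columns are missing).
#' @param ped a [Pedigree-class] or [SortedPedigree-class] containing every
#'   recorded cow.
#' @param spec an [RRModelSpec-class].
#' @param init optional [VarianceComponents-class] (or list with `G`, `P`,
#'   `v`) of starting values.
#' @param control list from [remlControl()].
#' @return an [RRMFit-class].
#' @examples
#' \donttest{
#' sim <- simulateHerd(simConfig(nCows = 150L, nDams = 60L, nSires = 8L,
#'                               seed = 1L))
#' tdd <- classifyRecords(applyFilters(sim$records))
#' fit <- fitRRM(tdd, sim$pedigree, rrModelSpec(1))
#' fit
#' }
#' @export
fitRRM <- function(tdd, ped, spec, init = NULL, control = remlControl()) {
    if (is.null(tdd@records$hys_class))
        tdd <- classifyRecords(tdd, spec@dimClassBounds)
    if (!is(ped, "SortedPedigree")) ped <- sortPedigree(ped)
    design <- buildDesign(tdd, ped, spec)
    ainv <- makeAInverse(ped)
    if (is.null(init)) init <- .defaultInit(design)
    if (is(init, "VarianceComponents"))
        init <- list(G = init@G, P = init@P,
                     v = mean(init@residual))
    nCls <- nrow(spec@dimClassBounds)

    runOnce <- function(weights, init) {
        ws <- .remlWorkspace(design, ainv, weights)
        .remlEngine(ws, init, control)
    }

    if (spec@residualMode == "homogeneous") {
        res <- runOnce(NULL, init)
        weights <- rep(1, nCls)
        vClass <- rep(res$v, nCls)
        vTab <- data.frame()
    } else {
        weights <- rep(1, nCls)
        res <- runOnce(NULL, init)
        vClass <- .classVariances(res, design, nCls)
        for (pass in seq_len(control$hetPasses)) {
            weights <- residualWeights(vClass)
            res <- runOnce(weights, list(G = res$G, P = res$P, v = res$v))
            vNew <- .classVariances(res, design, nCls)
            change <- max(abs(vNew - vClass) / vClass)
            vClass <- vNew
            if (control$verbose)
                message(sprintf("  het pass %d: max class-variance change %.3f",
                                pass, change))
            if (change < control$hetTol) break
        }
        weights <- residualWeights(vClass)
        b <- spec@dimClassBounds
        vTab <- data.frame(class = seq_len(nCls),
                           from = b[, 1L], to = b[, 2L],
                           n = tabulate(design@residualClass, nCls),
                           v = vClass, weight = weights)
    }

    mme <- list(blocks = list(fixed = seq_len(ncol(design@X)),
                              a = ws_aIdx <- ncol(design@X) +
                                  seq_len(length(design@animals) * (design@nr + 1L)),
                              pe = max(ws_aIdx) +
                                  seq_len(length(design@cows) * (design@np + 1L))))
    lab <- .labelSolutions(res$fit$sol, mme, design)
    comp <- VarianceComponents(G = res$G, P = res$P,
                               residual = if (spec@residualMode == "homogeneous")
                                   res$v else vClass,
                               weights = weights)
    new("RRMFit", spec = spec, components = comp,
        fixed = lab$fixed, a = lab$a, pe = lab$pe,
        logLik = res$logL, nIter = res$nIter, converged = res$converged,
        rankX = design@rankX, nRecords = length(design@y),
        residuals = res$stats$resid,
        residualClass = design@residualClass,
        edfModel = res$stats$edf,
        leverage = res$stats$leverage,
        vClassTable = vTab,
        history = res$history)
}

# Per-class residual variances by the leverage-exact moment/EM update
# v_i = (SSE_i + sum of record leverages in class i) / n_i, using
# h_j = x_j' C^-1 x_j from the selected inverse; E[e_hat_j^2] = v_j - h_j, so
# the update is unbiased at the fixed point and, unlike a proportional
# degrees-of-freedom split, stable when leverage varies over the lactation
# (edge DIM classes are fitted much more closely than mid-lactation ones).
.classVariances <- function(res, design, nCls) {
    cls <- design@residualClass
    ni <- tabulate(cls, nCls)
    if (any(ni == 0L))
        stop("empty residual class: ", paste(which(ni == 0L), collapse = ", "))
    vapply(seq_len(nCls), function(i) {
        j <- cls == i
        (sum(res$stats$resid[j]^2) + sum(res$stats$leverage[j])) / ni[i]
    }, numeric(1))
}

#' @rdname RRMFit-class
#' @export
setMethod("varianceComponents", "RRMFit", function(x) x@components)

#' @describeIn RRMFit-class restricted log-likelihood of the fit.
#' @export
setMethod("logLik", "RRMFit", function(object) {
    structure(object@logLik, df = countParameters(object@spec)$p,
              class = "logLik")
})

setMethod("show", "RRMFit", function(object) {
    cat(sprintf("RRMFit: LP%d/LP%d, %s residual\n", object@spec@nr,
                object@spec@np, object@spec@residualMode))
    cat(sprintf("  %d records, rank(X) = %d\n", object@nRecords, object@rankX))
    cat(sprintf("  REML %s after %d iterations, logL = %.3f\n",
                if (object@converged) "converged" else "NOT converged",
                object@nIter, object@logLik))
    show(object@components)
})
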