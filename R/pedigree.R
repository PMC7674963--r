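# Pedigree handling: parsing, parents-before-offspring ordering, inbreeding.

.asUnknown <- function(id) {
    id <- as.character(id)
    id[is.na(id) | id == "" | id == "0"] <- NA_character_
    id
}

#' Construct a pedigree
#'
#' @param animal,sire,dam identifier vectors; `0`, `""` and `NA` in the
#'   parent columns denote an unknown parent.
#' @param birthDate optional `Date` vector.
#' @return a [Pedigree-class].
#' @examples
#' pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' @export
pedigree <- function(animal, sire, dam, birthDate = NULL) {
    new("Pedigree", animal = as.character(animal),
        sire = .asUnknown(sire), dam = .asUnknown(dam),
        birthDate = birthDate)
}

#' Read a pedigree file
#'
#' Reads the common three-column animal-breeding exchange format
#' (animal, sire, dam, optionally a birth date as a fourth column) with `0`
#' or empty fields marking unknown parents.  Both whitespace- and
#' comma-delimited files are accepted.
#'
#' @param path file path.
#' @param sep field separator; `""` (default) splits on whitespace, use
#'   `","` for CSV.  Files with a `animal`/`sire`/`dam` header are detected.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, sep = "") {
    if (!file.exists(path)) stop("pedigree file not found: ", path)
    first <- readLines(path, n = 1L)
    if (sep == "" && grepl(",", first, fixed = TRUE)) sep <- ","
    hasHeader <- grepl("animal", first, ignore.case = TRUE)
    tab <- read.table(path, sep = sep, header = hasHeader,
                      colClasses = "character", strip.white = TRUE)
    if (ncol(tab) < 3L) stop("pedigree file needs at least 3 columns")
    bd <- NULL
    if (ncol(tab) >= 4L) {
        bd <- as.Date(tab[[4L]])
        if (all(is.na(bd))) bd <- NULL
    }
    pedigree(tab[[1L]], tab[[2L]], tab[[3L]], birthDate = bd)
}

#' Write a pedigree file
#'
#' @param ped a [Pedigree-class].
#' @param path output file path (CSV with header; unknown parents written
#'   as 0).
#' @export
writePedigree <- function(ped, path) {
    df <- data.frame(animal = ped@animal,
                     sire = ifelse(is.na(ped@sire), "0", ped@sire),
                     dam = ifelse(is.na(ped@dam), "0", ped@dam),
                     stringsAsFactors = FALSE)
    if (!is.null(ped@birthDate)) df$birth_date <- as.character(ped@birthDate)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Sort a pedigree parents-before-offspring
#'
#' Performs a stable topological (Kahn) sort so that every parent's row
#' precedes all its offspring's rows.  Identifiers appearing only in the
#' parent columns are inserted as founders ahead of the listed animals.
#' Inbreeding coefficients are computed on the sorted pedigree with the
#' Meuwissen-Luo algorithm unless `computeF = FALSE` (all F set to 0, which
#' reproduces the simpler inverse-relationship rules).
#'
#' @param ped a [Pedigree-class].
#' @param computeF logical; compute inbreeding coefficients (default `TRUE`).
#' @return a [SortedPedigree-class].
#' @export
sortPedigree <- function(ped, computeF = TRUE) {
    validObject(ped)
    extras <- setdiff(c(ped@sire, ped@dam), c(ped@animal, NA))
    animal <- c(extras, ped@animal)
    sire <- c(rep(NA_character_, length(extras)), ped@sire)
    dam <- c(rep(NA_character_, length(extras)), ped@dam)
    bd <- if (is.null(ped@birthDate)) NULL else
        c(as.Date(rep(NA, length(extras))), ped@birthDate)
    n <- length(animal)
    idx <- seq_len(n)
    names(idx) <- animal
    si <- unname(idx[sire])
    di <- unname(idx[dam])

    # Kahn's algorithm, stable in the input order
    indeg <- integer(n)
    kids <- vector("list", n)
    for (i in idx) {
        for (p in c(si[i], di[i])) if (!is.na(p)) {
            indeg[i] <- indeg[i] + 1L
            kids[[p]] <- c(kids[[p]], i)
        }
    }
    order <- integer(0)
    avail <- which(indeg == 0L)
    while (length(avail)) {
        i <- avail[1L]
        avail <- avail[-1L]
        order <- c(order, i)
        for (j in kids[[i]]) {
            indeg[j] <- indeg[j] - 1L
            if (indeg[j] == 0L) avail <- sort(c(avail, j))
        }
    }
    if (length(order) < n) {
        onCycle <- animal[setdiff(idx, order)][1L]
        stop("pedigree contains a cycle involving animal ", onCycle)
    }
    pos <- integer(n)
    pos[order] <- seq_len(n)
    sp <- new("SortedPedigree",
              animal = animal[order],
              sire = sire[order], dam = dam[order],
              birthDate = if (is.null(bd)) NULL else bd[order],
              sireIdx = ifelse(is.na(si[order]), NA_integer_, pos[si[order]]),
              damIdx = ifelse(is.na(di[order]), NA_integer_, pos[di[order]]),
              inbreeding = numeric(n))
    if (computeF) sp@inbreeding <- computeInbreeding(sp)
    validObject(sp)
    sp
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' `F_i = a(sire_i, dam_i) / 2`, computed as the ancestral decomposition
#' `1 + F_i = sum_j L_ij^2 d_j` over the ancestors j of i, where d_j is the
#' Mendelian-sampling variance share `0.5 - 0.25 (F_s + F_d)` (0.75 minus a
#' quarter of the known parent's F with one parent unknown; 1 with both
#' unknown).  Founders and animals with an unknown parent get F = 0.
#'
#' @param ped a [SortedPedigree-class].
#' @return numeric vector of inbreeding coefficients, named by animal.
#' @export
computeInbreeding <- function(ped) {
    n <- length(ped@animal)
    si <- ped@sireIdx
    di <- ped@damIdx
    Fv <- numeric(n)
    dv <- numeric(n)
    L <- numeric(n)
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        dv[i] <- if (is.na(s) && is.na(d)) 1 else
                 if (is.na(s)) 0.75 - 0.25 * Fv[d] else
                 if (is.na(d)) 0.75 - 0.25 * Fv[s] else
                 0.5 - 0.25 * (Fv[s] + Fv[d])
        if (is.na(s) || is.na(d)) next  # F = 0
        # accumulate a_ii = sum L_j^2 d_j over touched ancestors
        L[i] <- 1
        touched <- i
        acc <- 0
        while (length(touched)) {
            j <- max(touched)
            touched <- touched[touched != j]
            lj <- L[j]
            L[j] <- 0
            acc <- acc + lj * lj * dv[j]
            for (p in c(si[j], di[j])) if (!is.na(p)) {
                if (L[p] == 0) touched <- c(touched, p)
                L[p] <- L[p] + lj / 2
            }
        }
        Fv[i] <- acc - 1
    }
    names(Fv) <- ped@animal
    Fv
}

#' @rdname SortedPedigree-class
#' @export
setMethod("inbreeding", "SortedPedigree", function(x) x@inbreeding)

#' Sparse inverse numerator relationship matrix
#'
#' Assembles A-inverse directly from the sorted pedigree by Henderson's
#' rules with inbreeding: each animal i contributes `1/d_i` times the
#' (1, -1/2, -1/2) pattern on (i, sire, dam), where
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (adjusted to 0.75 - 0.25 F for one known
#' parent and 1 for none).
#'
#' @param ped a [SortedPedigree-class]; use `sortPedigree(p, computeF =
#'   FALSE)` for the classic rules that ignore inbreeding.
#' @return a sparse symmetric matrix (`Matrix::dsCMatrix`) with animals in
#'   pedigree order; attribute `"logdet"` holds `log det A = sum(log d_i)`
#'   and attribute `"d"` the per-animal Mendelian-sampling variances.
#' @seealso [makeA()] for the dense tabular oracle,
#'   [writeAInverse()] for MatrixMarket export.
#' @export
makeAInverse <- function(ped) {
    n <- length(ped@animal)
    si <- ped@sireIdx
    di <- ped@damIdx
    Fv <- ped@inbreeding
    Fs <- ifelse(is.na(si), 0, Fv[ifelse(is.na(si), 1L, si)])
    Fd <- ifelse(is.na(di), 0, Fv[ifelse(is.na(di), 1L, di)])
    d <- ifelse(is.na(si) & is.na(di), 1,
         ifelse(is.na(si), 0.75 - 0.25 * Fd,
         ifelse(is.na(di), 0.75 - 0.25 * Fs,
                0.5 - 0.25 * (Fs + Fd))))
    ii <- jj <- integer(0)
    xx <- numeric(0)
    addT <- function(i, j, v) {
        ii <<- c(ii, pmax(i, j)); jj <<- c(jj, pmin(i, j)); xx <<- c(xx, v)
    }
    alpha <- 1 / d
    addT(seq_len(n), seq_len(n), alpha)
    hs <- !is.na(si); hd <- !is.na(di)
    addT(which(hs), si[hs], -alpha[hs] / 2)
    addT(which(hd), di[hd], -alpha[hd] / 2)
    addT(si[hs], si[hs], alpha[hs] / 4)
    addT(di[hd], di[hd], alpha[hd] / 4)
    both <- hs & hd
    addT(si[both], di[both], alpha[both] / 4)
    ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n), symmetric = TRUE)
    dimnames(ainv) <- list(ped@animal, ped@animal)
    attr(ainv, "logdet") <- sum(log(d))
    attr(ainv, "d") <- d
    ainv
}

#' Dense numerator relationship matrix (tabular method)
#'
#' The recursive tabular method: `a_ii = 1 + F_i`,
#' `a_ij = (a_{j,s(i)} + a_{j,d(i)}) / 2` for j earlier than i.  Quadratic in
#' the number of animals; intended as an oracle and for small pedigrees.
#'
#' @param ped a [SortedPedigree-class].
#' @param maxAnimals guard against accidental use on large pedigrees.
#' @return dense numeric matrix in pedigree order.
#' @export
makeA <- function(ped, maxAnimals = 2000L) {
    n <- length(ped@animal)
    if (n > maxAnimals)
        stop("pedigree has ", n, " animals; makeA is a dense oracle (limit ",
             maxAnimals, ")")
    si <- ped@sireIdx
    di <- ped@damIdx
    A <- matrix(0, n, n, dimnames = list(ped@animal, ped@animal))
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        if (i > 1L) {
            j <- seq_len(i - 1L)
            row <- (if (is.na(s)) 0 else A[j, s]) / 2 +
                   (if (is.na(d)) 0 else A[j, d]) / 2
            A[j, i] <- A[i, j] <- row
        }
        A[i, i] <- 1 + (if (is.na(s) || is.na(d)) 0 else A[s, d] / 2)
    }
    A
}

#' Export A-inverse in MatrixMarket coordinate format
#'
#' @param ainv matrix from [makeAInverse()].
#' @param path output path (`.mtx`).
#' @export
writeAInverse <- function(ainv, path) {
    Matrix::writeMM(as(ainv, "generalMatrix"), path)
    invisible(path)
}

setMethod("show", "Pedigree", function(object) {
    n <- length(object@animal)
    founders <- sum(is.na(object@sire) & is.na(object@dam))
    cat(sprintf("%s with %d animals (%d founders)\n",
                class(object), n, founders))
    if (is(object, "SortedPedigree"))
        cat(sprintf("  mean inbreeding: %.4f (max %.4f)\n",
                    mean(object@inbreeding), max(object@inbreeding)))
})
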