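# Predictive-ability validation: refit without the last calving year and
# correlate 305-day EBVs from the full and reduced data.

#' Split records by the last calving year
#'
#' The reduced data drop every record of cows whose calving falls in the
#' last calendar year present (a cow-level rule: a late test date alone does
#' not remove a record).  The pedigree is left untouched, so the reduced fit
#' still carries the validation cows through their relatives.
#'
#' @param tdd a [TestDayData-class].
#' @return list with `full` (the input), `reduced` (a [TestDayData-class]),
#'   `validationAnimals` (ids of the cows whose phenotypes were removed) and
#'   `lastYear`.
#' @export
splitByLastCalvingYear <- function(tdd) {
    df <- tdd@records
    year <- as.integer(format(df$calving_date, "%Y"))
    lastYear <- max(year)
    drop <- year == lastYear
    if (all(drop))
        stop("all cows calve in ", lastYear, "; no training data would remain")
    reduced <- new("TestDayData", records = df[!drop, , drop = FALSE],
                   hysMap = tdd@hysMap)
    list(full = tdd, reduced = reduced,
         validationAnimals = unique(df$cow_id[drop]),
         lastYear = lastYear)
}

#' Correlations between full- and reduced-data EBVs
#'
#' Pearson and Spearman correlations of 305-day EBVs over a set of animals
#' (by default the validation animals whose phenotypes were removed).
#'
#' @param ebvFull,ebvReduced named numeric vectors of 305-day EBVs covering
#'   `animals`.
#' @param animals animal ids over which to correlate (at least 3).
#' @return named numeric: `pearson`, `spearman`.
#' @export
predictiveCorrelations <- function(ebvFull, ebvReduced, animals) {
    if (length(animals) < 3L) stop("need at least 3 animals")
    miss <- setdiff(animals, intersect(names(ebvFull), names(ebvReduced)))
    if (length(miss))
        stop("EBVs missing for: ", paste(head(miss, 3L), collapse = ", "))
    x <- ebvFull[animals]
    y <- ebvReduced[animals]
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in an EBV vector")
    c(pearson = cor(x, y), spearman = cor(x, y, method = "spearman"))
}

#' Fit and compare models of several orders
#'
#' Fits the test-day model for each order and residual mode, scores each fit
#' by AIC/BIC, and (optionally) assesses predictive ability by refitting on
#' the data without the last calving year and correlating the 305-day EBVs
#' of the validation cows between the two fits.
#'
#' @param tdd a filtered [TestDayData-class].
#' @param ped pedigree covering all recorded cows.
#' @param orders integer vector of Legendre orders to fit.
#' @param modes residual modes, subset of `c("HO", "HE")`.
#' @param validate logical; run the full/reduced predictive comparison.
#' @param allAnimals correlate over every recorded cow instead of the
#'   validation cows only.
#' @param control [remlControl()] settings.
#' @return list with `scores` (one row per fit, AIC/BIC table),
#'   `predictive` (per fit: Pearson/Spearman correlations and the number of
#'   validation animals; `NULL` unless `validate`) and `fits` (list of
#'   [RRMFit-class] on the full data, named `"HO_1"` etc.).
#' @export
compareOrders <- function(tdd, ped, orders = 1:3, modes = c("HO", "HE"),
                          validate = TRUE, allAnimals = FALSE,
                          control = remlControl()) {
    if (!is(ped, "SortedPedigree")) ped <- sortPedigree(ped)
    if (is.null(tdd@records$hys_class)) tdd <- classifyRecords(tdd)
    split <- if (validate) splitByLastCalvingYear(tdd) else NULL
    scores <- list()
    predictive <- list()
    fits <- list()
    for (mode in modes) for (ord in orders) {
        spec <- rrModelSpec(ord, residual = if (mode == "HE")
            "heterogeneous" else "homogeneous")
        tag <- paste(mode, ord, sep = "_")
        fit <- fitRRM(tdd, ped, spec, control = control)
        fits[[tag]] <- fit
        scores[[tag]] <- modelScores(fit)
        if (validate) {
            redFit <- fitRRM(split$reduced, ped, spec, control = control)
            animals <- if (allAnimals) unique(tdd@records$cow_id)
                       else split$validationAnimals
            pc <- predictiveCorrelations(ebv305(fit), ebv305(redFit), animals)
            predictive[[tag]] <- data.frame(
                mode = mode, order = ord,
                pearson = pc["pearson"], spearman = pc["spearman"],
                n_validation = length(animals), row.names = NULL)
        }
    }
    list(scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
         predictive = if (validate)
             do.call(rbind, c(predictive, list(make.row.names = FALSE)))
         else NULL,
         fits = fits)
}
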