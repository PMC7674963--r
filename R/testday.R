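# Test-day records: parsing, editing rules, fixed-effect class coding.

#' Default residual-class intervals over days in milk
#'
#' The ten inclusive DIM intervals used both for the heterogeneous residual
#' classes and for descriptive statistics: 5-34, 35-64, ..., 275-305 (the
#' last interval is 31 days wide).
#'
#' @return 10 x 2 integer matrix with columns `from`, `to`.
#' @export
dimClassBounds <- function() {
    from <- as.integer(seq(5L, 275L, by = 30L))
    to <- c(from[-1L] - 1L, 305L)
    cbind(from = from, to = to)
}

#' Construct test-day data
#'
#' Builds a [TestDayData-class] from a data.frame.  `calving_date` and
#' `test_date` are parsed as ISO-8601 dates.  When both dates are present,
#' days in milk are recomputed as their difference; if a supplied `dim`
#' column disagrees a warning is issued and the dates win.
#'
#' @param df data.frame with columns `cow_id`, `herd_id`, `calving_date`,
#'   `test_date`, `milk_kg`, `age_at_calving_months` and optionally `dim`.
#' @return a [TestDayData-class].
#' @export
testDayData <- function(df) {
    df <- as.data.frame(df)
    df$cow_id <- as.character(df$cow_id)
    df$herd_id <- as.character(df$herd_id)
    df$calving_date <- as.Date(df$calving_date)
    df$test_date <- as.Date(df$test_date)
    dimDates <- as.integer(df$test_date - df$calving_date)
    if (!is.null(df$dim)) {
        bad <- !is.na(dimDates) & !is.na(df$dim) & df$dim != dimDates
        if (any(bad))
            warning(sum(bad), " record(s) with dim inconsistent with the ",
                    "calving/test dates; recomputed from the dates")
        df$dim <- ifelse(is.na(dimDates), df$dim, dimDates)
    } else df$dim <- dimDates
    df$dim <- as.integer(df$dim)
    df$milk_kg <- as.numeric(df$milk_kg)
    df$age_at_calving_months <- as.integer(df$age_at_calving_months)
    new("TestDayData", records = df,
        hysMap = data.frame(herd = character(0), year = integer(0),
                            season = integer(0), hys_class = integer(0)))
}

#' Read test-day records from CSV
#'
#' @param path CSV file with a header naming at least `cow_id`, `herd_id`,
#'   `calving_date`, `test_date`, `milk_kg` and `age_at_calving_months`
#'   (a `dim` column is cross-checked against the dates).
#' @return a [TestDayData-class].
#' @export
readTestDayRecords <- function(path) {
    if (!file.exists(path)) stop("records file not found: ", path)
    testDayData(read.csv(path, stringsAsFactors = FALSE))
}

#' Write test-day records to CSV
#'
#' @param tdd a [TestDayData-class].
#' @param path output path.
#' @export
writeTestDayRecords <- function(tdd, path) {
    df <- tdd@records
    df$calving_date <- as.character(df$calving_date)
    df$test_date <- as.character(df$test_date)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname TestDayData-class
#' @export
setMethod("records", "TestDayData", function(x) x@records)

#' Number of records / cows
#' @param tdd a [TestDayData-class].
#' @export
nRecords <- function(tdd) nrow(tdd@records)

#' @rdname nRecords
#' @export
nCows <- function(tdd) length(unique(tdd@records$cow_id))

#' Apply the standard editing rules
#'
#' Keeps records with calving age, daily yield and days in milk inside the
#' given inclusive bounds, then drops all records of cows left with fewer
#' than `minTests` records.  The scalar filters are applied first, so the
#' per-cow count refers to the edited data.  The count of records removed by
#' each rule (in application order) is attached as attribute `"audit"`.
#'
#' @param tdd a [TestDayData-class].
#' @param minMilk,maxMilk daily milk yield bounds (kg), default 5 and 80.
#' @param minDIM,maxDIM days-in-milk bounds, default 5 and 305.
#' @param minAge,maxAge age-at-calving bounds (months), default 20 and 38.
#' @param minTests minimum surviving records per cow, default 3.
#' @return the filtered [TestDayData-class] with an `"audit"` attribute.
#' @export
applyFilters <- function(tdd, minMilk = 5, maxMilk = 80,
                         minDIM = 5L, maxDIM = 305L,
                         minAge = 20L, maxAge = 38L, minTests = 3L) {
    df <- tdd@records
    audit <- c(age = 0L, milk = 0L, dim = 0L, min_tests = 0L)

    keep <- !is.na(df$age_at_calving_months) &
        df$age_at_calving_months >= minAge & df$age_at_calving_months <= maxAge
    audit["age"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]

    keep <- !is.na(df$milk_kg) & df$milk_kg >= minMilk & df$milk_kg <= maxMilk
    audit["milk"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]

    keep <- !is.na(df$dim) & df$dim >= minDIM & df$dim <= maxDIM
    audit["dim"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]

    counts <- table(df$cow_id)
    keep <- df$cow_id %in% names(counts)[counts >= minTests]
    audit["min_tests"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]

    out <- new("TestDayData", records = df, hysMap = tdd@hysMap)
    attr(out, "audit") <- audit
    out
}

#' Calving season from calving month
#'
#' Season 1: March, April, May, September, October; season 2: June, July,
#' August; season 3: November, December, January, February.
#'
#' @param month integer month (1-12).
#' @return integer season in 1..3.
#' @export
calvingSeason <- function(month) {
    if (any(is.na(month) | month < 1 | month > 12)) stop("invalid month")
    s <- integer(length(month))
    s[month %in% c(3L, 4L, 5L, 9L, 10L)] <- 1L
    s[month %in% c(6L, 7L, 8L)] <- 2L
    s[month %in% c(11L, 12L, 1L, 2L)] <- 3L
    s
}

#' Calving-age class
#'
#' Four levels: 20-23, 24-27, 28-31, and 32 months or later.
#'
#' @param age integer age at calving in months (>= 20 after editing).
#' @return integer class in 1..4.
#' @export
assignAgeClass <- function(age) {
    if (any(age < 20))
        stop("age below 20 months after filtering; check the pipeline order")
    pmin(4L, (as.integer(age) - 20L) %/% 4L + 1L)
}

#' Residual-variance class from days in milk
#'
#' @param dim integer days in milk within the class range.
#' @param bounds interval matrix as from [dimClassBounds()].
#' @return integer class index (1..10 for the default bounds).
#' @export
assignResidualClass <- function(dim, bounds = dimClassBounds()) {
    if (any(dim < bounds[1L, 1L] | dim > bounds[nrow(bounds), 2L]))
        stop("dim outside the residual-class range")
    findInterval(dim, bounds[, 1L])
}

#' Assign fixed-effect and residual classes
#'
#' Adds to the records: `hys_class`, a dense 1..K re-coding of the observed
#' (herd, calving year, calving season) combinations ordered by herd, year
#' and season; `age_class` (1..4); `dim_class` (the DIM fixed-effect level,
#' equal to DIM itself); and `residual_class` (1..10).  Calving year -- not
#' test year -- defines the year in herd-year-season, consistent with the
#' seasons being calving seasons.
#'
#' @param tdd a filtered [TestDayData-class].
#' @param bounds residual-class intervals, see [dimClassBounds()].
#' @return the classified [TestDayData-class] (slot `hysMap` filled).
#' @export
classifyRecords <- function(tdd, bounds = dimClassBounds()) {
    df <- tdd@records
    year <- as.integer(format(df$calving_date, "%Y"))
    season <- calvingSeason(as.integer(format(df$calving_date, "%m")))
    key <- paste(df$herd_id, year, season, sep = "\r")
    combos <- unique(data.frame(herd = df$herd_id, year = year, season = season,
                                key = key, stringsAsFactors = FALSE))
    combos <- combos[order(combos$herd, combos$year, combos$season), ]
    combos$hys_class <- seq_len(nrow(combos))
    df$hys_class <- combos$hys_class[match(key, combos$key)]
    df$age_class <- assignAgeClass(df$age_at_calving_months)
    df$dim_class <- df$dim
    df$residual_class <- assignResidualClass(df$dim, bounds)
    new("TestDayData", records = df,
        hysMap = combos[, c("herd", "year", "season", "hys_class")])
}

setMethod("show", "TestDayData", function(object) {
    df <- object@records
    cat(sprintf("TestDayData: %d records from %d cows in %d herds\n",
                nrow(df), length(unique(df$cow_id)),
                length(unique(df$herd_id))))
    if (nrow(df)) {
        cat(sprintf("  DIM %d..%d, milk %.1f..%.1f kg\n",
                    min(df$dim), max(df$dim),
                    min(df$milk_kg), max(df$milk_kg)))
        if (!is.null(df$hys_class))
            cat(sprintf("  classified: %d herd-year-season classes\n",
                        max(df$hys_class)))
    }
})
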