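test_that("pedigree files parse with unknown-parent sentinels", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("A 0 0", "B 0 0", "C A B"), f)
    ped <- readPedigree(f)
    expect_length(ped@animal, 3L)
    expect_identical(ped@sire, c(NA, NA, "A"))
    expect_identical(ped@dam, c(NA, NA, "B"))

    fc <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("C,A,B", "A,0,0", "B,0,0"), fc)
    ped2 <- readPedigree(fc)          # offspring listed first is accepted
    sp <- sortPedigree(ped2)
    expect_lt(match("A", sp@animal), match("C", sp@animal))
    expect_lt(match("B", sp@animal), match("C", sp@animal))
})

test_that("invalid pedigrees are rejected with clear errors", {
    expect_error(readPedigree("no/such/file.txt"), "not found")
    expect_error(pedigree(c("X", "Y"), c("X", NA), c(NA, NA)), "self-parent")
    expect_error(pedigree(c("X", "X"), c(NA, NA), c(NA, NA)), "duplicate")
})

test_that("pedigree round-trips through write and read", {
    sp <- sortPedigree(pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B")))
    f <- withr::local_tempfile(fileext = ".csv")
    writePedigree(sp, f)
    back <- readPedigree(f)
    expect_identical(back@animal, sp@animal)
    expect_identical(back@sire, sp@sire)
    expect_identical(back@dam, sp@dam)
})

test_that("editing rules drop out-of-bound records then short cows", {
    tdd <- testDayData(rawRecords())
    out <- applyFilters(tdd)
    audit <- attr(out, "audit")
    # c3 (two records, age 19) removed by the age rule; c2 loses one milk
    # record (4 kg) and then its remaining two records by the count rule
    expect_identical(unname(audit["age"]), 2L)
    expect_identical(unname(audit["milk"]), 1L)
    expect_identical(unname(audit["min_tests"]), 2L)
    expect_identical(sort(unique(records(out)$cow_id)), "c1")
    expect_identical(nRecords(out), 3L)
})

test_that("filter bounds are inclusive and filtering is idempotent", {
    df <- rawRecords()[1:3, ]
    df$milk_kg <- c(5, 80, 40)
    df$age_at_calving_months <- c(20L, 38L, 25L)
    df$test_date <- as.character(as.Date(df$calving_date) + c(5L, 305L, 100L))
    out <- applyFilters(testDayData(df))
    expect_identical(nRecords(out), 3L)
    once <- applyFilters(testDayData(rawRecords()))
    twice <- applyFilters(once)
    expect_identical(records(twice), records(once))
    expect_true(all(attr(twice, "audit") == 0L))
})

test_that("records round-trip through write and read", {
    tdd <- classifyRecords(applyFilters(testDayData(rawRecords())))
    f <- withr::local_tempfile(fileext = ".csv")
    writeTestDayRecords(tdd, f)
    back <- readTestDayRecords(f)
    for (col in names(records(tdd)))
        expect_equal(records(back)[[col]], records(tdd)[[col]], label = col)
})

test_that("dim disagreeing with the dates is recomputed with a warning", {
    df <- rawRecords()
    df$dim <- c(10, 40, 71, 15, 45, 75, 20, 50)   # one wrong entry
    expect_warning(tdd <- testDayData(df), "inconsistent")
    expect_identical(records(tdd)$dim[3L], 70L)
})

test_that("calving seasons follow the three-season calendar", {
    expect_identical(calvingSeason(3L), 1L)
    expect_identical(calvingSeason(7L), 2L)
    expect_identical(calvingSeason(1L), 3L)
    expect_identical(calvingSeason(c(4L, 5L, 9L, 10L)), rep(1L, 4L))
    expect_identical(calvingSeason(c(6L, 8L)), c(2L, 2L))
    expect_identical(calvingSeason(c(11L, 12L, 2L)), c(3L, 3L, 3L))
    expect_error(calvingSeason(13L), "invalid month")
})

test_that("age classes split at 24, 28 and 32 months", {
    expect_identical(assignAgeClass(22L), 1L)
    expect_identical(assignAgeClass(c(20L, 23L)), c(1L, 1L))
    expect_identical(assignAgeClass(c(24L, 27L)), c(2L, 2L))
    expect_identical(assignAgeClass(c(28L, 31L)), c(3L, 3L))
    expect_identical(assignAgeClass(c(32L, 38L, 45L)), c(4L, 4L, 4L))
    expect_error(assignAgeClass(19L), "pipeline")
})

test_that("the ten DIM classes partition 5..305", {
    expect_identical(assignResidualClass(5L), 1L)
    expect_identical(assignResidualClass(34L), 1L)
    expect_identical(assignResidualClass(35L), 2L)
    expect_identical(assignResidualClass(305L), 10L)
    cls <- assignResidualClass(5:305)
    expect_identical(sort(unique(cls)), 1:10)
    widths <- table(cls)
    expect_identical(unname(as.integer(widths)), c(rep(30L, 9L), 31L))
    expect_error(assignResidualClass(4L), "range")
})

test_that("herd-year-season coding is a dense bijection", {
    sim <- tinyHerd(seed = 3L, nCows = 30L, nHerds = 3L)
    df <- records(sim$records)
    key <- paste(df$herd_id, format(df$calving_date, "%Y"),
                 calvingSeason(as.integer(format(df$calving_date, "%m"))))
    expect_identical(length(unique(key)), length(unique(df$hys_class)))
    expect_identical(sort(unique(df$hys_class)), seq_len(max(df$hys_class)))
    # same key <-> same class
    expect_identical(length(unique(tapply(df$hys_class, key, unique))),
                     length(unique(key)))
})
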