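# cohort I/O: schema encoding, imputation, stratified splitting.

test_that("schema has 28 well-formed entries and encoding round-trips", {
  sc <- defaultSchema()
  expect_length(sc@entries, 28)
  expect_true(validObject(sc))
  for (f in sc@entries) {
    if (f$kind == "continuous") next
    for (lv in f$levels)
      expect_identical(decodeLevel(sc, f$name, encodeLevel(sc, f$name, lv)),
                       lv)
    expect_equal(sum(f$probs), 1, tolerance = 1e-9)
  }
  # ordinal codes strictly increasing in clinical order
  kinds <- vapply(sc@entries, `[[`, "", "kind")
  for (f in sc@entries[kinds == "ordinal"])
    expect_true(all(diff(f$codes) > 0))
})

test_that("readCohort encodes, flags missing cells and validates", {
  sc <- defaultSchema()
  co <- makeCohort(4, 6, seed = 3)
  csv <- tempfile(fileext = ".csv")
  writeCohortCsv(co, csv, sc)
  back <- readCohort(csv, sc)
  expect_equal(cohortValues(back), cohortValues(co))
  expect_identical(cohortLabels(back), cohortLabels(co))
  expect_false(any(missingMask(back)))

  # blank cell -> missing; categorical cell -> its code
  df <- read.csv(csv, check.names = FALSE, colClasses = "character")
  df$ki67[2] <- ""
  df$lymph_node_status[1] <- "N2"
  write.csv(df, csv, row.names = FALSE, na = "")
  back2 <- readCohort(csv, sc)
  expect_true(missingMask(back2)[2, "ki67"])
  expect_equal(unname(cohortValues(back2)[1, "lymph_node_status"]),
               encodeLevel(sc, "lymph_node_status", "N2"))

  # dropped feature column -> schema error naming it
  df2 <- df[, setdiff(colnames(df), "grading")]
  write.csv(df2, csv, row.names = FALSE, na = "")
  expect_error(readCohort(csv, sc), "grading")

  # out-of-level value -> validation error with the row index
  df$diameter[3] <- "T9"
  write.csv(df, csv, row.names = FALSE, na = "")
  expect_error(readCohort(csv, sc), "row 3")
})

test_that("cohort JSON round-trip preserves values, mask and labels", {
  co <- simulateCohort(simulationConfig(c(5, 9), missingRate = 0.1,
                                        seed = 11))
  path <- tempfile(fileext = ".json")
  saveCohort(co, path)
  back <- loadCohort(path)
  expect_equal(cohortValues(back), unname(cohortValues(co)) -> v0,
               ignore_attr = TRUE)
  expect_identical(missingMask(back)[, 1], missingMask(co)[, 1])
  expect_identical(cohortLabels(back), cohortLabels(co))
  expect_identical(patientIds(back), patientIds(co))
})

test_that("imputation copies from the nearest complete donor", {
  # complete records unchanged
  co <- makeCohort(5, 7, seed = 2)
  expect_identical(cohortValues(imputeMissing(co)), cohortValues(co))

  # zero-distance donor adopted wholesale
  v <- cohortValues(makeCohort(4, 6, seed = 4))
  v2 <- rbind(v, v[3, ])
  v2[nrow(v2), 5] <- NA
  co2 <- clinicalCohort(v2, c(cohortLabels(makeCohort(4, 6, seed = 4)), 0L))
  imp <- imputeMissing(co2)
  expect_equal(cohortValues(imp)[nrow(v2), 5], v[3, 5])

  # donor matches brute-force minimization over scaled observed features
  set.seed(9)
  ref <- matrix(runif(5 * 4), 5, 4)   # 5 complete donors
  rec <- ref[2, ] + c(0.01, -0.02, 0.015, 0)
  rec[4] <- NA
  values <- rbind(rec, ref)
  co3 <- clinicalCohort(values, c(1L, 0L, 1L, 0L, 1L, 0L))
  refCo <- clinicalCohort(ref, c(0L, 1L, 0L, 1L, 0L))
  imp3 <- imputeMissing(co3, refCo)
  lo <- apply(ref, 2, min); hi <- apply(ref, 2, max)
  sc <- function(x) (x - lo) / (hi - lo)
  d <- apply(ref, 1, function(dn)
    sqrt(sum((sc(dn)[1:3] - sc(rec)[1:3])^2)))
  expect_equal(unname(cohortValues(imp3)[1, 4]), ref[which.min(d), 4])

  # idempotence and error without complete donors
  expect_identical(cohortValues(imputeMissing(imp)), cohortValues(imp))
  allMiss <- clinicalCohort(matrix(NA_real_, 3, 2), c(0L, 1L, 0L))
  expect_error(imputeMissing(allMiss), "no complete record")
})

test_that("stratified hold-out follows the round-half-up rule", {
  # the 10-year study sizes: 251/375 at 0.8 -> 501 train (201 + 300)
  co <- clinicalCohort(matrix(rnorm(626 * 3), 626),
                       rep(c(1L, 0L), c(251, 375)), horizon = "10y")
  sp <- stratifiedHoldout(co, 0.8, seed = 5)
  y <- cohortLabels(co)
  expect_length(sp@trainIdx, 501)
  expect_length(sp@testIdx, 125)
  expect_equal(sum(y[sp@trainIdx] == 1L), 201)
  expect_equal(sum(y[sp@testIdx] == 1L), 50)
  expect_equal(sum(y[sp@testIdx] == 0L), 75)

  # 10 patients, 4 positive: 3.2 -> 3 and 4.8 -> 5
  co2 <- clinicalCohort(matrix(rnorm(20), 10), rep(c(1L, 0L), c(4, 6)))
  sp2 <- stratifiedHoldout(co2, 0.8, seed = 1)
  expect_equal(sum(cohortLabels(co2)[sp2@trainIdx] == 1L), 3)
  expect_equal(sum(cohortLabels(co2)[sp2@trainIdx] == 0L), 5)

  # determinism and per-class count invariance across seeds
  expect_identical(stratifiedHoldout(co, 0.8, seed = 7)@trainIdx,
                   stratifiedHoldout(co, 0.8, seed = 7)@trainIdx)
  for (s in 1:5) {
    spx <- stratifiedHoldout(co, 0.65, seed = s)
    expect_equal(sum(y[spx@trainIdx] == 1L), round(0.65 * 251))
    expect_length(c(spx@trainIdx, spx@testIdx), 626)
    expect_length(intersect(spx@trainIdx, spx@testIdx), 0)
  }

  # degenerate partitions rejected
  small <- clinicalCohort(matrix(rnorm(8), 4), c(1L, 1L, 0L, 0L))
  expect_error(stratifiedHoldout(small, 0.9, seed = 1), "split error")
})
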