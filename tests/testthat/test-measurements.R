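test_that("microcurie-to-becquerel conversion is the exact unit definition", {
  expect_identical(toBecquerel(1), 3.7e4)
  expect_equal(toBecquerel(0.620), 2.294e4)
  expect_equal(signif(toBecquerel(1.572), 4), 5.816e4)
  expect_error(toBecquerel(-1), "non-negative")
  expect_error(toBecquerel(Inf), "finite")
  x <- c(0.5, 1.169, 2)
  expect_equal(toMicrocurie(toBecquerel(x)), x)
})

test_that("external-count burdens divide by the retained fraction", {
  expect_equal(burdenFromExternal(0.570, 0.31)$body_burden_uCi, 1.839)
  expect_equal(burdenFromExternal(0.556, 0.31)$body_burden_uCi, 1.794)
  expect_equal(burdenFromExternal(0.620, 0.31)$body_burden_uCi, 2.000)
  # identity at full retention
  expect_equal(burdenFromExternal(0.7, 1.0)$body_burden_uCi, 0.7)
  expect_error(burdenFromExternal(0.5, 0), "retained fraction")
  expect_error(burdenFromExternal(0.5, 1.2), "retained fraction")
  # homogeneous of degree 1 in the measurement, inverse in the fraction
  set.seed(11)
  for (i in 1:10) {
    m <- runif(1, 0.1, 2); rf <- runif(1, 0.2, 1); k <- runif(1, 0.5, 3)
    expect_equal(burdenFromExternal(k * m, rf)$body_burden_Bq,
                 k * burdenFromExternal(m, rf)$body_burden_Bq)
    expect_equal(burdenFromExternal(m, rf)$body_burden_Bq * rf,
                 burdenFromExternal(m, 1)$body_burden_Bq)
  }
})

test_that("paired breath + external burdens are simple sums", {
  expect_equal(burdenFromPaired(1.024, 0.548)$body_burden_uCi, 1.572)
  expect_equal(burdenFromPaired(0.659, 0.510)$body_burden_uCi, 1.169)
  expect_equal(burdenFromPaired(0, 0.9)$body_burden_uCi, 0.9)
  expect_error(burdenFromPaired(-0.1, 0.5), "non-negative")
})

test_that("emanating/retained complement round-trips exactly", {
  expect_equal(emanatingComplement(0.69), 0.31)
  expect_equal(emanatingComplement(0), 1)
  expect_equal(emanatingComplement(0.37), 0.63)
  expect_error(emanatingComplement(1.1), "\\[0, 1\\]")
  x <- seq(0, 1, by = 0.05)
  expect_equal(emanatingComplement(emanatingComplement(x)), x)
  # the historical pair round-trips at full precision
  expect_identical(emanatingComplement(emanatingComplement(0.69)), 0.69)
})

test_that("the bundled measurement history parses into 8 validated records", {
  recs <- parseMeasurementTable()
  expect_equal(nrow(recs), 8)
  expect_s3_class(recs$date, "Date")
  expect_equal(sum(recs$method == "rn_breath_plus_external"), 2)
  # the 1974 record carries its quality flag but is parsed normally
  expect_match(recs$flag[8], "biased low")
})

test_that("measurement table validation names the offending row", {
  # header-only file gives an empty record list
  empty <- writeMeasCSV(parseMeasurementTable()[0, ])
  expect_equal(nrow(parseMeasurementTable(empty)), 0)
  # external-only method without a retained fraction
  bad <- data.frame(date = "1960-01-01", age = 52, method = "tilting_chair",
                    external_uCi = 0.5, breath_uCi = NA, retained_fraction = NA,
                    flag = "")
  expect_error(parseMeasurementTable(writeMeasCSV(bad)),
               "row 1.*retained_fraction")
  # paired method must not carry a retained fraction
  bad2 <- data.frame(date = "1973-01-01", age = 64,
                     method = "rn_breath_plus_external",
                     external_uCi = 0.5, breath_uCi = 0.9,
                     retained_fraction = 0.31, flag = "")
  expect_error(parseMeasurementTable(writeMeasCSV(bad2)), "row 1")
  # unparseable date
  bad3 <- data.frame(date = "Oct 3 1966", age = 58, method = "tilting_chair",
                     external_uCi = 0.5, breath_uCi = NA,
                     retained_fraction = 0.31, flag = "")
  expect_error(parseMeasurementTable(writeMeasCSV(bad3)), "unparseable date")
  # missing required column
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("date,age,method", "1960-01-01,52,tilting_chair"), tmp)
  expect_error(parseMeasurementTable(tmp), "lacks column")
})

test_that("burden estimates agree between uCi and Bq representations", {
  burdens <- computeBurdens(parseMeasurementTable())
  expect_equal(nrow(burdens), 8)
  # Bq column is the exact conversion of the unrounded uCi burden
  paired <- burdens$method == "rn_breath_plus_external"
  expect_equal(burdens$body_burden_Bq[paired],
               toBecquerel(burdens$body_burden_uCi[paired]))
  expect_true(all(burdens$body_burden_Bq >= 0))
})
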