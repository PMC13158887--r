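test_that("two-period schedules encode the post-lip-pointing rate reduction", {
  sch <- buildSchedule("1923-08-01", "1927-08-01", "1927-01-01", 0.01, 5)
  p <- periods(sch)
  expect_equal(nrow(p), 2)
  expect_equal(p$rate_Bq_per_d, c(5, 0.05))
  expect_equal(p$start, as.Date(c("1923-08-01", "1927-01-01")))
  # degenerate work period: empty schedule, zero total intake
  empty <- buildSchedule("1923-08-01", "1923-08-01", "1927-01-01")
  expect_equal(nrow(periods(empty)), 0)
  expect_equal(totalIntake(empty), 0)
  # cutoff before work start: one period entirely at the reduced rate
  pre <- buildSchedule("1923-08-01", "1927-08-01", "1920-01-01", 0.01, 5)
  expect_equal(nrow(periods(pre)), 1)
  expect_equal(periods(pre)$rate_Bq_per_d, 0.05)
  # cutoff at/after work end: single high-rate period
  post <- buildSchedule("1923-08-01", "1927-08-01", "1928-01-01", 0.01, 5)
  expect_equal(periods(post)$rate_Bq_per_d, 5)
  expect_error(buildSchedule("1927-08-01", "1923-08-01", "1927-01-01"),
               "precedes")
  # total intake is the exact calendar integral
  expect_equal(totalIntake(sch),
               5 * as.numeric(as.Date("1927-01-01") - as.Date("1923-08-01")) +
               0.05 * as.numeric(as.Date("1927-08-01") - as.Date("1927-01-01")))
})

test_that("age interpolation is linear between reference sets and clamps at adulthood", {
  model <- loadBiokineticModel()
  p15 <- interpolateParameters(model, 15)
  expect_equal(p15$fA, 0.3)
  expect_equal(p15$matrix["blood", "bone_surface"], 9.0)
  p40 <- interpolateParameters(model, 40)
  expect_equal(p40$fA, 0.2)
  expect_equal(p40$matrix, interpolateParameters(model, 25)$matrix)
  expect_error(interpolateParameters(model, 12), "below the youngest")
  # toy table {15: k=2, 25: k=4} interpolates to k=3 at age 20
  toy <- harnessModel(bloodLoss = 1)
  toy@transfers$rate <- c(2, 4)
  expect_equal(interpolateParameters(toy, 20)$matrix["blood", "excreta"], 3)
  # interpolated alimentary split reflects interpolated fA
  p20 <- interpolateParameters(model, 20)
  expect_equal(p20$fA, 0.25)
  expect_equal(p20$matrix["alimentary", "blood"], 0.25 * 2.0)
})

test_that("a zero-rate schedule solves to identically zero activity", {
  model <- loadBiokineticModel(); chain <- loadChain()
  sch <- buildSchedule("1923-08-01", "1927-08-01", "1927-01-01", 0.01, 0)
  tad <- solveBiokinetics(model, sch, chain, "1908-08-01", "1930-01-01")
  expect_equal(max(abs(activities(tad))), 0)
})

test_that("the solved system is linear in the ingestion rate", {
  model <- loadBiokineticModel(); chain <- loadChain()
  s1 <- buildSchedule("1923-08-01", "1925-08-01", "1925-01-01", 0.01, 1)
  s3 <- buildSchedule("1923-08-01", "1925-08-01", "1925-01-01", 0.01, 3)
  t1 <- solveBiokinetics(model, s1, chain, "1908-08-01", "1926-01-01")
  t3 <- solveBiokinetics(model, s3, chain, "1908-08-01", "1926-01-01")
  expect_equal(activities(t3), 3 * activities(t1), tolerance = 1e-10)
})

test_that("atoms are conserved: body plus sinks equals cumulative intake", {
  # effectively-undecaying nuclide: every ingested atom must still be in a
  # compartment or sink at the end of the solution
  chain <- noDecayChain()
  model <- harnessModel(bloodLoss = 0.1)
  sch <- buildSchedule("1923-08-01", "1924-08-01", "1924-01-01", 0.01, 1)
  tad <- solveBiokinetics(model, sch, chain, "1908-08-01", "1926-01-01")
  lam <- nuclides(chain)$lambda_per_d[1]
  totalAtoms <- sum(tad@atoms[length(timesDays(tad)), , 1])
  intakeAtoms <- totalIntake(sch) / lam
  expect_equal(totalAtoms, intakeAtoms, tolerance = 1e-6)
})

test_that("absorbed fraction controls systemic uptake (mass-balance oracle)", {
  # absorbing blood, no decay: blood activity asymptotes to fA x intake
  chain <- noDecayChain()
  model <- harnessModel(fA15 = 0.3, fA25 = 0.2, bloodLoss = 0)
  sch <- buildSchedule("1950-08-01", "1950-08-02", "1951-01-01", 0.01, 1)
  tad <- solveBiokinetics(model, sch, chain, "1908-08-01", "1952-01-01")
  n <- length(timesDays(tad))
  blood <- activities(tad)[n, "blood", 1]
  expect_equal(blood, 0.2 * totalIntake(sch), tolerance = 1e-8)
})

test_that("chronic intake approaches the closed-form steady state", {
  # one loss route from blood: steady state = fA x rate / loss
  chain <- noDecayChain()
  model <- harnessModel(bloodLoss = 0.05)
  sch <- buildSchedule("1940-01-01", "1970-01-01", "1975-01-01", 0.01, 2)
  tad <- solveBiokinetics(model, sch, chain, "1908-08-01", "1970-01-01")
  n <- length(timesDays(tad))
  blood <- activities(tad)[n, "blood", 1]
  expect_equal(blood, 0.2 * 2 / 0.05, tolerance = 1e-3)
})

test_that("matrix-exponential propagation matches fine-step integration", {
  model <- loadBiokineticModel(); chain <- loadChain()
  sch <- buildSchedule("1923-08-01", "1927-08-01", "1927-01-01", 0.01, 1)
  tad <- solveBiokinetics(model, sch, chain, "1908-08-01", "1930-01-01")
  oracle <- odeBiokinetics(model, sch, chain, "1908-08-01", "1930-01-01")
  n <- length(timesDays(tad))
  for (nuc in colnames(oracle)) {
    got <- tad@atoms[n, , nuc]
    want <- oracle[, nuc]
    keep <- want > 1e-12 * max(want)
    expect_equal(unname(got[keep] / want[keep]), rep(1, sum(keep)),
                 tolerance = 1e-6)
  }
})

test_that("body burden is zero before intake and declines after work ends", {
  tad <- caseUnitTad()
  expect_equal(bodyBurden(tad, as.Date("1915-01-01")), 0)
  expect_equal(bodyBurden(tad, 0), 0)
  tg <- timesDays(tad)
  tEnd <- as.numeric(as.Date("1927-08-01") - as.Date("1908-08-01"))
  bb <- bodyBurden(tad, tg[tg >= tEnd])
  expect_true(all(diff(bb) <= 1e-9 * max(bb)))
  expect_error(bodyBurden(tad, max(tg) + 1000), "outside")
  # body burden equals the compartment-wise Ra-226 total, alimentary included
  i <- which.min(abs(tg - as.numeric(as.Date("1957-10-23") - as.Date("1908-08-01"))))
  expect_equal(bodyBurden(tad, tg[i]),
               sum(activities(tad)[i, compartments(tad@model), "Ra-226"]))
  # decades after intake the alimentary contents contribution is negligible
  sys <- c("blood", "soft_tissue", "bone_surface", "bone_volume")
  expect_equal(bodyBurden(tad, tg[i]), sum(activities(tad)[i, sys, "Ra-226"]),
               tolerance = 1e-6)
})

test_that("the emanating fraction is an output of the radon escape kinetics", {
  tad <- caseUnitTad()
  chain <- loadChain()
  f <- emanatingFraction(tad, chain, as.Date("1957-10-23"))
  expect_gte(f, 0.37)
  expect_lte(f, 0.75)
  # escape switched off: nothing emanates
  model0 <- loadBiokineticModel()
  model0@radonEscape[] <- 0
  sch <- buildSchedule("1923-08-01", "1925-08-01", "1925-01-01", 0.01, 1)
  tad0 <- solveBiokinetics(model0, sch, chain, "1908-08-01", "1926-01-01")
  expect_equal(emanatingFraction(tad0, chain, as.Date("1925-01-01")), 0)
  # radon decay made negligible: essentially all radon escapes
  chainSlow <- decayChain(c("Ra-226", "Rn-222"), c(1600 * 365.25, 1e9),
                          c("alpha", "alpha"))
  tadS <- solveBiokinetics(loadBiokineticModel(), sch, chainSlow,
                           "1908-08-01", "1926-01-01")
  expect_gt(emanatingFraction(tadS, chainSlow, as.Date("1925-06-01")), 0.99)
  # zero production before any intake is an error
  expect_error(emanatingFraction(tad, chain, as.Date("1910-01-01")),
               "zero Rn-222 production")
})

test_that("legacy power-law retention evaluates and is monotone", {
  expect_equal(legacyRetention(123, data.frame(A = 1, b = 0)), 1)
  expect_equal(legacyRetention(4, data.frame(A = 1, b = 0.5)), 0.5)
  tt <- seq(1, 1000, length.out = 50)
  r <- legacyRetention(tt, data.frame(A = c(0.5, 0.5), b = c(0.2, 0.05)))
  expect_true(all(diff(r) <= 0))
  expect_error(legacyRetention(0, data.frame(A = 1, b = 0.5)), "positive")
})
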