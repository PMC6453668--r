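test_that("carrier frequency is a 2-decimal percentage", {
  expect_equal(carrierFrequency(10, 712), 1.40)
  expect_equal(carrierFrequency(0, 500), 0)
  expect_equal(carrierFrequency(500, 500), 100)
  expect_error(carrierFrequency(1, 0), "nTotal")
  expect_error(carrierFrequency(-1, 10), "nCarriers")
  expect_error(carrierFrequency(11, 10), "nCarriers")
})

test_that("odds ratio and Woolf CI match the cross-product formulas", {
  res <- oddsRatioCI(twoByTwo(10, 702, 20, 980))
  expect_equal(res$or, (10 * 980) / (702 * 20), tolerance = 1e-12)
  expect_equal(res$or, 0.698, tolerance = 1e-3)
  o <- woolfOracle(10, 702, 20, 980)
  expect_equal(res$ci_low, unname(o["lo"]), tolerance = 1e-10)
  expect_equal(res$ci_high, unname(o["hi"]), tolerance = 1e-10)
  expect_equal(round(c(res$ci_low, res$ci_high), 3), c(0.325, 1.500))
  expect_false(res$corrected)
})

test_that("OR symmetry: identical rows give OR 1; swapped rows invert", {
  expect_equal(oddsRatioCI(twoByTwo(7, 93, 7, 93))$or, 1)
  set.seed(21)
  for (rep in 1:10) {
    cells <- rpois(4, 40) + 1
    orig <- oddsRatioCI(twoByTwo(cells[1], cells[2], cells[3], cells[4]))
    swap <- oddsRatioCI(twoByTwo(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(orig$or * swap$or, 1, tolerance = 1e-12)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  expect_message(res <- oddsRatioCI(twoByTwo(0, 100, 5, 95)),
                 "Haldane")
  expect_true(res$corrected)
  expect_equal(res$or, (0.5 * 95.5) / (100.5 * 5.5), tolerance = 1e-12)
  expect_error(oddsRatioCI(twoByTwo(0, 0, 0, 0)), "margins")
})

test_that("the 2x2 chi-square matches the expected-count oracle", {
  ident <- chisqTest2x2(twoByTwo(15, 85, 15, 85))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)

  m <- twoByTwo(20, 180, 10, 190)
  res <- chisqTest2x2(m)
  expect_equal(res$chi2, chisqOracle(m), tolerance = 1e-10)
  expect_equal(res$df, 1)
  tr <- chisqTest2x2(t(m))
  expect_equal(tr$chi2, res$chi2, tolerance = 1e-12)

  expect_error(chisqTest2x2(twoByTwo(0, 100, 0, 50)), "margin")
})

test_that("heterogeneity across subgroups is a K x 2 chi-square", {
  same <- heterogeneityTest(c(5, 5), c(500, 500))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  het <- heterogeneityTest(c(5, 25), c(500, 500))
  m <- cbind(c(5, 25), c(495, 475))
  expect_equal(het$chi2, chisqOracle(m), tolerance = 1e-10)
  expect_equal(het$df, 1)

  four <- heterogeneityTest(c(5, 8, 12, 20), c(400, 450, 500, 600))
  expect_equal(four$df, 3)
  expect_error(heterogeneityTest(c(5), c(100)), "2 subgroups")
  expect_error(heterogeneityTest(c(0, 0), c(100, 100)), "margin")
})

test_that("per-group association bundles frequencies, OR, CI and P", {
  res <- associateCarriers(10, 712, 20, 1000)
  expect_s3_class(res, "cnvAssociation")
  expect_equal(res$freq_cases, 1.40)
  expect_equal(res$freq_controls, 2)
  expect_equal(res$or, (10 * 980) / (702 * 20), tolerance = 1e-12)
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  expect_equal(res$p,
               chisqTest2x2(twoByTwo(10, 702, 20, 980))$p,
               tolerance = 1e-12)
})

test_that("Mantel-Haenszel combination degenerates and matches the oracle", {
  t1 <- twoByTwo(10, 702, 20, 980)
  single <- combineGroups(list(t1))
  woolf <- oddsRatioCI(t1)
  expect_equal(single$or, woolf$or, tolerance = 1e-12)
  expect_equal(single$ci_low, woolf$ci_low, tolerance = 1e-12)
  expect_equal(single$ci_high, woolf$ci_high, tolerance = 1e-12)

  twice <- combineGroups(list(t1, t1))
  expect_equal(twice$or, woolf$or, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    strata <- lapply(1:3, function(i) {
      cells <- rpois(4, c(12, 400, 18, 500)) + 1
      twoByTwo(cells[1], cells[2], cells[3], cells[4])
    })
    mine <- combineGroups(strata)
    arr <- array(unlist(lapply(strata, t)), dim = c(2, 2, 3))
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    expect_equal(mine$or, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mine$ci_low, ref$conf.int[1], tolerance = 1e-10)
    expect_equal(mine$ci_high, ref$conf.int[2], tolerance = 1e-10)
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("replication power: null calibration and asymptotic limit", {
  null <- replicationPower(2000, 2000, 0.026, orAlt = 1,
                           nSims = 5000, seed = 61)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(c(null) - 0.05), 3 * se)

  huge <- replicationPower(1e6, 1e6, 0.026, orAlt = 0.5,
                           nSims = 500, seed = 62)
  expect_gt(c(huge), 0.999)

  expect_error(replicationPower(100, 100, 0, 0.5), "pControl")
  expect_error(replicationPower(100, 100, 0.02, -1), "orAlt")
  expect_error(replicationPower(100, 100, 0.02, 0.5, nSims = 10), "nSims")
})

test_that("the vectorised chi-square inside the power loop matches chisqTest2x2", {
  set.seed(71)
  for (rep in 1:20) {
    cells <- rpois(4, c(30, 970, 50, 950)) + 1
    ref <- chisqTest2x2(twoByTwo(cells[1], cells[2], cells[3], cells[4]))
    vec <- targetedCNV:::.chisqP2x2Vec(cells[1], cells[2], cells[3],
                                       cells[4])
    expect_equal(vec, ref$p, tolerance = 1e-12)
  }
})
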