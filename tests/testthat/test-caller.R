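test_that("noiseless signatures are called at the generating copy number", {
  cfg <- noiselessConfig()
  for (cn in 1:3) {
    call <- callCopyNumber(simulateSample(cfg, cn, seed = cn), cfg@interval)
    expect_identical(copyNumber(call), as.integer(cn))
  }
})

test_that("too few SNPs inside the interval gives a flagged no-call", {
  cfg <- SimulationConfig(nSnpsInside = 5L)
  call <- callCopyNumber(simulateSample(cfg, 1, seed = 9), cfg@interval)
  expect_true(isNoCall(call))
  expect_true("INSUFFICIENT_SNPS" %in% qcFlags(call))
})

test_that("LRR/BAF disagreement is a DISCORDANT_EVIDENCE no-call", {
  iv <- CnvInterval("12", 1000, 2000, flankBp = 500)
  # strong upward LRR shift but a clearly diploid BAF pattern with
  # heterozygotes: the channels disagree
  set.seed(5)
  sig <- makeSignal(c(500 + 1:30, 1001 + 1:30, 2001 + 1:30),
                    baf = rep(rep(c(0, 0.5, 1), 10), 3),
                    lrr = c(rnorm(30, 0, 0.05), rnorm(30, 0.4, 0.05),
                            rnorm(30, 0, 0.05)))
  call <- callCopyNumber(sig, iv)
  expect_true(isNoCall(call))
  expect_true("DISCORDANT_EVIDENCE" %in% qcFlags(call))
  # and symmetrically: heterozygous BAFs veto a deletion-like LRR shift
  set.seed(6)
  sigDel <- makeSignal(c(500 + 1:30, 1001 + 1:30, 2001 + 1:30),
                       baf = rep(rep(c(0, 0.5, 1), 10), 3),
                       lrr = c(rnorm(30, 0, 0.05), rnorm(30, -0.66, 0.05),
                               rnorm(30, 0, 0.05)))
  callDel <- callCopyNumber(sigDel, iv)
  expect_true(isNoCall(callDel))
  expect_true("DISCORDANT_EVIDENCE" %in% qcFlags(callDel))
})

test_that("deletions are called through the homozygous-only BAF route", {
  cfg <- SimulationConfig()
  call <- callCopyNumber(simulateSample(cfg, 1, seed = 77), cfg@interval)
  expect_identical(copyNumber(call), 1L)
  expect_true("BAF_UNINFORMATIVE" %in% qcFlags(call))
  expect_lt(call@lrrTest$lrr_delta, 0)
})

test_that("noisy arrays are flagged HIGH_LRR_SD but still called", {
  cfg <- SimulationConfig(lrrNoiseSd = 0.45)
  call <- callCopyNumber(simulateSample(cfg, 2, seed = 15), cfg@interval)
  expect_true("HIGH_LRR_SD" %in% qcFlags(call))
  expect_false(isNoCall(call))
})

test_that("identical inputs give identical calls", {
  cfg <- SimulationConfig()
  s <- simulateSample(cfg, 3, seed = 50)
  c1 <- callCopyNumber(s, cfg@interval)
  c2 <- callCopyNumber(s, cfg@interval)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("cohort calls match the simulator's ground truth", {
  cfg <- SimulationConfig(delFreq = 0.05, dupFreq = 0.10)
  coh <- simulateCohort(cfg, nSamples = 100, seed = 8)
  expect_true(all(c(1L, 3L) %in% coh$labels))
  res <- callCohort(coh$samples, cfg@interval)
  called <- vapply(res$calls, copyNumber, integer(1))
  expect_identical(called, coh$labels)
  expect_identical(res$n_no_call, 0L)
  expect_identical(res$counts$n_total, 100L)
  expect_identical(res$counts$n_del, sum(coh$labels == 1L))
  expect_identical(res$counts$n_dup, sum(coh$labels == 3L))
})

test_that("an all-diploid cohort yields zero carriers", {
  cfg <- SimulationConfig(delFreq = 0, dupFreq = 0)
  coh <- simulateCohort(cfg, nSamples = 20, seed = 2)
  res <- callCohort(coh$samples, cfg@interval)
  expect_identical(res$counts$n_del, 0L)
  expect_identical(res$counts$n_dup, 0L)
})

test_that("a cohort that is entirely no-call warns and reports n_total 0", {
  cfg <- SimulationConfig(nSnpsInside = 3L)
  coh <- simulateCohort(cfg, nSamples = 3, seed = 2)
  expect_warning(res <- callCohort(coh$samples, cfg@interval),
                 "no samples")
  expect_identical(res$counts$n_total, 0L)
  expect_identical(res$n_no_call, 3L)
})

test_that("call accuracy does not increase with BAF noise", {
  accuracyAt <- function(bafSd) {
    cfg <- SimulationConfig(bafNoiseSd = bafSd)
    hits <- 0L; n <- 0L
    for (cn in 1:3) {
      for (i in 1:100) {
        got <- copyNumber(callCopyNumber(
          simulateSample(cfg, cn, seed = 90000 + 1000 * cn + i),
          cfg@interval))
        hits <- hits + identical(got, as.integer(cn))
        n <- n + 1L
      }
    }
    hits / n
  }
  acc <- vapply(c(0.03, 0.10, 0.25), accuracyAt, 0)
  # allow small Monte-Carlo slack on the non-increasing ordering
  expect_gte(acc[1] + 0.03, acc[2])
  expect_gte(acc[2] + 0.03, acc[3])
  expect_gt(acc[1], acc[3])
})
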