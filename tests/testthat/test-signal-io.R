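writeSignalLines <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

header1 <- "Name\tChr\tPosition\tS1.B Allele Freq\tS1.Log R Ratio"

test_that("a well-formed file parses into position-ordered records", {
  tf <- writeSignalLines(c(header1,
                           "rs1\t12\t100\t0.5\t0.1",
                           "rs2\t12\t200\t0.0\t-0.2",
                           "rs3\t12\t300\t1.0\t0.0"))
  sig <- readSignalFile(tf)
  expect_s4_class(sig, "SampleSignal")
  expect_identical(sampleId(sig), "S1")
  expect_identical(nSnps(sig), 3L)
  expect_identical(GenomicRanges::start(snps(sig)), c(100L, 200L, 300L))
  expect_identical(snps(sig)$snpId, c("rs1", "rs2", "rs3"))
  expect_equal(snps(sig)$baf, c(0.5, 0, 1))
  expect_equal(snps(sig)$lrr, c(0.1, -0.2, 0))
})

test_that("unparseable BAF/LRR tokens become missing, record retained", {
  tf <- writeSignalLines(c(header1,
                           "rs1\t12\t100\tNaN\t0.1",
                           "rs2\t12\t200\t\tNA",
                           "rs3\t12\t300\t0.5\tjunk"))
  sig <- readSignalFile(tf)
  expect_identical(nSnps(sig), 3L)
  expect_identical(is.na(snps(sig)$baf), c(TRUE, TRUE, FALSE))
  expect_identical(is.na(snps(sig)$lrr), c(FALSE, TRUE, TRUE))
})

test_that("record order is independent of input row order", {
  shuffled <- writeSignalLines(c(header1,
                                 "rs3\t12\t300\t1.0\t0.0",
                                 "rs1\t12\t100\t0.5\t0.1",
                                 "rs2\t12\t200\t0.0\t-0.2"))
  ordered <- writeSignalLines(c(header1,
                                "rs1\t12\t100\t0.5\t0.1",
                                "rs2\t12\t200\t0.0\t-0.2",
                                "rs3\t12\t300\t1.0\t0.0"))
  expect_equal(readSignalFile(shuffled), readSignalFile(ordered))
})

test_that("format errors name the absent column and reject empty files", {
  noLrr <- writeSignalLines(c("Name\tChr\tPosition\tS1.B Allele Freq",
                              "rs1\t12\t100\t0.5"))
  expect_error(readSignalFile(noLrr, "S1"), "S1\\.Log R Ratio")
  noPos <- writeSignalLines(c("Name\tChr\tS1.B Allele Freq\tS1.Log R Ratio",
                              "rs1\t12\t0.5\t0.1"))
  expect_error(readSignalFile(noPos, "S1"), "Position")
  headerOnly <- writeSignalLines(header1)
  expect_error(readSignalFile(headerOnly), "no data rows")
  empty <- tempfile(); file.create(empty)
  expect_error(readSignalFile(empty), "empty")
})

test_that("multi-sample files select columns by the sample prefix", {
  tf <- writeSignalLines(c(paste0("Name\tChr\tPosition\t",
                                  "A.B Allele Freq\tA.Log R Ratio\t",
                                  "B.B Allele Freq\tB.Log R Ratio"),
                           "rs1\t12\t100\t0.0\t0.1\t0.5\t-0.3"))
  expect_setequal(signalSampleIds(tf), c("A", "B"))
  expect_error(readSignalFile(tf), "2 samples")
  b <- readSignalFile(tf, "B")
  expect_equal(snps(b)$baf, 0.5)
  expect_equal(snps(b)$lrr, -0.3)
})

test_that("signal write/read round-trip is lossless to 6 decimals", {
  cfg <- SimulationConfig()
  s <- simulateSample(cfg, copyNumber = 3, seed = 21, sampleIdent = "RT")
  tf <- tempfile(fileext = ".txt")
  writeSignalFile(s, tf)
  back <- readSignalFile(tf)
  expect_identical(nSnps(back), nSnps(s))
  expect_identical(snps(back)$snpId, snps(s)$snpId)
  expect_identical(GenomicRanges::start(snps(back)),
                   GenomicRanges::start(snps(s)))
  expect_lt(max(abs(snps(back)$baf - snps(s)$baf)), 5e-7)
  expect_lt(max(abs(snps(back)$lrr - snps(s)$lrr)), 5e-7)
})

test_that("calls tables round-trip: NC rows, flags and 6-decimal numerics", {
  cfg <- SimulationConfig()
  iv <- cfg@interval
  good <- callCopyNumber(simulateSample(cfg, 1, seed = 4), iv)
  few <- callCopyNumber(
    simulateSample(SimulationConfig(nSnpsInside = 5L), 2, seed = 4), iv)
  expect_true(isNoCall(few))
  tf <- tempfile(fileext = ".tsv")
  writeCalls(list(good, few), tf)
  tab <- readCalls(tf)
  expect_identical(tab$copy_number, c("1", "NC"))
  expect_match(tab$qc_flags[2], "INSUFFICIENT_SNPS")
  orig <- do.call(rbind, lapply(list(good, few), as.data.frame))
  num <- vapply(orig, is.numeric, TRUE)
  for (col in names(orig)[num])
    expect_equal(tab[[col]], orig[[col]], tolerance = 1e-6)
})

test_that("counts tables validate rows and tolerate empty input", {
  tf <- tempfile()
  writeLines(c("group\tn_total\tn_del\tn_dup",
               "RA_cases\t712\t10\t28"), tf)
  counts <- readCountsTable(tf)
  expect_identical(counts$group, "RA_cases")
  expect_identical(counts$n_total, 712L)
  expect_identical(counts$n_del, 10L)
  expect_identical(counts$n_dup, 28L)

  writeLines(c("group\tn_total\tn_del\tn_dup",
               "bad\t100\t-1\t0"), tf)
  expect_error(readCountsTable(tf), "bad")

  writeLines(c("group\tn_total\tn_del\tn_dup",
               "ok\t100\t1\t2",
               "over\t10\t8\t5"), tf)
  expect_error(readCountsTable(tf), "over")

  writeLines("group\tn_total\tn_del\tn_dup", tf)
  expect_warning(res <- readCountsTable(tf), "empty")
  expect_identical(nrow(res), 0L)
})
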