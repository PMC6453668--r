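## Plain-vector view of a SampleSignal; extracted once per caller entry to
## avoid repeated S4 subsetting on hot paths.
.signalVectors <- function(sample) {
  gr <- sample@snps
  mc <- mcols(gr)
  list(chrom = as.character(S4Vectors::decode(seqnames(gr))),
       pos = start(gr), baf = mc[["baf"]], lrr = mc[["lrr"]])
}

## Logical index vectors for the inside/left/right partitions.
.partitionIdx <- function(v, interval) {
  onChrom <- v$chrom == interval@chrom
  list(inside = onChrom & v$pos >= interval@start & v$pos <= interval@end,
       left = onChrom & v$pos >= interval@start - interval@flankBp &
         v$pos < interval@start,
       right = onChrom & v$pos > interval@end &
         v$pos <= interval@end + interval@flankBp)
}

.flankLrrTestVec <- function(v, interval, minSnps) {
  idx <- .partitionIdx(v, interval)
  lin <- v$lrr[idx$inside]; lin <- lin[!is.na(lin)]
  lle <- v$lrr[idx$left];   lle <- lle[!is.na(lle)]
  lri <- v$lrr[idx$right];  lri <- lri[!is.na(lri)]
  out <- list(p_left = NA_real_, p_right = NA_real_, min_p = NA_real_,
              lrr_delta = NA_real_, n_in = length(lin),
              n_left = length(lle), n_right = length(lri),
              sufficient = FALSE)
  if (min(out$n_in, out$n_left, out$n_right) < minSnps)
    return(out)
  out$p_left <- welchP(lin, lle)
  out$p_right <- welchP(lin, lri)
  out$min_p <- min(out$p_left, out$p_right)
  out$lrr_delta <- mean(lin) - mean(c(lle, lri))
  out$sufficient <- TRUE
  out
}

#' Partition a sample's SNPs into inside, left-flank and right-flank sets
#'
#' Breakpoints are inclusive: inside means `start <= pos <= end`; the left
#' flank is `start - flankBp <= pos < start`, the right flank
#' `end < pos <= end + flankBp`. The three sets are disjoint; SNPs on other
#' chromosomes or beyond the flanks fall in none of them.
#'
#' @param sample a [SampleSignal-class].
#' @param interval a [CnvInterval-class].
#' @return named list of three `GRanges` (`inside`, `left`, `right`), each
#'   with the `snpId`/`baf`/`lrr` metadata columns.
#' @examples
#' cfg <- SimulationConfig()
#' s <- simulateSample(cfg, copyNumber = 2, seed = 1)
#' lengths(partitionSnps(s, cfg@interval))
#' @export
partitionSnps <- function(sample, interval) {
  stopifnot(is(sample, "SampleSignal"), is(interval, "CnvInterval"))
  gr <- snps(sample)
  idx <- .partitionIdx(.signalVectors(sample), interval)
  list(inside = gr[idx$inside], left = gr[idx$left], right = gr[idx$right])
}

## Welch P value with the degenerate-data convention: when both groups have
## (numerically) zero variance the t statistic is undefined; equal means are
## taken as no evidence (P = 1), unequal constant means as infinite evidence
## (P = 0).
welchP <- function(x, y) {
  vx <- if (length(x) > 1L) stats::var(x) else 0
  vy <- if (length(y) > 1L) stats::var(y) else 0
  if (vx <= .Machine$double.eps && vy <= .Machine$double.eps) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)$p.value
}

#' Flanking-window LRR t-tests at a CNV interval
#'
#' Compares LRR values of SNPs inside the known CNV breakpoints to those in
#' each flanking window with a two-sided Welch (unequal-variance)
#' two-sample t-test, and summarises the two tests by their minimum P value
#' — a screening statistic, not an inferential P value (no multiplicity
#' correction). `lrr_delta` is the mean LRR inside minus the mean LRR of
#' both flanks pooled; its sign separates deletion (negative) from
#' duplication (positive). Missing LRR values are excluded per-statistic.
#'
#' If fewer than `minSnps` non-missing LRR values are available inside or in
#' either flank, the result carries `sufficient = FALSE` with `NA`
#' statistics; [callCopyNumber()] turns this into a no-call.
#'
#' @param sample a [SampleSignal-class].
#' @param interval a [CnvInterval-class].
#' @param minSnps minimum non-missing LRR count per partition (default 10).
#' @return named list: `p_left`, `p_right`, `min_p`, `lrr_delta`, `n_in`,
#'   `n_left`, `n_right`, `sufficient`.
#' @examples
#' cfg <- SimulationConfig()
#' del <- simulateSample(cfg, copyNumber = 1, seed = 7)
#' flankLrrTest(del, cfg@interval)$min_p
#' @export
flankLrrTest <- function(sample, interval, minSnps = 10L) {
  stopifnot(is(sample, "SampleSignal"), is(interval, "CnvInterval"))
  .flankLrrTestVec(.signalVectors(sample), interval, minSnps)
}

#' Sample-level LRR standard deviation
#'
#' The sample standard deviation (n - 1 denominator) of all non-missing LRR
#' values of the sample — the standard array-QC metric: noisy arrays show
#' high LRR SD and their CNV calls warrant review.
#'
#' @param sample a [SampleSignal-class].
#' @return single non-negative number.
#' @examples
#' cfg <- SimulationConfig()
#' lrrSd(simulateSample(cfg, copyNumber = 2, seed = 1))
#' @export
lrrSd <- function(sample) {
  stopifnot(is(sample, "SampleSignal"))
  lrr <- snps(sample)$lrr
  lrr <- lrr[!is.na(lrr)]
  if (length(lrr) < 2L)
    stop("at least 2 non-missing LRR values are required")
  stats::sd(lrr)
}
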