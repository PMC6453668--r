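## Evenly spaced SNP positions tiling the interval and both flanks.
simPositions <- function(config) {
  iv <- config@interval
  list(
    left = round(seq(iv@start - iv@flankBp, iv@start - 1,
                     length.out = config@nSnpsFlank)),
    inside = round(seq(iv@start, iv@end,
                       length.out = config@nSnpsInside)),
    right = round(seq(iv@end + 1, iv@end + iv@flankBp,
                      length.out = config@nSnpsFlank)))
}

## Draw BAF/LRR for n SNPs at a given total copy number. Per SNP the
## population B-allele frequency q is uniform on popBFreqRange; the number
## of B alleles among k copies is Binomial(k, q); BAF is the B fraction
## plus Gaussian noise clamped to [0, 1] (intensity ratios saturate at the
## homozygous clusters).
simChannel <- function(n, k, config, lrrMean) {
  q <- stats::runif(n, config@popBFreqRange[1], config@popBFreqRange[2])
  nB <- stats::rbinom(n, k, q)
  baf <- nB / k + stats::rnorm(n, 0, config@bafNoiseSd)
  baf <- pmin(1, pmax(0, baf))
  lrr <- lrrMean + stats::rnorm(n, 0, config@lrrNoiseSd)
  list(baf = baf, lrr = lrr)
}

#' Simulate one sample's SNP-array signal at the CNV locus
#'
#' Generates a synthetic [SampleSignal-class] with known copy number inside
#' the interval: per inside SNP, a population B-allele frequency `q` is
#' drawn uniformly, `copyNumber` allele copies are each B with probability
#' `q`, and BAF is the B fraction plus Gaussian noise truncated to \[0,1\];
#' LRR is the copy-number's mean shift plus Gaussian noise. Flank SNPs are
#' always diploid. Positions are evenly spaced within the interval and
#' flanks. A fixed `seed` gives identical output on every call.
#'
#' @param config a [SimulationConfig-class].
#' @param copyNumber the true copy number inside the interval (1, 2 or 3).
#' @param seed integer RNG seed.
#' @param sampleIdent sample identifier for the generated signal.
#' @return a [SampleSignal-class].
#' @examples
#' simulateSample(SimulationConfig(), copyNumber = 1, seed = 42)
#' @export
simulateSample <- function(config, copyNumber, seed,
                           sampleIdent = sprintf("sim_cn%d_seed%d",
                                                 copyNumber, seed)) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(copyNumber) != 1L || is.na(copyNumber) ||
      !copyNumber %in% 1:3)
    stop("'copyNumber' must be 1, 2 or 3")
  set.seed(as.integer(seed))
  pos <- simPositions(config)
  m2 <- config@lrrMeanByCn[["2"]]
  left <- simChannel(length(pos$left), 2L, config, m2)
  inside <- simChannel(length(pos$inside), as.integer(copyNumber), config,
                       config@lrrMeanByCn[[as.character(copyNumber)]])
  right <- simChannel(length(pos$right), 2L, config, m2)
  position <- c(pos$left, pos$inside, pos$right)
  ## positions are strictly increasing by construction, so the (already
  ## validated) record-order invariant holds and the validity re-check is
  ## skipped for speed
  gr <- GRanges(config@interval@chrom, IRanges(start = position, width = 1L))
  mcols(gr) <- DataFrame(snpId = sprintf("snp%04d", seq_along(position)),
                         baf = c(left$baf, inside$baf, right$baf),
                         lrr = c(left$lrr, inside$lrr, right$lrr))
  S4Vectors::new2("SampleSignal", sampleId = as.character(sampleIdent),
                  snps = gr, check = FALSE)
}

#' Simulate a cohort with known copy-number ground truth
#'
#' Each sample's true copy number is drawn independently: 1 with
#' probability `delFreq`, 3 with probability `dupFreq`, otherwise 2.
#' Per-sample child seeds are derived deterministically from the master
#' seed, so the cohort is fully reproducible and individual samples can be
#' regenerated in isolation.
#'
#' @param config a [SimulationConfig-class].
#' @param nSamples number of samples (`>= 1`).
#' @param seed master seed (default `config@seed`).
#' @return named list: `samples` (list of [SampleSignal-class]), `labels`
#'   (integer vector of true copy numbers), `seeds` (per-sample child
#'   seeds).
#' @examples
#' coh <- simulateCohort(SimulationConfig(), nSamples = 5, seed = 1)
#' coh$labels
#' @export
simulateCohort <- function(config, nSamples, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"), nSamples >= 1L)
  set.seed(as.integer(seed))
  u <- stats::runif(nSamples)
  labels <- ifelse(u < config@delFreq, 1L,
                   ifelse(u < config@delFreq + config@dupFreq, 3L, 2L))
  childSeeds <- sample.int(.Machine$integer.max - 1L, nSamples)
  samples <- lapply(seq_len(nSamples), function(i)
    simulateSample(config, labels[i], childSeeds[i],
                   sampleIdent = sprintf("S%05d", i)))
  list(samples = samples, labels = labels, seeds = childSeeds)
}
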