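#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' One sample's per-SNP BAF/LRR signal track
#'
#' `SampleSignal` holds one subject's ordered SNP-array signal at a locus:
#' per-SNP position, B-allele frequency (BAF) and log R ratio (LRR), stored
#' as a [GenomicRanges::GRanges] of width-1 ranges with metadata columns
#' `snpId`, `baf` and `lrr`. Records are kept sorted by (chromosome,
#' position); missing BAF/LRR are `NA` and are dropped per-statistic, not
#' per-record.
#'
#' @slot sampleId single character, the subject/array identifier.
#' @slot snps `GRanges` of width-1 SNP positions with metadata columns
#'   `snpId` (character), `baf` (numeric in \[0,1\] or `NA`) and `lrr`
#'   (numeric or `NA`).
#'
#' @seealso [SampleSignal()] constructor, [readSignalFile()],
#'   [simulateSample()]
#' @export
setClass("SampleSignal",
  slots = c(sampleId = "character", snps = "GRanges"))

setValidity("SampleSignal", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  need <- c("snpId", "baf", "lrr")
  have <- colnames(mcols(object@snps))
  if (!all(need %in% have)) {
    msg <- c(msg, paste0("snps must carry metadata columns: ",
                         paste(setdiff(need, have), collapse = ", ")))
  } else {
    baf <- object@snps$baf
    if (any(!is.na(baf) & (baf < 0 | baf > 1)))
      msg <- c(msg, "non-missing 'baf' values must lie in [0, 1]")
    if (any(GenomicRanges::width(object@snps) != 1L))
      msg <- c(msg, "SNP ranges must have width 1")
    chr <- as.character(S4Vectors::decode(seqnames(object@snps)))
    pos <- start(object@snps)
    ord <- order(chr, pos)
    if (!identical(ord, seq_along(object@snps)))
      msg <- c(msg, "records must be sorted by (chromosome, position)")
    else if (length(pos) > 1L &&
             any(chr[-1] == chr[-length(chr)] &
                 pos[-1] == pos[-length(pos)]))
      msg <- c(msg, "duplicate (chromosome, position) pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' A known CNV locus with flanking windows
#'
#' The target interval for locus-specific copy-number calling: chromosome,
#' inclusive start/end breakpoints (1-based, array-manifest convention: a
#' SNP is inside iff `start <= position <= end`), and the width of the
#' flanking reference windows used by the LRR t-tests (default 350 kb on
#' each side).
#'
#' @slot chrom single character chromosome name.
#' @slot start,end integer-valued breakpoint coordinates in basepairs,
#'   `start < end`, both inclusive.
#' @slot flankBp flank width in basepairs, `> 0`.
#'
#' @seealso [CnvInterval()], [partitionSnps()], [flankLrrTest()]
#' @export
setClass("CnvInterval",
  slots = c(chrom = "character", start = "numeric", end = "numeric",
            flankBp = "numeric"))

setValidity("CnvInterval", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  for (s in c("start", "end", "flankBp")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      msg <- c(msg, sprintf("'%s' must be a single integer-valued number", s))
  }
  if (length(object@start) == 1L && length(object@end) == 1L &&
      isTRUE(object@start >= object@end))
    msg <- c(msg, "'start' must be < 'end'")
  if (length(object@flankBp) == 1L && isTRUE(object@flankBp <= 0))
    msg <- c(msg, "'flankBp' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Decision thresholds for the copy-number caller
#'
#' Tunable cutoffs combined by [callCopyNumber()]. The t-test/fit-ratio
#' method itself states that cutoffs exist without fixing values; the
#' defaults here were calibrated on the package's own simulations (see the
#' methods vignette).
#'
#' @slot pCutoff significance cutoff applied to the minimum flank t-test P
#'   value (default `1e-4`).
#' @slot ratioCutoff minimum BAF fit ratio favouring the non-diploid model
#'   (default `2`; ratios are diploid misfit over non-diploid misfit, so
#'   `>= 1` means the non-diploid model fits at least as well).
#' @slot minSnps minimum number of non-missing LRR observations required in
#'   the inside set and in each flank (default `10`); below it the sample is
#'   a no-call.
#' @slot lrrSdMax sample-level LRR standard-deviation QC ceiling (default
#'   `0.30`); above it the call is still attempted but flagged
#'   `HIGH_LRR_SD` for review.
#' @slot homBafTol half-width of the homozygous BAF window around 0 and 1
#'   (default `0.12`): if every inside BAF falls within it the interval is
#'   homozygous-only, the fit-ratio requirement is waived and the flag
#'   `BAF_UNINFORMATIVE` is recorded.
#' @slot epsilon small positive constant guarding the fit-ratio division on
#'   noiseless data (default `1e-6`).
#'
#' @seealso [CallThresholds()], [callCopyNumber()]
#' @export
setClass("CallThresholds",
  slots = c(pCutoff = "numeric", ratioCutoff = "numeric",
            minSnps = "integer", lrrSdMax = "numeric",
            homBafTol = "numeric", epsilon = "numeric"))

setValidity("CallThresholds", function(object) {
  msg <- character()
  if (!(object@pCutoff > 0 && object@pCutoff < 1))
    msg <- c(msg, "'pCutoff' must lie strictly between 0 and 1")
  if (object@ratioCutoff < 1)
    msg <- c(msg, "'ratioCutoff' must be >= 1")
  if (object@minSnps < 1L)
    msg <- c(msg, "'minSnps' must be >= 1")
  if (object@lrrSdMax <= 0)
    msg <- c(msg, "'lrrSdMax' must be > 0")
  if (object@homBafTol <= 0 || object@homBafTol >= 0.5)
    msg <- c(msg, "'homBafTol' must lie in (0, 0.5)")
  if (object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Generative model configuration for synthetic SNP-array signals
#'
#' Parameters of the signal simulator: locus geometry, SNP density, BAF and
#' LRR noise, per-copy-number LRR mean shifts, the per-SNP population
#' B-allele frequency range, and cohort carrier frequencies.
#'
#' @slot interval the [CnvInterval-class] whose inside/flank geometry the
#'   simulated positions tile.
#' @slot nSnpsInside,nSnpsFlank number of SNPs placed evenly inside the
#'   interval and in each flank.
#' @slot bafNoiseSd,lrrNoiseSd Gaussian noise SDs for BAF (truncated to
#'   \[0,1\]) and LRR; `0` gives exact noiseless signals.
#' @slot lrrMeanByCn named numeric, mean LRR for copy numbers 1, 2, 3
#'   (must be increasing).
#' @slot popBFreqRange range of the uniform per-SNP population B-allele
#'   frequency.
#' @slot delFreq,dupFreq cohort carrier frequencies of the deletion and the
#'   duplication; `delFreq + dupFreq <= 1`.
#' @slot seed default master seed for cohort simulation.
#'
#' @seealso [SimulationConfig()], [simulateSample()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  slots = c(interval = "CnvInterval",
            nSnpsInside = "integer", nSnpsFlank = "integer",
            bafNoiseSd = "numeric", lrrNoiseSd = "numeric",
            lrrMeanByCn = "numeric", popBFreqRange = "numeric",
            delFreq = "numeric", dupFreq = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSnpsInside < 1L || object@nSnpsFlank < 1L)
    msg <- c(msg, "SNP counts must be >= 1")
  if (object@bafNoiseSd < 0 || object@lrrNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  m <- object@lrrMeanByCn
  if (length(m) != 3L || !identical(names(m), c("1", "2", "3")))
    msg <- c(msg, "'lrrMeanByCn' must be named c('1','2','3')")
  else if (!(m[["1"]] < m[["2"]] && m[["2"]] < m[["3"]]))
    msg <- c(msg, "'lrrMeanByCn' must increase with copy number")
  r <- object@popBFreqRange
  if (length(r) != 2L || r[1] < 0 || r[2] > 1 || r[1] > r[2])
    msg <- c(msg, "'popBFreqRange' must be an ordered range within [0, 1]")
  if (object@delFreq < 0 || object@dupFreq < 0 ||
      object@delFreq + object@dupFreq > 1)
    msg <- c(msg, "'delFreq' and 'dupFreq' must be >= 0 and sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' A per-sample copy-number call with its supporting evidence
#'
#' Result of [callCopyNumber()]: the called copy number (1, 2, 3 or
#' `NA` for a no-call), the flanking-window LRR t-test summary, the BAF
#' model fits and fit ratios, the sample-level LRR SD, and QC flags. A
#' no-call always carries at least one flag (`INSUFFICIENT_SNPS` or
#' `DISCORDANT_EVIDENCE`).
#'
#' @slot sampleId single character.
#' @slot copyNumber integer 1, 2 or 3, or `NA_integer_` for a no-call.
#' @slot lrrTest named list with `p_left`, `p_right`, `min_p`, `lrr_delta`
#'   (mean inside LRR minus mean pooled-flank LRR), `n_in`, `n_left`,
#'   `n_right`.
#' @slot bafFit named list with `fit_cn1`, `fit_cn2`, `fit_cn3` (mean
#'   squared distance to the nearest expected BAF cluster), `ratio_del`,
#'   `ratio_dup`, `n_baf`.
#' @slot lrrSd sample standard deviation of all non-missing LRR values.
#' @slot qcFlags character vector of QC flags (possibly empty).
#'
#' @seealso [callCopyNumber()], [writeCalls()]
#' @export
setClass("CnvCall",
  slots = c(sampleId = "character", copyNumber = "integer",
            lrrTest = "list", bafFit = "list",
            lrrSd = "numeric", qcFlags = "character"))

setValidity("CnvCall", function(object) {
  msg <- character()
  cn <- object@copyNumber
  if (length(cn) != 1L || (!is.na(cn) && !cn %in% 1:3))
    msg <- c(msg, "'copyNumber' must be 1, 2, 3 or NA")
  if (is.na(cn) && length(object@qcFlags) == 0L)
    msg <- c(msg, "a no-call must carry at least one QC flag")
  d <- object@lrrTest$lrr_delta
  if (!is.na(cn) && !is.null(d) && !is.na(d)) {
    if (cn == 1L && d >= 0)
      msg <- c(msg, "copy number 1 requires lrr_delta < 0")
    if (cn == 3L && d <= 0)
      msg <- c(msg, "copy number 3 requires lrr_delta > 0")
  }
  if (length(msg)) msg else TRUE
})
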