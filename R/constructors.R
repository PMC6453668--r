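#' Construct a SampleSignal from per-SNP vectors
#'
#' Records are sorted by (chromosome, position) on construction, so the
#' resulting object is independent of input row order. Non-missing BAF must
#' lie in \[0,1\]; `NaN` in `baf`/`lrr` is normalised to `NA`.
#'
#' @param sampleId single character sample identifier.
#' @param snpId character vector of SNP names.
#' @param chrom character vector (or single value, recycled) of chromosome
#'   names.
#' @param position integer-valued 1-based basepair positions.
#' @param baf,lrr numeric vectors; `NA`/`NaN` mark missing values.
#' @return a [SampleSignal-class] object.
#' @examples
#' sig <- SampleSignal("S1", c("rs1", "rs2"), "12",
#'                     c(8000000, 8000500), baf = c(0, 0.5), lrr = c(0, 0.1))
#' nSnps(sig)
#' @export
SampleSignal <- function(sampleId, snpId, chrom, position, baf, lrr) {
  n <- length(position)
  chrom <- rep_len(as.character(chrom), n)
  baf <- as.numeric(baf)
  lrr <- as.numeric(lrr)
  baf[is.nan(baf)] <- NA_real_
  lrr[is.nan(lrr)] <- NA_real_
  if (any(!is.finite(position)) || any(position < 1))
    stop("'position' must be finite and >= 1")
  ord <- order(chrom, position)
  gr <- GRanges(chrom[ord], IRanges(start = position[ord], width = 1L))
  mcols(gr) <- DataFrame(snpId = as.character(snpId)[ord],
                         baf = baf[ord], lrr = lrr[ord])
  new("SampleSignal", sampleId = as.character(sampleId), snps = gr)
}

#' Construct a CnvInterval
#'
#' @param chrom chromosome name.
#' @param start,end inclusive 1-based breakpoint coordinates, `start < end`.
#' @param flankBp flanking-window width in basepairs (default 350 kb).
#' @return a [CnvInterval-class] object.
#' @examples
#' CnvInterval("12", 7999000, 8128000)
#' @export
CnvInterval <- function(chrom, start, end, flankBp = 350000) {
  new("CnvInterval", chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end),
      flankBp = as.numeric(flankBp))
}

#' Construct caller thresholds
#'
#' @param pCutoff,ratioCutoff,minSnps,lrrSdMax,homBafTol,epsilon see
#'   [CallThresholds-class] for meanings and defaults.
#' @return a [CallThresholds-class] object.
#' @examples
#' CallThresholds(pCutoff = 1e-3)
#' @export
CallThresholds <- function(pCutoff = 1e-4, ratioCutoff = 2,
                           minSnps = 10L, lrrSdMax = 0.30,
                           homBafTol = 0.12, epsilon = 1e-6) {
  new("CallThresholds", pCutoff = as.numeric(pCutoff),
      ratioCutoff = as.numeric(ratioCutoff), minSnps = as.integer(minSnps),
      lrrSdMax = as.numeric(lrrSdMax), homBafTol = as.numeric(homBafTol),
      epsilon = as.numeric(epsilon))
}

#' Construct a simulation configuration
#'
#' Defaults encode the study conditions the simulator emulates: a 129-kb
#' interval on chromosome 12 with 350-kb flanks, LRR mean shifts of -0.66
#' (one copy) and +0.40 (three copies) around 0, LRR noise SD 0.20, BAF
#' noise SD 0.03, uniform per-SNP population B-allele frequencies on
#' \[0.05, 0.95\], and cohort carrier frequencies of 1% deletion / 4%
#' duplication.
#'
#' @param interval the target [CnvInterval-class]; the default is an
#'   approximate hg19 12p13.31 locus of 129 kb.
#' @param nSnpsInside,nSnpsFlank SNPs placed inside the interval and in each
#'   flank (defaults 25).
#' @param bafNoiseSd,lrrNoiseSd Gaussian noise SDs (defaults 0.03, 0.20);
#'   `0` gives exact noiseless signals.
#' @param lrrMeanByCn named numeric of mean LRR per copy number.
#' @param popBFreqRange range of the uniform per-SNP population B-allele
#'   frequency.
#' @param delFreq,dupFreq cohort carrier frequencies.
#' @param seed default master seed used by [simulateCohort()].
#' @return a [SimulationConfig-class] object.
#' @examples
#' SimulationConfig(lrrNoiseSd = 0.1)
#' @export
SimulationConfig <- function(interval = CnvInterval("12", 7999000, 8128000),
                             nSnpsInside = 25L, nSnpsFlank = 25L,
                             bafNoiseSd = 0.03, lrrNoiseSd = 0.20,
                             lrrMeanByCn = c("1" = -0.66, "2" = 0,
                                             "3" = 0.40),
                             popBFreqRange = c(0.05, 0.95),
                             delFreq = 0.01, dupFreq = 0.04,
                             seed = 1L) {
  new("SimulationConfig", interval = interval,
      nSnpsInside = as.integer(nSnpsInside),
      nSnpsFlank = as.integer(nSnpsFlank),
      bafNoiseSd = as.numeric(bafNoiseSd),
      lrrNoiseSd = as.numeric(lrrNoiseSd),
      lrrMeanByCn = lrrMeanByCn,
      popBFreqRange = as.numeric(popBFreqRange),
      delFreq = as.numeric(delFreq), dupFreq = as.numeric(dupFreq),
      seed = as.integer(seed))
}

## ---- accessors ----

#' @rdname SampleSignal-class
#' @export
setMethod("sampleId", "SampleSignal", function(x) x@sampleId)

#' @rdname SampleSignal-class
#' @export
setMethod("snps", "SampleSignal", function(x) x@snps)

#' @rdname SampleSignal-class
#' @export
setMethod("nSnps", "SampleSignal", function(x) length(x@snps))

#' @rdname CnvCall-class
#' @export
setMethod("copyNumber", "CnvCall", function(x) x@copyNumber)

#' @rdname CnvCall-class
#' @export
setMethod("qcFlags", "CnvCall", function(x) x@qcFlags)

#' @rdname CnvCall-class
#' @export
setMethod("isNoCall", "CnvCall", function(x) is.na(x@copyNumber))

#' @rdname CnvInterval-class
#' @export
setMethod("flankWidth", "CnvInterval", function(x) x@flankBp)

## ---- show methods ----

setMethod("show", "SampleSignal", function(object) {
  gr <- object@snps
  nb <- sum(!is.na(gr$baf)); nl <- sum(!is.na(gr$lrr))
  cat(sprintf("SampleSignal '%s': %d SNPs on %s\n", object@sampleId,
              length(gr),
              paste(unique(as.character(seqnames(gr))), collapse = ",")))
  if (length(gr))
    cat(sprintf("  positions %s-%s; %d BAF, %d LRR non-missing\n",
                format(min(start(gr)), big.mark = ","),
                format(max(start(gr)), big.mark = ","), nb, nl))
})

setMethod("show", "CnvInterval", function(object) {
  cat(sprintf("CnvInterval %s:%s-%s (%.1f kb), flanks %.0f kb\n",
              object@chrom, format(object@start, big.mark = ","),
              format(object@end, big.mark = ","),
              (object@end - object@start + 1) / 1000,
              object@flankBp / 1000))
})

setMethod("show", "CallThresholds", function(object) {
  cat(sprintf(paste0("CallThresholds: pCutoff=%g, ratioCutoff=%g, ",
                     "minSnps=%d, lrrSdMax=%g, homBafTol=%g\n"),
              object@pCutoff, object@ratioCutoff, object@minSnps,
              object@lrrSdMax, object@homBafTol))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d SNPs inside / %d per flank; ",
                     "BAF SD %g, LRR SD %g\n"),
              object@nSnpsInside, object@nSnpsFlank, object@bafNoiseSd,
              object@lrrNoiseSd))
  cat(sprintf("  LRR means CN1/2/3: %g / %g / %g; del %g%%, dup %g%%\n",
              object@lrrMeanByCn[["1"]], object@lrrMeanByCn[["2"]],
              object@lrrMeanByCn[["3"]], 100 * object@delFreq,
              100 * object@dupFreq))
  show(object@interval)
})

setMethod("show", "CnvCall", function(object) {
  cn <- if (is.na(object@copyNumber)) "NC" else as.character(object@copyNumber)
  cat(sprintf("CnvCall '%s': copy number %s\n", object@sampleId, cn))
  lt <- object@lrrTest; bf <- object@bafFit
  cat(sprintf("  min_p=%.3g  lrr_delta=%+.3f  (n in/left/right: %d/%d/%d)\n",
              lt$min_p, lt$lrr_delta, lt$n_in, lt$n_left, lt$n_right))
  cat(sprintf("  BAF fits CN1/2/3: %.4g/%.4g/%.4g  ratio del/dup: %.3g/%.3g\n",
              bf$fit_cn1, bf$fit_cn2, bf$fit_cn3, bf$ratio_del, bf$ratio_dup))
  cat(sprintf("  lrr_sd=%.3f  flags: %s\n", object@lrrSd,
              if (length(object@qcFlags)) paste(object@qcFlags, collapse = ",")
              else "none"))
})

#' @describeIn CnvCall-class flatten a call into the one-row data.frame
#'   layout of the calls table written by [writeCalls()].
#' @param row.names,optional,... passed through (see
#'   [base::as.data.frame()]).
#' @export
as.data.frame.CnvCall <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  lt <- x@lrrTest; bf <- x@bafFit
  data.frame(
    sample_id = x@sampleId,
    copy_number = if (is.na(x@copyNumber)) "NC"
                  else as.character(x@copyNumber),
    min_p = lt$min_p, lrr_delta = lt$lrr_delta,
    fit_cn1 = bf$fit_cn1, fit_cn2 = bf$fit_cn2, fit_cn3 = bf$fit_cn3,
    ratio_del = bf$ratio_del, ratio_dup = bf$ratio_dup,
    n_snps_in = lt$n_in, n_snps_left = lt$n_left, n_snps_right = lt$n_right,
    lrr_sd = x@lrrSd,
    qc_flags = paste(x@qcFlags, collapse = ","),
    row.names = row.names, stringsAsFactors = FALSE)
}
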