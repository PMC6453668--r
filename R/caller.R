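#' Call the copy number of one sample at a known CNV interval
#'
#' Combines the flanking-window LRR t-tests ([flankLrrTest()]) with the
#' expected-BAF fit ratios ([bafFitRatios()]) into a copy-number call of 1,
#' 2 or 3 (or a no-call). The decision rule:
#'
#' 1. If the sample-level LRR SD exceeds `lrrSdMax`, flag `HIGH_LRR_SD`
#'    (the call is still attempted; the flag marks the sample for review).
#' 2. If any partition has fewer than `minSnps` non-missing LRR values:
#'    no-call, flag `INSUFFICIENT_SNPS`.
#' 3. If every inside BAF lies within `homBafTol` of 0 or 1 the interval is
#'    homozygous-only: BAF cannot separate copy-number states, the flag
#'    `BAF_UNINFORMATIVE` is added and the fit-ratio requirement below is
#'    waived (the call rests on the LRR channel).
#' 4. If `min_p < pCutoff` and `lrr_delta < 0`: copy number 1 when
#'    `ratio_del >= ratioCutoff` or BAF is uninformative; otherwise no-call
#'    with flag `DISCORDANT_EVIDENCE` (the LRR and BAF channels disagree —
#'    the situation resolved by visual review, see [plotSample()]).
#' 5. Symmetrically with `lrr_delta > 0` and `ratio_dup`: copy number 3 or
#'    `DISCORDANT_EVIDENCE`.
#' 6. Otherwise copy number 2.
#'
#' Because the single-copy BAF centers are a subset of the diploid centers,
#' `ratio_del` never exceeds 1 and deletions are in practice called through
#' the homozygous-only route: a one-copy locus shows only homozygous BAFs,
#' so the deletion call is LRR-driven with the BAF pattern acting as a
#' consistency check (heterozygous BAFs inside the interval veto a
#' deletion via `DISCORDANT_EVIDENCE`).
#'
#' @param sample a [SampleSignal-class].
#' @param interval a [CnvInterval-class].
#' @param thresholds a [CallThresholds-class] (defaults via
#'   [CallThresholds()]).
#' @return a [CnvCall-class].
#' @examples
#' cfg <- SimulationConfig()
#' callCopyNumber(simulateSample(cfg, copyNumber = 3, seed = 11),
#'                cfg@interval)
#' @export
callCopyNumber <- function(sample, interval, thresholds = CallThresholds()) {
  stopifnot(is(sample, "SampleSignal"), is(interval, "CnvInterval"),
            is(thresholds, "CallThresholds"))
  flags <- character()
  v <- .signalVectors(sample)

  allLrr <- v$lrr[!is.na(v$lrr)]
  sdv <- if (length(allLrr) >= 2L) stats::sd(allLrr) else NA_real_
  if (!is.na(sdv) && sdv > thresholds@lrrSdMax)
    flags <- c(flags, "HIGH_LRR_SD")

  lt <- .flankLrrTestVec(v, interval, thresholds@minSnps)

  bafs <- v$baf[.partitionIdx(v, interval)$inside]
  bafs <- bafs[!is.na(bafs)]
  if (length(bafs)) {
    bf <- bafFitRatios(bafs, epsilon = thresholds@epsilon)
    bafUninformative <- all(pmin(bafs, 1 - bafs) <= thresholds@homBafTol)
  } else {
    bf <- list(fit_cn1 = NA_real_, fit_cn2 = NA_real_, fit_cn3 = NA_real_,
               ratio_del = NA_real_, ratio_dup = NA_real_, n_baf = 0L)
    bafUninformative <- TRUE
  }
  if (bafUninformative)
    flags <- c(flags, "BAF_UNINFORMATIVE")

  if (!lt$sufficient) {
    flags <- c(flags, "INSUFFICIENT_SNPS")
    cn <- NA_integer_
  } else if (lt$min_p < thresholds@pCutoff && lt$lrr_delta < 0) {
    if (bafUninformative ||
        (!is.na(bf$ratio_del) && bf$ratio_del >= thresholds@ratioCutoff)) {
      cn <- 1L
    } else {
      flags <- c(flags, "DISCORDANT_EVIDENCE")
      cn <- NA_integer_
    }
  } else if (lt$min_p < thresholds@pCutoff && lt$lrr_delta > 0) {
    if (bafUninformative ||
        (!is.na(bf$ratio_dup) && bf$ratio_dup >= thresholds@ratioCutoff)) {
      cn <- 3L
    } else {
      flags <- c(flags, "DISCORDANT_EVIDENCE")
      cn <- NA_integer_
    }
  } else {
    cn <- 2L
  }

  new("CnvCall", sampleId = sampleId(sample), copyNumber = cn,
      lrrTest = lt[c("p_left", "p_right", "min_p", "lrr_delta",
                     "n_in", "n_left", "n_right")],
      bafFit = bf, lrrSd = sdv, qcFlags = flags)
}

#' Genotype a cohort of samples at one CNV interval
#'
#' Applies [callCopyNumber()] to every sample and summarises the cohort:
#' `n_total` counts successfully called samples (no-calls excluded and
#' reported separately), `n_del` the copy-number-1 carriers and `n_dup`
#' the copy-number-3 carriers.
#'
#' @param samples a list of [SampleSignal-class] objects.
#' @param interval a [CnvInterval-class].
#' @param thresholds a [CallThresholds-class].
#' @return named list: `calls` (list of [CnvCall-class]), `table` (the
#'   calls flattened to a data.frame, one row per sample), `counts`
#'   (one-row data.frame with `n_total`, `n_del`, `n_dup`), `n_no_call`.
#' @examples
#' cfg <- SimulationConfig()
#' coh <- simulateCohort(cfg, nSamples = 20, seed = 3)
#' callCohort(coh$samples, cfg@interval)$counts
#' @export
callCohort <- function(samples, interval, thresholds = CallThresholds()) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  calls <- lapply(samples, callCopyNumber, interval = interval,
                  thresholds = thresholds)
  tab <- do.call(rbind, lapply(calls, as.data.frame))
  cns <- vapply(calls, copyNumber, integer(1))
  counts <- data.frame(n_total = sum(!is.na(cns)),
                       n_del = sum(cns == 1L, na.rm = TRUE),
                       n_dup = sum(cns == 3L, na.rm = TRUE))
  if (counts$n_total == 0L)
    warning("no samples were successfully called")
  list(calls = calls, table = tab, counts = counts,
       n_no_call = sum(is.na(cns)))
}
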