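#' Expected BAF cluster centers for a copy-number state
#'
#' Under the allelic-dosage model, a locus with total copy number k places
#' the B-allele frequency of a SNP with i copies of the B allele at i/k, so
#' the expected cluster set is `{i/k : i = 0..k}`: `{0, 1}` for a single
#' copy, `{0, 1/2, 1}` for a diploid interval, `{0, 1/3, 2/3, 1}` for a
#' duplication. The sets are symmetric under `b -> 1 - b`.
#'
#' @param copyNumber integer 1, 2 or 3.
#' @return numeric vector of cluster centers in \[0,1\].
#' @examples
#' expectedBafClusters(3)
#' @export
expectedBafClusters <- function(copyNumber) {
  if (length(copyNumber) != 1L || is.na(copyNumber) ||
      !copyNumber %in% 1:3)
    stop("'copyNumber' must be 1, 2 or 3")
  k <- as.integer(copyNumber)
  (0:k) / k
}

#' BAF model fit: mean squared distance to the nearest cluster center
#'
#' Scores how well observed B-allele frequencies inside a CNV interval match
#' the expected cluster positions of a copy-number state: the mean over
#' SNPs of the squared distance from each BAF to its nearest center of
#' [expectedBafClusters()]. The fit is 0 iff every BAF lies exactly on a
#' center; it is invariant to permutation and to duplication of the input,
#' and mirror-symmetric (`bafFit(1 - b, k) == bafFit(b, k)`).
#'
#' @param bafs numeric vector of BAFs in \[0,1\]; `NA` values are dropped.
#' @param copyNumber integer 1, 2 or 3.
#' @return single non-negative number.
#' @examples
#' bafFit(c(0, 0.5, 1), 2)     # 0: exactly on the diploid centers
#' bafFit(0.5, 1)              # 0.25: nearest single-copy center is 0 or 1
#' @export
bafFit <- function(bafs, copyNumber) {
  bafs <- bafs[!is.na(bafs)]
  if (length(bafs) == 0L)
    stop("'bafs' must contain at least one non-missing value")
  if (any(bafs < 0 | bafs > 1))
    stop("'bafs' must lie in [0, 1]")
  centers <- expectedBafClusters(copyNumber)
  d2 <- outer(bafs, centers, function(b, ctr) (b - ctr)^2)
  mean(apply(d2, 1L, min))
}

#' BAF fits under all three copy-number models and their fit ratios
#'
#' Computes [bafFit()] under copy numbers 1, 2 and 3 and the two fit
#' ratios that orient the evidence against the diploid model:
#' `ratio_del = (fit_cn2 + epsilon) / (fit_cn1 + epsilon)` and
#' `ratio_dup = (fit_cn2 + epsilon) / (fit_cn3 + epsilon)`. A ratio above 1
#' means the non-diploid model fits better than diploid. Because the
#' single-copy centers `{0, 1}` are a subset of the diploid centers,
#' `ratio_del` can never exceed 1: deletions manifest as `ratio_del`
#' near 1 together with a homozygous-only BAF pattern, whereas true
#' diploid intervals with heterozygotes push `ratio_del` toward 0 (see
#' [callCopyNumber()] for how the caller uses this).
#'
#' @param bafs numeric vector of BAFs in \[0,1\]; `NA` values are dropped.
#' @param epsilon small positive constant guarding division on noiseless
#'   data (default `1e-6`).
#' @return named list: `fit_cn1`, `fit_cn2`, `fit_cn3`, `ratio_del`,
#'   `ratio_dup`, `n_baf` (number of BAFs used).
#' @examples
#' bafFitRatios(c(0, 1/3, 2/3, 1))$ratio_dup  # duplication-like pattern
#' @export
bafFitRatios <- function(bafs, epsilon = 1e-6) {
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  bafs <- bafs[!is.na(bafs)]
  if (length(bafs) == 0L)
    stop("'bafs' must contain at least one non-missing value")
  f1 <- bafFit(bafs, 1L)
  f2 <- bafFit(bafs, 2L)
  f3 <- bafFit(bafs, 3L)
  list(fit_cn1 = f1, fit_cn2 = f2, fit_cn3 = f3,
       ratio_del = (f2 + epsilon) / (f1 + epsilon),
       ratio_dup = (f2 + epsilon) / (f3 + epsilon),
       n_baf = length(bafs))
}
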