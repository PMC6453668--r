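#' Carrier frequency as a percentage
#'
#' @param nCarriers carrier count, `0 <= nCarriers <= nTotal`.
#' @param nTotal number of genotyped subjects, `> 0`.
#' @return percentage, rounded to 2 decimals.
#' @examples
#' carrierFrequency(10, 712)   # 1.4
#' @export
carrierFrequency <- function(nCarriers, nTotal) {
  if (any(nTotal <= 0)) stop("'nTotal' must be > 0")
  if (any(nCarriers < 0 | nCarriers > nTotal))
    stop("'nCarriers' must lie in [0, nTotal]")
  round(100 * nCarriers / nTotal, 2)
}

## Coerce to a validated 2x2 matrix: rows = cases/controls,
## cols = carrier/non-carrier.
.as2x2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(is.na(m)) || any(m < 0))
    stop("table cells must be non-negative counts")
  storage.mode(m) <- "double"
  dimnames(m) <- list(group = c("cases", "controls"),
                      status = c("carrier", "non-carrier"))
  m
}

#' Build a carrier-status 2x2 table
#'
#' Dominant (carrier vs non-carrier) coding: `a` carriers among cases, `b`
#' non-carriers among cases, `c` carriers among controls, `d` non-carriers
#' among controls.
#'
#' @param a,b,c,d non-negative counts.
#' @return 2x2 numeric matrix (rows cases/controls, columns
#'   carrier/non-carrier).
#' @examples
#' twoByTwo(10, 702, 20, 980)
#' @export
twoByTwo <- function(a, b, c, d) {
  .as2x2(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))
}

#' Odds ratio with a Woolf confidence interval
#'
#' Point estimate `ad/bc` with the Woolf log-OR interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied first and reported via a message and the `corrected` field.
#'
#' @param table a 2x2 table as from [twoByTwo()].
#' @param confidence confidence level (default 0.95).
#' @return named list: `or`, `ci_low`, `ci_high`, `confidence`,
#'   `corrected`.
#' @examples
#' oddsRatioCI(twoByTwo(10, 702, 20, 980))
#' @export
oddsRatioCI <- function(table, confidence = 0.95) {
  m <- .as2x2(table)
  if (sum(m[1, ]) == 0 && sum(m[2, ]) == 0)
    stop("both margins are empty")
  corrected <- any(m == 0)
  if (corrected) {
    message("zero cell: applying Haldane-Anscombe 0.5 correction")
    m <- m + 0.5
  }
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       confidence = confidence, corrected = corrected)
}

#' Pearson chi-square test on a 2x2 carrier table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom.
#'
#' @param table a 2x2 table as from [twoByTwo()].
#' @return named list: `chi2`, `df`, `p`.
#' @examples
#' chisqTest2x2(twoByTwo(20, 180, 10, 190))
#' @export
chisqTest2x2 <- function(table) {
  m <- .as2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square test undefined: a table margin is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Subgroup heterogeneity test of carrier frequencies
#'
#' K x 2 Pearson chi-square of carrier vs non-carrier counts across K
#' subgroups (df = K - 1): a small P value indicates the subgroups'
#' carrier frequencies differ, arguing against pooling them for
#' association testing.
#'
#' @param nCarriers,nTotals numeric vectors of per-subgroup carrier counts
#'   and totals (same length, `>= 2` subgroups, totals `> 0`).
#' @return named list: `chi2`, `df`, `p`.
#' @examples
#' heterogeneityTest(c(5, 25), c(500, 500))
#' @export
heterogeneityTest <- function(nCarriers, nTotals) {
  if (length(nCarriers) != length(nTotals) || length(nCarriers) < 2L)
    stop("at least 2 subgroups with matching counts are required")
  if (any(nTotals <= 0) || any(nCarriers < 0) || any(nCarriers > nTotals))
    stop("invalid subgroup counts")
  m <- cbind(carrier = nCarriers, non_carrier = nTotals - nCarriers)
  if (any(colSums(m) == 0))
    stop("heterogeneity test undefined: pooled margin is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-group carrier association: frequencies, OR, CI and chi-square
#'
#' The per-cohort association summary: carrier frequencies in cases and
#' controls, the odds ratio with its Woolf confidence interval
#' ([oddsRatioCI()]), and the Pearson chi-square P value
#' ([chisqTest2x2()]).
#'
#' @param nCaseCarriers,nCases carrier count and total among cases.
#' @param nControlCarriers,nControls carrier count and total among
#'   controls.
#' @param confidence confidence level for the OR interval.
#' @return named list of class `cnvAssociation`: `table`, `freq_cases`,
#'   `freq_controls` (percentages), `or`, `ci_low`, `ci_high`, `chi2`,
#'   `p`.
#' @examples
#' associateCarriers(10, 712, 20, 1000)
#' @export
associateCarriers <- function(nCaseCarriers, nCases, nControlCarriers,
                              nControls, confidence = 0.95) {
  tab <- twoByTwo(nCaseCarriers, nCases - nCaseCarriers,
                  nControlCarriers, nControls - nControlCarriers)
  orr <- oddsRatioCI(tab, confidence)
  ch <- chisqTest2x2(tab)
  structure(list(table = tab,
                 freq_cases = carrierFrequency(nCaseCarriers, nCases),
                 freq_controls = carrierFrequency(nControlCarriers,
                                                  nControls),
                 or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
                 chi2 = ch$chi2, p = ch$p),
            class = "cnvAssociation")
}

#' @export
print.cnvAssociation <- function(x, ...) {
  cat(sprintf("carrier frequency: cases %.2f%%, controls %.2f%%\n",
              x$freq_cases, x$freq_controls))
  cat(sprintf("OR %.3f [%.3f-%.3f], chi2 = %.3f, P = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$chi2, x$p))
  invisible(x)
}

#' Mantel-Haenszel combined odds ratio across strata
#'
#' Combines per-cohort 2x2 carrier tables into a common odds ratio by the
#' Mantel-Haenszel estimator, with a Robins-Breslow-Greenland confidence
#' interval and the Cochran-Mantel-Haenszel chi-square test (no continuity
#' correction). With a single stratum this reduces exactly to
#' [oddsRatioCI()] of that table.
#'
#' @param tables list of 2x2 tables as from [twoByTwo()].
#' @param confidence confidence level (default 0.95).
#' @return named list: `or`, `ci_low`, `ci_high`, `chi2`, `p`, `k`
#'   (number of strata).
#' @examples
#' combineGroups(list(twoByTwo(10, 702, 20, 980),
#'                    twoByTwo(8, 492, 12, 688)))
#' @export
combineGroups <- function(tables, confidence = 0.95) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  ms <- lapply(tables, .as2x2)
  a <- vapply(ms, function(m) m[1, 1], 0)
  b <- vapply(ms, function(m) m[1, 2], 0)
  c <- vapply(ms, function(m) m[2, 1], 0)
  d <- vapply(ms, function(m) m[2, 2], 0)
  n <- a + b + c + d
  if (any(n == 0)) stop("empty stratum")

  R <- a * d / n
  S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0)
    stop("Mantel-Haenszel OR undefined: a cross-product sum is zero")
  or <- sum(R) / sum(S)

  ## Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n
  Q <- (b + c) / n
  varLog <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  ciLow <- exp(log(or) - z * sqrt(varLog))
  ciHigh <- exp(log(or) + z * sqrt(varLog))

  ## CMH test statistic
  E <- (a + b) * (a + c) / n
  V <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  chi2 <- sum(a - E)^2 / sum(V)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  list(or = or, ci_low = ciLow, ci_high = ciHigh, chi2 = chi2, p = p,
       k = length(ms))
}

## Vectorised Pearson chi-square P values for 2x2 tables given as cell
## vectors; algebraically identical to chisq.test(correct = FALSE).
## Tables with a zero margin give P = 1 (no evidence).
.chisqP2x2Vec <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, num / den, 0)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Monte-Carlo power to replicate a carrier association
#'
#' Estimates the power of a case-control replication study by simulation:
#' the case carrier probability is derived from the control carrier
#' frequency and the alternative odds ratio via the odds transform
#' (`odds_case = or * odds_control`), carrier counts are drawn binomially
#' for each replicate, the Pearson chi-square test (no continuity
#' correction) is applied, and the rejection fraction at level `alpha` is
#' returned. Replicates with a degenerate margin (no carriers at all)
#' count as non-rejections.
#'
#' @param nCases,nControls cohort sizes.
#' @param pControl control carrier frequency as a fraction in (0, 1).
#' @param orAlt alternative odds ratio (`> 0`); `1` recovers the null.
#' @param alpha significance level (default 0.05).
#' @param nSims number of Monte-Carlo replicates (`>= 100`).
#' @param seed RNG seed.
#' @return power as a fraction in \[0,1\], with the Monte-Carlo standard
#'   error in attribute `"se"`.
#' @examples
#' replicationPower(2000, 2000, pControl = 0.026, orAlt = 0.5,
#'                  nSims = 1000, seed = 1)
#' @export
replicationPower <- function(nCases, nControls, pControl, orAlt,
                             alpha = 0.05, nSims = 10000L, seed = 1L) {
  if (!(pControl > 0 && pControl < 1))
    stop("'pControl' must lie strictly between 0 and 1")
  if (orAlt <= 0) stop("'orAlt' must be > 0")
  if (nSims < 100L) stop("'nSims' must be >= 100")
  oddsCase <- orAlt * pControl / (1 - pControl)
  pCase <- oddsCase / (1 + oddsCase)
  if (pCase <= 0 || pCase >= 1)
    stop("degenerate case carrier probability")
  set.seed(as.integer(seed))
  a <- stats::rbinom(nSims, nCases, pCase)
  c <- stats::rbinom(nSims, nControls, pControl)
  pvals <- .chisqP2x2Vec(a, nCases - a, c, nControls - c)
  power <- mean(pvals < alpha)
  structure(power, se = sqrt(power * (1 - power) / nSims))
}
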