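# Independent textbook implementations used as oracles; kept deliberately
# separate from the package's code paths.

# Welch two-sample two-sided t-test P value from the closed form.
welchOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# Pearson chi-square statistic from expected counts, sum((O-E)^2/E).
chisqOracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Woolf log-OR confidence interval, written out directly.
woolfOracle <- function(a, b, c, d, conf = 0.95) {
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  c(or = exp(lor), lo = exp(lor - z * se), hi = exp(lor + z * se))
}

# Analytic two-proportion power (pooled-variance null SE, unpooled
# alternative SE), the normal approximation matching the chi-square test.
twoPropPowerOracle <- function(n1, n2, p1, p2, alpha = 0.05) {
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- qnorm(1 - alpha / 2)
  pnorm((abs(p1 - p2) - z * se0) / se1)
}

# Hand-built signal track for explicit scenarios.
makeSignal <- function(position, baf, lrr, chrom = "12", id = "T1") {
  SampleSignal(id, sprintf("s%03d", seq_along(position)), chrom,
               position, baf, lrr)
}

# The default test locus (matches SimulationConfig()'s interval).
testInterval <- function() CnvInterval("12", 7999000, 8128000)

noiselessConfig <- function(...) {
  SimulationConfig(bafNoiseSd = 0, lrrNoiseSd = 0, ...)
}
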