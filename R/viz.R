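#' Cumulative LRR series along the chromosome
#'
#' The running sum of LRR in position order — the review statistic whose
#' slope changes sign over a CNV: persistently negative LRR inside a
#' deletion bends the cumulative curve downward, a duplication bends it
#' upward. Missing LRR values are skipped (they contribute nothing and do
#' not appear in the output).
#'
#' @param sample a [SampleSignal-class] with at least one non-missing LRR.
#' @return data.frame with columns `position` and `cum_lrr`.
#' @examples
#' cfg <- SimulationConfig()
#' head(cumulativeLrr(simulateSample(cfg, copyNumber = 1, seed = 2)))
#' @export
cumulativeLrr <- function(sample) {
  stopifnot(is(sample, "SampleSignal"))
  gr <- snps(sample)
  keep <- !is.na(gr$lrr)
  if (!any(keep))
    stop("no non-missing LRR values")
  data.frame(position = start(gr)[keep], cum_lrr = cumsum(gr$lrr[keep]))
}

#' Three-panel BAF / LRR / cumulative-LRR review plot
#'
#' The per-sample adjudication plot used for visual copy-number calls: BAF
#' scatter (top), LRR scatter (middle) and the cumulative LRR curve
#' (bottom) against chromosomal position, with dotted vertical lines at
#' the CNV breakpoints and optional gene-annotation boxes. Intended for
#' manual review of `DISCORDANT_EVIDENCE` no-calls.
#'
#' @param sample a [SampleSignal-class].
#' @param interval a [CnvInterval-class]; breakpoints drawn as dotted
#'   lines.
#' @param path optional output file; `.png` (default), `.pdf` or `.svg`
#'   by extension. When `NULL`, draws on the current device.
#' @param windowBp plotted half-window beyond each breakpoint (default
#'   twice the flank width).
#' @param annotations optional data.frame with columns `label`, `start`,
#'   `end` for gene boxes under the BAF panel.
#' @return the path (or `NULL`), invisibly. The sample is not modified.
#' @examples
#' cfg <- SimulationConfig()
#' s <- simulateSample(cfg, copyNumber = 1, seed = 5)
#' tf <- tempfile(fileext = ".png")
#' plotSample(s, cfg@interval, tf)
#' @export
plotSample <- function(sample, interval, path = NULL,
                       windowBp = 2 * flankWidth(interval),
                       annotations = NULL) {
  stopifnot(is(sample, "SampleSignal"), is(interval, "CnvInterval"))
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           pdf = grDevices::pdf(path, width = 8, height = 9),
           svg = grDevices::svg(path, width = 8, height = 9),
           grDevices::png(path, width = 800, height = 900))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  gr <- snps(sample)
  lo <- interval@start - windowBp
  hi <- interval@end + windowBp
  win <- as.character(seqnames(gr)) == interval@chrom &
    start(gr) >= lo & start(gr) <= hi
  gr <- gr[win]
  pos <- start(gr)
  xlim <- c(lo, hi)
  bp <- c(interval@start, interval@end)

  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1),
                      oma = c(2, 0, 2, 0))
  on.exit(graphics::par(op), add = TRUE)

  graphics::plot(pos, gr$baf, pch = 16, cex = 0.6, col = "grey25",
                 xlim = xlim, ylim = c(0, 1), xlab = "", ylab = "BAF")
  graphics::abline(v = bp, lty = 3)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    for (i in seq_len(nrow(annotations))) {
      graphics::rect(annotations$start[i], -0.02, annotations$end[i],
                     0.02, col = "steelblue", border = NA)
      graphics::text((annotations$start[i] + annotations$end[i]) / 2,
                     0.07, annotations$label[i], cex = 0.7, font = 3)
    }
  }
  graphics::mtext(sampleId(sample), side = 3, outer = TRUE, font = 2)

  graphics::plot(pos, gr$lrr, pch = 16, cex = 0.6, col = "grey25",
                 xlim = xlim, xlab = "", ylab = "LRR")
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(v = bp, lty = 3)

  cl <- cumulativeLrr(sample)
  cl <- cl[cl$position >= lo & cl$position <= hi, ]
  graphics::plot(cl$position, cl$cum_lrr, type = "l", xlim = xlim,
                 xlab = "", ylab = "cumulative LRR")
  graphics::abline(v = bp, lty = 3)
  graphics::mtext(sprintf("position on chr%s (bp)", interval@chrom),
                  side = 1, outer = TRUE)
  invisible(path)
}
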