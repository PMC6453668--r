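## Columns of the PennCNV signal-intensity text dialect.
.BAF_SUFFIX <- ".B Allele Freq"
.LRR_SUFFIX <- ".Log R Ratio"

.readSignalHeader <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header))
    stop("signal file '", path, "' is empty")
  strsplit(header, "\t", fixed = TRUE)[[1]]
}

#' List the sample identifiers present in a signal file
#'
#' A PennCNV-dialect signal file carries one `<sample>.B Allele Freq` /
#' `<sample>.Log R Ratio` column pair per sample; this returns the
#' `<sample>` prefixes.
#'
#' @param path path to a tab-delimited signal file.
#' @return character vector of sample identifiers.
#' @export
signalSampleIds <- function(path) {
  cols <- .readSignalHeader(path)
  bafIds <- sub(paste0("\\Q", .BAF_SUFFIX, "\\E$"), "",
                grep(paste0("\\Q", .BAF_SUFFIX, "\\E$"), cols, value = TRUE))
  lrrIds <- sub(paste0("\\Q", .LRR_SUFFIX, "\\E$"), "",
                grep(paste0("\\Q", .LRR_SUFFIX, "\\E$"), cols, value = TRUE))
  intersect(bafIds, lrrIds)
}

#' Read one sample from a PennCNV-dialect signal-intensity file
#'
#' Parses a tab-delimited signal file with header columns `Name`, `Chr`,
#' `Position` and per-sample `<sample>.B Allele Freq` / `<sample>.Log R
#' Ratio` pairs (multi-sample exports are supported; columns are selected
#' by the `sampleIdent` prefix). Records are returned sorted by position
#' regardless of input row order. BAF/LRR tokens that fail to parse
#' (empty, `NA`, `NaN`, or malformed) are carried as missing values with
#' the record retained; rows with an unparseable position are skipped and
#' the skip count is reported via [message()].
#'
#' @param path path to the signal file.
#' @param sampleIdent sample identifier selecting the column pair; may be
#'   omitted when the file contains exactly one sample.
#' @return a [SampleSignal-class].
#' @examples
#' cfg <- SimulationConfig()
#' s <- simulateSample(cfg, copyNumber = 2, seed = 1, sampleIdent = "S1")
#' tf <- tempfile(fileext = ".txt")
#' writeSignalFile(s, tf)
#' readSignalFile(tf)
#' @export
readSignalFile <- function(path, sampleIdent = NULL) {
  cols <- .readSignalHeader(path)
  for (req in c("Name", "Chr", "Position"))
    if (!req %in% cols)
      stop("signal file '", path, "' lacks required column '", req, "'")
  ids <- signalSampleIds(path)
  if (is.null(sampleIdent)) {
    if (length(ids) != 1L)
      stop("signal file has ", length(ids), " samples (",
           paste(ids, collapse = ", "),
           "); specify 'sampleIdent' to select one")
    sampleIdent <- ids
  }
  bafCol <- paste0(sampleIdent, .BAF_SUFFIX)
  lrrCol <- paste0(sampleIdent, .LRR_SUFFIX)
  for (req in c(bafCol, lrrCol))
    if (!req %in% cols)
      stop("signal file '", path, "' lacks required column '", req, "'")

  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L)
    stop("signal file '", path, "' contains no data rows")
  pos <- suppressWarnings(as.numeric(raw$Position))
  bad <- is.na(pos) | pos < 1 | pos != round(pos)
  if (any(bad))
    message(sum(bad), " row(s) with unparseable position skipped")
  keep <- !bad
  baf <- suppressWarnings(as.numeric(raw[[bafCol]][keep]))
  lrr <- suppressWarnings(as.numeric(raw[[lrrCol]][keep]))
  SampleSignal(sampleId = sampleIdent, snpId = raw$Name[keep],
               chrom = raw$Chr[keep], position = pos[keep],
               baf = baf, lrr = lrr)
}

#' Write samples to a PennCNV-dialect signal-intensity file
#'
#' Writes one or more [SampleSignal-class] objects sharing the same SNP
#' scaffold (identical `Name`/`Chr`/`Position`) to a tab-delimited file
#' with one `<sample>.B Allele Freq` / `<sample>.Log R Ratio` column pair
#' per sample. BAF/LRR are written with 6 decimals; missing values as
#' `NA`.
#'
#' @param samples a [SampleSignal-class] or a list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSignalFile <- function(samples, path) {
  if (is(samples, "SampleSignal")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  ref <- snps(samples[[1]])
  scaffold <- data.frame(Name = ref$snpId,
                         Chr = as.character(seqnames(ref)),
                         Position = start(ref),
                         check.names = FALSE, stringsAsFactors = FALSE)
  out <- scaffold
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  for (s in samples) {
    gr <- snps(s)
    if (!identical(gr$snpId, ref$snpId) ||
        !identical(as.character(seqnames(gr)), scaffold$Chr) ||
        !identical(start(gr), start(ref)))
      stop("all samples must share the same SNP scaffold ",
           "(Name/Chr/Position)")
    out[[paste0(sampleId(s), .BAF_SUFFIX)]] <- fmt(gr$baf)
    out[[paste0(sampleId(s), .LRR_SUFFIX)]] <- fmt(gr$lrr)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a calls table
#'
#' One row per sample with the call and its supporting statistics:
#' `sample_id`, `copy_number` (1|2|3|NC), `min_p`, `lrr_delta`, `fit_cn1`,
#' `fit_cn2`, `fit_cn3`, `ratio_del`, `ratio_dup`, `n_snps_in`,
#' `n_snps_left`, `n_snps_right`, `lrr_sd`, `qc_flags` (comma-joined,
#' empty when none). Numeric fields survive a read-back to at least 6
#' decimals.
#'
#' @param calls a list of [CnvCall-class] objects (e.g. `callCohort()$calls`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalls <- function(calls, path) {
  if (is(calls, "CnvCall")) calls <- list(calls)
  stopifnot(is.list(calls), length(calls) >= 1L)
  tab <- do.call(rbind, lapply(calls, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a calls table written by [writeCalls()]
#'
#' @param path path to the tab-delimited calls table.
#' @return data.frame with the columns documented in [writeCalls()];
#'   `copy_number` as character (`"1"`, `"2"`, `"3"` or `"NC"`),
#'   `qc_flags` as character (empty string when none).
#' @export
readCalls <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(sample_id = "character",
                                          copy_number = "character",
                                          qc_flags = "character"))
  tab$qc_flags[is.na(tab$qc_flags)] <- ""
  tab
}

#' Read a carrier-count table
#'
#' A delimited table with columns `group`, `n_total`, `n_del`, `n_dup`
#' giving, per cohort group, the number of genotyped subjects and the
#' heterozygous-deletion and duplication carrier counts. Each row is
#' validated: counts must be non-negative and `n_del + n_dup <= n_total`.
#'
#' @param path path to the tab-delimited counts table.
#' @return data.frame with one validated row per group (possibly empty,
#'   with a warning).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("group\tn_total\tn_del\tn_dup",
#'              "RA_cases\t712\t10\t28"), tf)
#' readCountsTable(tf)
#' @export
readCountsTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  for (req in c("group", "n_total", "n_del", "n_dup"))
    if (!req %in% names(tab))
      stop("counts table lacks required column '", req, "'")
  if (nrow(tab) == 0L) {
    warning("counts table '", path, "' is empty")
    return(tab)
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (any(is.na(c(r$n_total, r$n_del, r$n_dup))) ||
        r$n_total < 0 || r$n_del < 0 || r$n_dup < 0)
      stop("counts table row ", i, " ('", r$group,
           "'): counts must be non-negative")
    if (r$n_del + r$n_dup > r$n_total)
      stop("counts table row ", i, " ('", r$group,
           "'): n_del + n_dup exceeds n_total")
  }
  tab$group <- as.character(tab$group)
  tab
}
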