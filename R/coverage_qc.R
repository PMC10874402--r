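#' Read alignment summaries from TSV or BAM
#'
#' The QC statistics need only one record per primary alignment: reference
#' span and full read length. The native input is a 5-column TSV
#' (`read_id`, `chrom`, `start`, `end`, `read_length`; 0-based half-open
#' reference span, no header). A BAM file is accepted when Rsamtools is
#' installed; secondary and supplementary alignments are skipped so each
#' read's footprint is counted once.
#'
#' @param path TSV or BAM file.
#' @return data.frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `read_length`.
#' @export
read_alignment_summaries <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package; supply a TSV instead")
    flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isUnmappedQuery = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("qname", "rname", "pos", "qwidth", "cigar"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    ref_width <- GenomicAlignments_width(b$cigar)
    return(data.frame(read_id = b$qname, chrom = as.character(b$rname),
                      start = b$pos - 1, end = b$pos - 1 + ref_width,
                      read_length = b$qwidth, stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("read_id", "chrom", "start", "end",
                                        "read_length"),
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "numeric"))
  if (any(df$start >= df$end)) stop("alignment with start >= end")
  df
}

## reference width from CIGAR without importing GenomicAlignments
GenomicAlignments_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(x) {
    n <- as.numeric(sub("[A-Z=]$", "", x))
    op <- sub("^\\d+", "", x)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0)
}

#' Classify alignments as on- or off-target
#'
#' An alignment is on-target iff its reference span overlaps the target
#' set by at least one base (half-open abutment does not count).
#'
#' @param alns Alignment summary data.frame (see
#'   [read_alignment_summaries()]).
#' @param targets A `region_set`.
#' @return Character vector `"on_target"`/`"off_target"`, one per
#'   alignment.
#' @export
classify_read <- function(alns, targets) {
  hit <- region_overlaps(alns$chrom, alns$start, alns$end, targets, margin = 0)
  ifelse(hit, "on_target", "off_target")
}

#' Mean per-base depth of a region set
#'
#' Total aligned bases falling inside the (normalized) regions divided by
#' the region size.
#'
#' @param alns Alignment summary data.frame.
#' @param regions A `region_set` with `total_bp > 0`.
#' @return Mean depth (x).
#' @export
mean_depth <- function(alns, regions) {
  regions <- merge(regions)
  tb <- total_bp(regions)
  if (tb == 0) stop("mean depth undefined: regions cover 0 bp")
  if (nrow(alns) == 0L) return(0)
  sum(overlap_bp(alns$chrom, alns$start, alns$end, regions)) / tb
}

#' N50 of a set of lengths
#'
#' The largest length L such that pieces of length >= L together contain
#' at least half of all bases (descending cumulative sum crossing
#' total/2).
#'
#' @param lengths Numeric vector of positive lengths (non-empty).
#' @return N50 in the units of `lengths`.
#' @examples
#' n50(c(1, 2, 3, 4, 5))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("N50 of an empty length set is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Adaptive-sampling QC summary for one sample
#'
#' Combines read classification, mean on/off-target depth (off-target =
#' genome complement of the targets over the supplied chromosome sizes),
#' per-class N50 and the enrichment ratio. With zero off-target depth the
#' enrichment is reported as `Inf` with a warning.
#'
#' @param alns Alignment summary data.frame.
#' @param targets Target `region_set`.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n50_on What to compute N50 over: full `"read_length"` (default)
#'   or aligned `"aligned_length"` spans.
#' @return A `coverage_summary` list: `on_target_depth`,
#'   `off_target_depth`, `enrichment`, `on_target_n50`, `off_target_n50`,
#'   `n_reads_on`, `n_reads_off`.
#' @export
summarize_sample <- function(alns, targets, chrom_sizes,
                             n50_on = c("read_length", "aligned_length")) {
  n50_on <- match.arg(n50_on)
  targets <- merge(targets)
  offt <- complement_regions(targets, chrom_sizes)
  cls <- classify_read(alns, targets)
  on <- alns[cls == "on_target", , drop = FALSE]
  off <- alns[cls == "off_target", , drop = FALSE]
  lens <- function(df) if (n50_on == "read_length") df$read_length else df$end - df$start
  on_depth <- mean_depth(alns, targets)
  off_depth <- mean_depth(alns, offt)
  if (off_depth == 0) {
    warning("no off-target coverage: enrichment reported as Inf")
    enr <- Inf
  } else enr <- on_depth / off_depth
  structure(list(
    on_target_depth = on_depth,
    off_target_depth = off_depth,
    enrichment = enr,
    on_target_n50 = if (nrow(on)) n50(lens(on)) else NA_real_,
    off_target_n50 = if (nrow(off)) n50(lens(off)) else NA_real_,
    n_reads_on = nrow(on),
    n_reads_off = nrow(off)), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "coverage_summary: on-target %.2fx (%d reads, N50 %s), ",
    "off-target %.3fx (%d reads, N50 %s), enrichment %.2f\n"),
    x$on_target_depth, x$n_reads_on, format_bp(x$on_target_n50),
    x$off_target_depth, x$n_reads_off, format_bp(x$off_target_n50),
    x$enrichment))
  invisible(x)
}
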