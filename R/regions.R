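#' Genomic region sets (0-based half-open)
#'
#' A `region_set` is the coordinate container used throughout the package:
#' a set of genomic intervals with 0-based half-open coordinates (the BED
#' convention) plus a purpose label (`targets`, `simple_repeats`, `segdups`,
#' `gene_spans`, ...). All interval algebra (merging, overlap queries,
#' complements) is delegated to IRanges/GenomicRanges internally; 1-based
#' values from VCF/GTF or printed text are converted only at the I/O
#' boundary (see [printed_to_internal()]).
#'
#' @param chrom Character vector of chromosome names (exact string match is
#'   used everywhere: `"chr6"` and `"6"` are different sequences).
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, 0-based exclusive ends; `start < end` required.
#' @param strand Optional character vector in `+`, `-`, `*` (unstranded).
#' @param label Purpose tag for the set.
#' @return An object of class `region_set`: a list with elements `chrom`,
#'   `start`, `end`, `strand` (parallel vectors) and `label`.
#' @examples
#' rs <- region_set("chr1", c(0L, 5L), c(10L, 15L))
#' total_bp(merge(rs))
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), strand = NULL, label = "regions") {
  n <- length(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0L) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
      stop("interval coordinates must not be NA")
    if (any(start < 0)) stop("start positions must be >= 0")
    bad <- which(start >= end)
    if (length(bad))
      stop(sprintf("zero- or negative-length interval at record %d (start %s >= end %s)",
                   bad[1L], format(start[bad[1L]], scientific = FALSE),
                   format(end[bad[1L]], scientific = FALSE)))
  }
  if (is.null(strand)) strand <- rep("*", n)
  strand <- as.character(strand)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand, label = label),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d intervals, %s bp\n",
              x$label, length(x$chrom),
              format(total_bp(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$chrom)

#' @export
as.data.frame.region_set <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             strand = x$strand, stringsAsFactors = FALSE)
}

## internal: region_set <-> GRanges (the only two places 0-based half-open
## meets 1-based closed)
rs_to_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1, end = rs$end),
    strand = rs$strand)
}

granges_to_rs <- function(gr, label = "regions") {
  region_set(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             label = label)
}

#' Total base pairs covered by a region set
#'
#' Sum of `end - start` over intervals. Equals the per-base union size only
#' after [merge.region_set()].
#' @param rs A `region_set`.
#' @return Numeric scalar (bp).
#' @export
total_bp <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  sum(rs$end - rs$start)
}

#' Merge a region set to its minimal sorted non-overlapping cover
#'
#' @param x A `region_set`.
#' @param ... Ignored.
#' @return A normalized `region_set` (sorted, per-chromosome
#'   non-overlapping); idempotent, order-independent. Strand is dropped
#'   (`*`): merging is strand-blind, as for a sequencing target list.
#' @export
merge.region_set <- function(x, ...) {
  if (length(x) == 0L) return(x)
  gr <- GenomicRanges::reduce(rs_to_granges(x), ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  granges_to_rs(gr, label = x$label)
}

#' Overlap query with symmetric margin
#'
#' Tests whether query intervals intersect a region set after expanding
#' every region by `margin` bp on both sides (equivalently, expanding the
#' query: the relation is symmetric in the margin).
#'
#' @param chrom,start,end Parallel vectors describing query intervals,
#'   0-based half-open.
#' @param rs A `region_set`.
#' @param margin Non-negative expansion in bp (default 0).
#' @return Logical vector, one element per query interval.
#' @export
region_overlaps <- function(chrom, start, end, rs, margin = 0) {
  stopifnot(inherits(rs, "region_set"))
  if (length(margin) != 1L || is.na(margin) || margin < 0)
    stop("margin must be a single non-negative number")
  n <- length(chrom)
  if (n == 0L) return(logical(0))
  if (length(rs) == 0L) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
  s <- rs_to_granges(rs)
  if (margin > 0) {
    s <- GenomicRanges::trim(suppressWarnings(s + margin))
    s <- GenomicRanges::restrict(s, start = 1L)
  }
  ## distinct seqlevel sets between query and subject are routine here
  suppressWarnings(IRanges::overlapsAny(q, s, ignore.strand = TRUE))
}

#' Point-in-region membership
#'
#' Convenience wrapper over [region_overlaps()] for single 1-based
#' positions (VCF-style).
#' @param chrom,pos Parallel vectors; `pos` is 1-based.
#' @param rs A `region_set`.
#' @param margin Expansion in bp.
#' @return Logical vector.
#' @export
position_in_regions <- function(chrom, pos, rs, margin = 0) {
  region_overlaps(chrom, pos - 1, pos, rs, margin = margin)
}

#' Read a BED file into a region_set
#'
#' Accepts 3+ column BED. Coordinates are kept in BED's native 0-based
#' half-open convention. Records with `start >= end` and malformed lines
#' are rejected with the offending line number. Strand is taken from
#' column 6 when present, `*` otherwise.
#'
#' @param path Path to a BED file.
#' @param label Purpose tag for the returned set.
#' @return A `region_set`.
#' @export
read_bed <- function(path, label = "regions") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(region_set(label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3L)[1L]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)))
    stop(sprintf("malformed BED line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1L]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("rejected BED record at line %d: start >= end", bad[1L]))
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  region_set(chrom, start, end, strand, label = label)
}

#' Write a region_set as BED
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @param name Optional name column (recycled); when given, a 6-column BED
#'   is written (name, score 0, strand).
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path, name = NULL) {
  stopifnot(inherits(rs, "region_set"))
  if (is.null(name)) {
    df <- data.frame(rs$chrom, format_bp(rs$start), format_bp(rs$end))
  } else {
    df <- data.frame(rs$chrom, format_bp(rs$start), format_bp(rs$end),
                     rep_len(name, length(rs)), 0L, rs$strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Genome complement of a region set
#'
#' @param rs A `region_set`.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return A normalized `region_set` covering every base of the listed
#'   chromosomes not covered by `rs`.
#' @export
complement_regions <- function(rs, chrom_sizes) {
  stopifnot(inherits(rs, "region_set"))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  rs <- merge(rs)
  out_chrom <- character(); out_start <- numeric(); out_end <- numeric()
  for (chr in names(chrom_sizes)) {
    len <- chrom_sizes[[chr]]
    sel <- rs$chrom == chr
    starts <- rs$start[sel]; ends <- pmin(rs$end[sel], len)
    keep <- starts < len
    starts <- starts[keep]; ends <- ends[keep]
    gaps_start <- c(0, ends)
    gaps_end <- c(starts, len)
    ok <- gaps_start < gaps_end
    out_chrom <- c(out_chrom, rep(chr, sum(ok)))
    out_start <- c(out_start, gaps_start[ok])
    out_end <- c(out_end, gaps_end[ok])
  }
  region_set(out_chrom, out_start, out_end,
             label = paste0("complement_of_", rs$label))
}

#' Per-interval overlap width against a region set
#'
#' For each query interval, the number of its bases falling inside `rs`
#' (after normalization of `rs`).
#' @param chrom,start,end Query intervals, 0-based half-open.
#' @param rs A `region_set`.
#' @return Numeric vector of overlapped bp per query.
#' @export
overlap_bp <- function(chrom, start, end, rs) {
  stopifnot(inherits(rs, "region_set"))
  n <- length(chrom)
  if (n == 0L) return(numeric(0))
  rs <- merge(rs)
  if (length(rs) == 0L) return(rep(0, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
  s <- rs_to_granges(rs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE))
  if (length(hits) == 0L) return(rep(0, n))
  qi <- S4Vectors::queryHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(q)[qi],
    GenomicRanges::ranges(s)[S4Vectors::subjectHits(hits)]))
  out <- rep(0, n)
  agg <- tapply(ov, qi, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Convert printed 1-based inclusive coordinates to internal convention
#'
#' Printed genomic coordinates (papers, browsers, VCF-style
#' "chr6:122,847,699-122,847,780") are 1-based inclusive. Internally the
#' package is 0-based half-open, so `start` loses 1 and `end` is kept:
#' the interval length is `end - start` in both conventions afterwards.
#'
#' @param start1,end1 1-based inclusive coordinates (numeric; commas not
#'   accepted -- strip formatting before calling).
#' @return A list with `start`, `end` (0-based half-open) and `length`.
#' @examples
#' printed_to_internal(122847699, 122847780)$length  # 82
#' @export
printed_to_internal <- function(start1, end1) {
  if (any(start1 < 1) || any(end1 < start1))
    stop("printed coordinates must satisfy 1 <= start <= end")
  list(start = start1 - 1, end = end1, length = end1 - start1 + 1)
}

#' Convert internal 0-based half-open coordinates to printed 1-based form
#' @param start0,end0 0-based half-open coordinates.
#' @return A list with `start`, `end` (1-based inclusive).
#' @export
internal_to_printed <- function(start0, end0) {
  list(start = start0 + 1, end = end0)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length (no header).
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}
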