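#' Build an adaptive-sampling target region design
#'
#' Expands every gene's maximal transcript span by a symmetric margin,
#' clips at chromosome bounds, unions in any manual extension regions
#' (e.g. an extra promoter/first-exon interval missing from the
#' annotation release), and merges to a normalized BED-ready set. The
#' default margin of 10 kbp matches common practice for nanopore adaptive
#' sampling, where the pore decision point needs flanking sequence.
#'
#' @param genes List of `gene_model`s (see [read_gene_annotation()]).
#' @param margin Symmetric flank in bp added to each gene span (default
#'   10000).
#' @param extra Optional `region_set` of manual extensions, unioned after
#'   margin expansion.
#' @param chrom_sizes Named numeric vector of chromosome lengths; must
#'   cover every gene's chromosome.
#' @return A `target_design`: list with `genes`, `margin`, `extra`,
#'   `regions` (merged `region_set`) and `total_bp`.
#' @export
build_target_regions <- function(genes, margin = 10000, extra = NULL,
                                 chrom_sizes) {
  if (margin < 0) stop("margin must be >= 0")
  if (length(genes) == 0L) stop("no genes supplied")
  chroms <- vapply(genes, `[[`, "", "chrom")
  absent <- !chroms %in% names(chrom_sizes)
  if (any(absent))
    stop("chromosome missing from chrom_sizes for gene(s): ",
         paste(vapply(genes[absent], `[[`, "", "symbol"), collapse = ", "))
  start <- pmax(0, vapply(genes, function(g) g$span[["start"]], 0) - margin)
  end <- pmin(unname(chrom_sizes[chroms]),
              vapply(genes, function(g) g$span[["end"]], 0) + margin)
  rs <- region_set(chroms, start, end, label = "targets")
  if (!is.null(extra) && length(extra) > 0L) {
    rs <- region_set(c(rs$chrom, extra$chrom), c(rs$start, extra$start),
                     c(rs$end, extra$end), label = "targets")
  }
  regions <- merge(rs)
  structure(list(genes = genes, margin = margin, extra = extra,
                 regions = regions, total_bp = total_bp(regions)),
            class = "target_design")
}

#' @export
print.target_design <- function(x, ...) {
  cat(sprintf("target_design: %d genes, margin %s bp, %d merged regions, %s bp total\n",
              length(x$genes), format_bp(x$margin), length(x$regions),
              format(x$total_bp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Per-gene review table for a target design
#'
#' One row per gene: span length, margin-expanded (clipped) length, and
#' the id of the merged output region containing the gene. Manual
#' extension intervals are appended as additional rows tagged `extra`.
#'
#' @param td A `target_design`.
#' @return data.frame with columns `gene`, `chrom`, `span_bp`,
#'   `expanded_bp`, `region_id`, `kind`.
#' @export
design_report <- function(td) {
  stopifnot(inherits(td, "target_design"))
  genes <- td$genes
  chroms <- vapply(genes, `[[`, "", "chrom")
  sp_start <- vapply(genes, function(g) g$span[["start"]], 0)
  sp_end <- vapply(genes, function(g) g$span[["end"]], 0)
  exp_start <- pmax(0, sp_start - td$margin)
  exp_end <- sp_end + td$margin  # report unclipped-at-top; regions are clipped
  reg <- td$regions
  region_id <- integer(length(genes))
  for (i in seq_along(genes)) {
    hit <- which(reg$chrom == chroms[i] & reg$start <= sp_start[i] &
                   reg$end >= sp_end[i])
    region_id[i] <- if (length(hit)) hit[1L] else NA_integer_
  }
  df <- data.frame(
    gene = vapply(genes, `[[`, "", "symbol"),
    chrom = chroms,
    span_bp = sp_end - sp_start,
    expanded_bp = exp_end - exp_start,
    region_id = region_id,
    kind = "gene",
    stringsAsFactors = FALSE)
  if (!is.null(td$extra) && length(td$extra) > 0L) {
    ex <- td$extra
    exdf <- data.frame(
      gene = if (!is.null(ex$name)) ex$name else rep("extra", length(ex)),
      chrom = ex$chrom,
      span_bp = ex$end - ex$start,
      expanded_bp = ex$end - ex$start,
      region_id = NA_integer_,
      kind = "extra",
      stringsAsFactors = FALSE)
    df <- rbind(df, exdf)
  }
  rownames(df) <- NULL
  df
}
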