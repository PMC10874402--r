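#' Gene models from GTF/GFF annotation
#'
#' Reads a GENCODE-dialect GTF (or GFF3) via rtracklayer and assembles one
#' gene model per requested gene: the maximal span over all transcripts,
#' per-transcript exon/CDS/UTR intervals and transcription start sites.
#' Genes are matched by symbol (`gene_name`) first, then `gene_id`;
#' requested genes absent from the annotation are reported in the
#' `missing_genes` attribute rather than raising an error.
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention at this boundary. A gene model is a list with fields
#' `gene_id`, `symbol`, `chrom`, `strand`, `span` (c(start, end)),
#' `tss` (1-based, per transcript) and `transcripts` (each with `tx_id`,
#' `exons`, `cds`, `utrs` data frames and `tss`).
#'
#' @param path GTF/GFF file.
#' @param genes Optional character vector of gene symbols or ids to keep.
#' @return List of `gene_model` objects, named by symbol, with attribute
#'   `missing_genes`.
#' @export
read_gene_annotation <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("annotation lacks gene_id attributes")
  sym <- if (!is.null(md$gene_name)) as.character(md$gene_name) else as.character(md$gene_id)
  sym[is.na(sym)] <- as.character(md$gene_id)[is.na(sym)]
  type <- as.character(md$type)
  gid <- as.character(md$gene_id)
  txid <- if (!is.null(md$transcript_id)) as.character(md$transcript_id) else rep(NA_character_, length(gr))

  if (!is.null(genes)) {
    keep_gene <- unique(gid[sym %in% genes | gid %in% genes])
    missing <- setdiff(genes, unique(c(sym, gid)))
  } else {
    keep_gene <- unique(gid)
    missing <- character()
  }

  chrom_all <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  strand_all <- as.character(GenomicRanges::strand(gr))

  out <- list()
  for (g in keep_gene) {
    sel <- gid == g
    g_sym <- sym[sel][1L]
    g_chrom <- chrom_all[sel][1L]
    g_strand <- strand_all[sel][1L]
    tx_ids <- unique(txid[sel & !is.na(txid)])
    transcripts <- list()
    for (tx in tx_ids) {
      tsel <- sel & !is.na(txid) & txid == tx
      exons <- interval_df(start0[tsel & type == "exon"], end0[tsel & type == "exon"])
      cds <- interval_df(start0[tsel & type == "CDS"], end0[tsel & type == "CDS"])
      utr_sel <- tsel & type %in% c("UTR", "five_prime_utr", "three_prime_utr",
                                    "five_prime_UTR", "three_prime_UTR")
      utrs <- interval_df(start0[utr_sel], end0[utr_sel])
      if (nrow(utrs) == 0L && nrow(cds) > 0L && nrow(exons) > 0L)
        utrs <- interval_setdiff(exons, cds)
      if (nrow(exons) == 0L) next
      tx_start <- min(exons$start); tx_end <- max(exons$end)
      tss <- if (g_strand == "-") tx_end else tx_start + 1  # 1-based
      transcripts[[tx]] <- list(tx_id = tx, exons = exons, cds = cds,
                                utrs = utrs, tss = tss)
    }
    if (length(transcripts) == 0L) next
    sp_start <- min(vapply(transcripts, function(t) min(t$exons$start), 0))
    sp_end <- max(vapply(transcripts, function(t) max(t$exons$end), 0))
    gm <- structure(list(
      gene_id = g, symbol = g_sym, chrom = g_chrom, strand = g_strand,
      span = c(start = sp_start, end = sp_end),
      tss = vapply(transcripts, `[[`, 0, "tss"),
      transcripts = transcripts), class = "gene_model")
    out[[g_sym]] <- gm
  }
  if (!is.null(genes)) out <- out[intersect(genes, names(out))]
  attr(out, "missing_genes") <- missing
  out
}

interval_df <- function(start, end) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end))
  df[order(df$start), , drop = FALSE]
}

## set difference of two interval tables on one chromosome (0-based half-open)
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  ir_a <- IRanges::IRanges(a$start + 1, a$end)
  ir_b <- IRanges::IRanges(b$start + 1, b$end)
  d <- IRanges::setdiff(ir_a, ir_b)
  interval_df(IRanges::start(d) - 1, IRanges::end(d))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%s-%s [%s], %d transcript(s)\n",
              x$symbol, x$gene_id, x$chrom,
              format_bp(x$span[["start"]]), format_bp(x$span[["end"]]),
              x$strand, length(x$transcripts)))
  invisible(x)
}

#' Gene-level transcription start site
#'
#' The TSS of the outermost transcript: the 5'-most transcript start on the
#' gene's strand (minimum span start on `+`, maximum span end on `-`).
#' @param g A `gene_model`.
#' @return 1-based TSS position.
#' @export
gene_tss <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  if (g$strand == "-") g$span[["end"]] else g$span[["start"]] + 1
}

#' Gene spans as a region_set
#'
#' @param genes List of `gene_model`s.
#' @return A `region_set` labelled `gene_spans` (one interval per gene,
#'   unmerged).
#' @export
gene_spans <- function(genes) {
  region_set(
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, function(g) g$span[["start"]], 0),
    end = vapply(genes, function(g) g$span[["end"]], 0),
    strand = vapply(genes, `[[`, "", "strand"),
    label = "gene_spans")
}

## union interval table over all transcripts of a gene, one of "exons",
## "cds", "utrs"
gene_feature_intervals <- function(g, what) {
  parts <- lapply(g$transcripts, `[[`, what)
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0L)
    return(interval_df(numeric(0), numeric(0)))
  ir <- IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
  interval_df(IRanges::start(ir) - 1, IRanges::end(ir))
}
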