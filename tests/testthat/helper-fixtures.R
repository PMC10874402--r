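# Small hand-built fixtures shared across tests.

# single-transcript gene model with explicit CDS/UTR structure
toy_gene <- function(symbol, chrom, start, end, strand = "+",
                     cds = NULL, utrs = NULL, exons = NULL) {
  if (is.null(exons)) exons <- data.frame(start = start, end = end)
  if (is.null(cds)) cds <- exons
  if (is.null(utrs)) utrs <- data.frame(start = numeric(0), end = numeric(0))
  tss <- if (strand == "-") max(exons$end) else min(exons$start) + 1
  tx <- list(tx_id = paste0(symbol, ".T1"),
             exons = exons[order(exons$start), , drop = FALSE],
             cds = cds[order(cds$start), , drop = FALSE],
             utrs = utrs[order(utrs$start), , drop = FALSE],
             tss = tss)
  structure(list(gene_id = symbol, symbol = symbol, chrom = chrom,
                 strand = strand,
                 span = c(start = min(exons$start), end = max(exons$end)),
                 tss = c(tss), transcripts = stats::setNames(list(tx), tx$tx_id)),
            class = "gene_model")
}

# random region_set on one chromosome
random_region_set <- function(n, len, chrom = "chr1", max_width = 500) {
  start <- sample.int(len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  region_set(rep(chrom, n), start, pmin(start + width, len))
}

# standard SV fixture bundle used by several files
sv_fixture <- function(seed = 7) {
  cs <- c(chr1 = 200000, chr2 = 60000)
  c(make_sv_callset(seed, cs), list(chrom_sizes = cs))
}
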