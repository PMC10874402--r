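#' Deterministic substream seed
#'
#' Every generator draws from its own random-number stream derived from
#' the master seed and a stable label, so adding a generator (or calling
#' them in a different order) never perturbs another generator's output.
#'
#' @param seed Master seed (integer).
#' @param label Stream label (string).
#' @return Integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, label) {
  val <- 0
  for (ch in utf8ToInt(label)) val <- (val * 31 + ch) %% 2147483647
  as.integer((val + (as.numeric(seed) %% 2147483647) * 1000003) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random genome
#'
#' Uniform random nucleotide sequence per chromosome, with optional
#' planted repeat loci recorded as a repeat-mask region set (the
#' sequence inside a planted locus is replaced by the supplied repeat
#' sequence).
#'
#' @param seed Master seed.
#' @param lengths Named numeric vector of chromosome lengths (>= 1e4).
#' @param plant List of planted loci: each `list(chrom, start, seq)`
#'   (0-based start); optional.
#' @return List: `sequences` (named character vector), `chrom_sizes`,
#'   `repeat_mask` (`region_set` of planted loci).
#' @export
make_genome <- function(seed, lengths = c(chr1 = 50000), plant = list()) {
  if (any(lengths < 1e4)) stop("chromosome lengths must be >= 1e4")
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  set.seed(substream_seed(seed, "genome"))
  seqs <- vapply(lengths, random_dna, "")
  mk_chrom <- character(); mk_start <- numeric(); mk_end <- numeric()
  for (p in plant) {
    L <- nchar(p$seq)
    if (p$start + L > lengths[[p$chrom]]) stop("planted locus exceeds chromosome")
    substr(seqs[[p$chrom]], p$start + 1, p$start + L) <- p$seq
    mk_chrom <- c(mk_chrom, p$chrom)
    mk_start <- c(mk_start, p$start)
    mk_end <- c(mk_end, p$start + L)
  }
  mask <- if (length(mk_chrom)) region_set(mk_chrom, mk_start, mk_end,
                                           label = "repeats")
          else region_set(label = "repeats")
  list(sequences = seqs, chrom_sizes = lengths, repeat_mask = mask)
}

#' Generate a repeat consensus library
#'
#' Random consensus sequences for the common mobile-element families.
#' SVA entries begin with five copies of the CCCTCT hexamer (the
#' retrotransposition-competent head); everything downstream is random,
#' which is enough for the segmentation rules the package applies (the
#' library is synthetic, not a RepBase/Dfam excerpt).
#'
#' @param seed Master seed.
#' @param lengths Named numeric vector of consensus lengths. Defaults to
#'   plausible magnitudes for SVA subfamilies, L1 and AluY.
#' @return Named character vector of consensus sequences.
#' @export
make_repeat_library <- function(seed,
                                lengths = c(SVA_A = 1100, SVA_B = 1200,
                                            SVA_C = 1250, SVA_D = 1300,
                                            SVA_E = 1350, SVA_F = 1400,
                                            L1 = 6000, AluY = 300)) {
  set.seed(substream_seed(seed, "repeat_library"))
  lib <- vapply(names(lengths), function(fam) {
    n <- lengths[[fam]]
    if (startsWith(fam, "SVA")) {
      head <- strrep("CCCTCT", 5)
      paste0(head, random_dna(n - nchar(head)))
    } else random_dna(n)
  }, "")
  names(lib) <- names(lengths)
  lib
}

new_gene_model <- function(gene_id, symbol, chrom, strand, transcripts) {
  sp_start <- min(vapply(transcripts, function(t) min(t$exons$start), 0))
  sp_end <- max(vapply(transcripts, function(t) max(t$exons$end), 0))
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, span = c(start = sp_start, end = sp_end),
                 tss = vapply(transcripts, `[[`, 0, "tss"),
                 transcripts = transcripts), class = "gene_model")
}

#' Generate a gene annotation
#'
#' Random non-overlapping gene models (2-8 exons per transcript, 1-2
#' transcripts, both strands, CDS flanked by UTR portions in the first
#' and last exon), returned in memory and optionally written as a
#' GENCODE-dialect GTF.
#'
#' @param seed Master seed.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n_genes Number of genes.
#' @param out_gtf Optional path; when given, a GTF is written.
#' @return List: `genes` (list of `gene_model`, named by symbol),
#'   `manifest` (data.frame gene/chrom/strand/n_transcripts/n_exons),
#'   `gtf` (path or NULL).
#' @export
make_gene_annotation <- function(seed, chrom_sizes, n_genes = 10,
                                 out_gtf = NULL) {
  set.seed(substream_seed(seed, "gene_annotation"))
  ## lay genes in evenly spaced slots with padding so spans never touch
  slots <- list()
  for (chr in names(chrom_sizes)) {
    len <- chrom_sizes[[chr]]
    n_slot <- max(1L, floor(len / 12000))
    bounds <- floor(seq(0, len, length.out = n_slot + 1L))
    for (i in seq_len(n_slot))
      slots[[length(slots) + 1L]] <- list(chrom = chr, start = bounds[i],
                                          end = bounds[i + 1L])
  }
  if (n_genes > length(slots))
    stop("genome too small for ", n_genes, " genes")
  use <- sort(sample(seq_along(slots), n_genes))
  genes <- list(); rows <- list()
  for (gi in seq_len(n_genes)) {
    slot <- slots[[use[gi]]]
    pad <- 2500  # promoter + flank room inside the slot
    g_start <- slot$start + pad
    g_len <- sample(3000:min(7000, slot$end - g_start - pad), 1L)
    g_end <- g_start + g_len
    strand <- sample(c("+", "-"), 1L)
    sym <- sprintf("GENE%03d", gi)
    gid <- sprintf("G%03d", gi)
    n_tx <- sample(1:2, 1L)
    transcripts <- list()
    for (ti in seq_len(n_tx)) {
      ## inner transcripts may start later / end earlier
      t_start <- if (ti == 1L) g_start else g_start + sample(0:500, 1L)
      t_end <- if (ti == 1L) g_end else g_end - sample(0:500, 1L)
      n_ex <- sample(2:8, 1L)
      ## cut the transcript into exons separated by introns
      cuts <- sort(sample(seq(t_start + 200, t_end - 200, by = 50),
                          2L * (n_ex - 1L)))
      ex_start <- c(t_start, cuts[seq(2, length(cuts), by = 2)])
      ex_end <- c(cuts[seq(1, length(cuts), by = 2)], t_end)
      exons <- interval_df(ex_start, ex_end)
      u5 <- sample(50:150, 1L); u3 <- sample(50:150, 1L)
      utrs <- interval_df(c(t_start, t_end - u3),
                          c(t_start + u5, t_end))
      cds <- interval_setdiff(exons, utrs)
      tss <- if (strand == "-") t_end else t_start + 1
      tx_id <- sprintf("%s.T%d", gid, ti)
      transcripts[[tx_id]] <- list(tx_id = tx_id, exons = exons, cds = cds,
                                   utrs = interval_setdiff(exons, cds),
                                   tss = tss)
    }
    genes[[sym]] <- new_gene_model(gid, sym, slot$chrom, strand, transcripts)
    rows[[gi]] <- data.frame(
      gene = sym, gene_id = gid, chrom = slot$chrom, strand = strand,
      n_transcripts = n_tx,
      n_exons = sum(vapply(transcripts, function(t) nrow(t$exons), 0L)),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_gtf)) write_gtf(genes, out_gtf)
  list(genes = genes, manifest = manifest, gtf = out_gtf)
}

#' Write gene models as a GENCODE-dialect GTF
#'
#' @param genes List of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character()
  feat <- function(chrom, type, start0, end0, strand, attrs) {
    sprintf("%s\tsynthetic\t%s\t%s\t%s\t.\t%s\t.\t%s", chrom, type,
            format_bp(start0 + 1), format_bp(end0), strand, attrs)
  }
  for (g in genes) {
    a_gene <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)
    lines <- c(lines, feat(g$chrom, "gene", g$span[["start"]],
                           g$span[["end"]], g$strand, a_gene))
    for (t in g$transcripts) {
      a_tx <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                      g$gene_id, t$tx_id, g$symbol)
      lines <- c(lines, feat(g$chrom, "transcript", min(t$exons$start),
                             max(t$exons$end), g$strand, a_tx))
      for (i in seq_len(nrow(t$exons)))
        lines <- c(lines, feat(g$chrom, "exon", t$exons$start[i],
                               t$exons$end[i], g$strand, a_tx))
      for (i in seq_len(nrow(t$cds)))
        lines <- c(lines, feat(g$chrom, "CDS", t$cds$start[i],
                               t$cds$end[i], g$strand, a_tx))
      for (i in seq_len(nrow(t$utrs)))
        lines <- c(lines, feat(g$chrom, "UTR", t$utrs$start[i],
                               t$utrs$end[i], g$strand, a_tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a mobile-element insertion event with ground truth
#'
#' Plants a source locus in a random genome (concatenated repeat-family
#' consensus copies followed by the chromosome's native downstream
#' sequence, which becomes the 3' transduction), then constructs the
#' insertion as the 5'-truncated element copy + transduction + poly-A
#' tail + target-site duplication, with reference flanks carrying the
#' TSD. The construction *is* the ground truth recorded in the manifest.
#'
#' The transduction's 3'-terminal bases are drawn from C/G/T so the
#' transduction/poly-A boundary is identifiable, and the AATAAA
#' polyadenylation signal is embedded in the transduction when
#' `plant_polya_signal` is TRUE. Insertion sites whose local sequence
#' makes the planted TSD ambiguous (a chance extension of the
#' duplication) are resampled: the recovery guarantees assume
#' non-repetitive flanks.
#'
#' @param seed Master seed.
#' @param lib Repeat library (see [make_repeat_library()]); only the
#'   families used need be present.
#' @param families Character vector of family labels concatenated to
#'   form the source element (default two SVA_F copies).
#' @param tsd_len,polya_len,transduction_len Planted lengths (defaults
#'   14 / 24 / 82 bp).
#' @param truncation_5p Bases removed from the element 5' end before
#'   insertion (default 200: the hexamer head is lost).
#' @param genome_length Chromosome length (default 60000).
#' @param flank Flank window size (default 100).
#' @param plant_polya_signal Embed AATAAA in the transduction (default
#'   TRUE).
#' @return List: `call` (`insertion_call`), `genome`
#'   (see [make_genome()]), `lib`, `manifest` (planted truth: lengths,
#'   `tsd_seq`, `source_locus`, `element_interval`, `site`,
#'   `families`, `hexamer_head_present`).
#' @export
make_mei_event <- function(seed, lib = NULL, families = c("SVA_F", "SVA_F"),
                           tsd_len = 14, polya_len = 24,
                           transduction_len = 82, truncation_5p = 200,
                           genome_length = 60000, flank = 100,
                           plant_polya_signal = TRUE) {
  if (is.null(lib)) lib <- make_repeat_library(seed)
  miss <- setdiff(families, names(lib))
  if (length(miss)) stop("families not in library: ", paste(miss, collapse = ", "))
  element <- paste(vapply(families, function(f) lib[[f]], ""), collapse = "")
  if (truncation_5p >= nchar(element)) stop("truncation exceeds element length")
  set.seed(substream_seed(seed, "mei_event"))
  g <- make_genome(seed, c(chrS = genome_length))
  chrom <- "chrS"
  src_start <- 5000                           # 0-based
  src_elem_end <- src_start + nchar(element)
  seqs <- g$sequences
  substr(seqs[[chrom]], src_start + 1, src_elem_end) <- element
  ## transduction = native sequence downstream of the element
  td_start <- src_elem_end
  td_end <- td_start + transduction_len
  if (transduction_len > 0) {
    if (plant_polya_signal && transduction_len >= 16)
      substr(seqs[[chrom]], td_start + 2, td_start + 7) <- "AATAAA"
    ## A-free 3' terminus so the transduction/poly-A boundary is
    ## identifiable under the tail detector's mismatch tolerance
    n_fix <- min(10L, transduction_len)
    fix_seq <- paste(sample(c("C", "G", "T"), n_fix, replace = TRUE),
                     collapse = "")
    substr(seqs[[chrom]], td_end - n_fix + 1, td_end) <- fix_seq
  }
  trunc_element <- substr(element, truncation_5p + 1, nchar(element))
  td_seq <- substr(seqs[[chrom]], td_start + 1, td_end)
  core <- paste0(trunc_element, td_seq, strrep("A", polya_len))

  ## pick a TSD-compatible site well away from the source locus
  site_lo <- td_end + 10000
  site_hi <- genome_length - flank - tsd_len - 10
  call <- NULL
  for (try in 1:50) {
    pos0 <- sample(site_lo:site_hi, 1L)        # 0-based insertion point
    tsd_seq <- substr(seqs[[chrom]], pos0 + 1, pos0 + tsd_len)
    ins <- paste0(core, tsd_seq)
    cand <- insertion_call(
      chrom = chrom, pos = pos0 + 1, inserted_seq = ins,
      left_flank = substr(seqs[[chrom]], pos0 - flank + 1, pos0),
      right_flank = substr(seqs[[chrom]], pos0 + 1, pos0 + flank))
    found <- detect_tsd(cand)
    if (identical(found, tsd_seq)) { call <- cand; break }
  }
  if (is.null(call)) stop("could not place a non-degenerate TSD site")
  genome <- list(sequences = seqs, chrom_sizes = g$chrom_sizes,
                 repeat_mask = region_set(chrom, src_start, src_elem_end,
                                          label = "repeats"))
  manifest <- list(
    seed = seed, families = families,
    tsd_len = tsd_len, tsd_seq = tsd_seq,
    polya_len = polya_len, transduction_len = transduction_len,
    truncation_5p = truncation_5p,
    element_interval = list(chrom = chrom, start = src_start,
                            end = src_elem_end),
    source_locus = list(chrom = chrom, start = src_start + truncation_5p,
                        end = td_end),
    site = list(chrom = chrom, pos = call$pos),
    hexamer_head_present = truncation_5p == 0,
    polya_signal_planted = plant_polya_signal && transduction_len >= 10)
  list(call = call, genome = genome, lib = lib, manifest = manifest)
}

#' Generate a haplotype-resolved methylation dataset with one epimutation
#'
#' Per-CpG methylated/unmethylated counts for a control panel and one
#' target sample. CpG positions are taken from CG dinucleotides of the
#' supplied genome within each gene's promoter window and span (or laid
#' out at ~16 bp spacing when no genome is given). Background
#' methylation follows the usual promoter/gene-body pattern (promoter
#' CpGs near ratio 0.05, gene body near 0.85); the planted gene x
#' haplotype has promoter CpGs near 0.9 in the target sample only.
#'
#' @param seed Master seed.
#' @param genes List of `gene_model`s.
#' @param genome Optional genome (see [make_genome()]) for real CG
#'   positions.
#' @param n_controls Control panel size (default 10).
#' @param coverage Total per-CpG coverage per sample (split evenly
#'   across the two haplotypes; default 20).
#' @param epimutated_gene Symbol of the gene to epimutate (default: the
#'   first gene).
#' @param epimutated_haplotype `"1"` or `"2"` (default `"1"`).
#' @param promoter_width Promoter window (default 2000 bp).
#' @param epimutate Set FALSE for a null dataset with no planted signal.
#' @return List: `target` (count data.frame), `controls` (list of count
#'   data.frames), `manifest` (planted gene/haplotype, per-region
#'   background ratios, CpG counts per promoter).
#' @export
make_methylation_dataset <- function(seed, genes, genome = NULL,
                                     n_controls = 10, coverage = 20,
                                     epimutated_gene = NULL,
                                     epimutated_haplotype = "1",
                                     promoter_width = 2000,
                                     epimutate = TRUE) {
  set.seed(substream_seed(seed, "methylation"))
  if (is.null(epimutated_gene)) epimutated_gene <- genes[[1L]]$symbol
  if (!epimutated_gene %in% vapply(genes, `[[`, "", "symbol"))
    stop("epimutated_gene not among supplied genes")
  p_promoter <- 0.05; p_body <- 0.85; p_epi <- 0.9
  cov_hap <- max(1L, round(coverage / 2))

  sites <- list()
  for (g in genes) {
    win <- promoter_window(g, width = promoter_width)
    regions <- list(list(start = win$start, end = win$end, kind = "promoter"),
                    list(start = g$span[["start"]], end = g$span[["end"]],
                         kind = "body"))
    for (r in regions) {
      if (!is.null(genome)) {
        seqr <- substr(genome$sequences[[g$chrom]], r$start + 1, r$end)
        hits <- gregexpr("CG", seqr, fixed = TRUE)[[1L]]
        pos <- if (hits[1L] == -1L) integer(0) else r$start + as.integer(hits)
      } else {
        pos <- seq(r$start + 8, r$end - 1, by = 16)
      }
      if (length(pos))
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = g$chrom, pos = pos, gene = g$symbol, kind = r$kind,
          stringsAsFactors = FALSE)
    }
  }
  sites <- unique(do.call(rbind, sites))
  base_p <- ifelse(sites$kind == "promoter", p_promoter, p_body)

  draw_sample <- function(p_by_site_hap) {
    do.call(rbind, lapply(c("1", "2"), function(h) {
      p <- p_by_site_hap[[h]]
      n_meth <- stats::rbinom(nrow(sites), cov_hap, p)
      data.frame(chrom = sites$chrom, pos = sites$pos, haplotype = h,
                 n_meth = n_meth, n_unmeth = cov_hap - n_meth,
                 stringsAsFactors = FALSE)
    }))
  }
  controls <- lapply(seq_len(n_controls), function(i)
    draw_sample(list(`1` = base_p, `2` = base_p)))
  p_target <- list(`1` = base_p, `2` = base_p)
  if (epimutate) {
    epi_sites <- sites$gene == epimutated_gene & sites$kind == "promoter"
    p_target[[epimutated_haplotype]][epi_sites] <- p_epi
  }
  target <- draw_sample(p_target)
  n_prom <- table(sites$gene[sites$kind == "promoter"])
  list(target = target, controls = controls,
       manifest = list(seed = seed,
                       epimutated_gene = if (epimutate) epimutated_gene else NA,
                       epimutated_haplotype = if (epimutate) epimutated_haplotype else NA,
                       p_promoter = p_promoter, p_body = p_body, p_epi = p_epi,
                       coverage_per_haplotype = cov_hap,
                       n_promoter_cpgs = as.list(n_prom)))
}

#' Generate a truth/test genotype pair with planted per-bin discordance
#'
#' Sites are spread across the standard MAF bins (bin chosen uniformly,
#' MAF uniform within the bin), truth genotypes drawn from
#' Hardy-Weinberg proportions at the site's MAF, and test genotypes
#' flipped to a different dosage at the planted per-bin error rate.
#' Truth records carry depth 30 and GQ 60, passing the default
#' concordance filters.
#'
#' @param seed Master seed.
#' @param n_sites Number of sites (default 10000).
#' @param error_rate Per-bin flip probability: scalar or vector of
#'   length `length(edges) - 1` (default 0.02).
#' @param edges MAF bin edges (see [bin_by_maf()]).
#' @param out_dir Optional directory; when given, `truth.vcf`,
#'   `test.vcf` and `panel_af.tsv` are written there.
#' @return List: `truth`, `test` (genotype data.frames in the
#'   [read_genotypes()] shape), `manifest`, and file paths when written.
#' @export
make_genotype_pair <- function(seed, n_sites = 10000, error_rate = 0.02,
                               edges = c(0, 0.001, 0.002, 0.005, 0.010,
                                         0.050, 0.100, 0.200, 0.500),
                               out_dir = NULL) {
  set.seed(substream_seed(seed, "genotype_pair"))
  n_bins <- length(edges) - 1L
  error_rate <- rep_len(error_rate, n_bins)
  if (any(error_rate < 0 | error_rate > 1)) stop("error rates must be in [0,1]")
  bin <- sample.int(n_bins, n_sites, replace = TRUE)
  maf <- stats::runif(n_sites, edges[bin], edges[bin + 1L])
  gt_truth <- stats::rbinom(n_sites, 2L, maf)
  flip <- stats::runif(n_sites) < error_rate[bin]
  gt_test <- gt_truth
  gt_test[flip] <- (gt_truth[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
  pos <- sort(sample.int(3e7, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  mk <- function(gt, depth, gq) data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt, gt = gt,
    depth = depth, gq = gq, maf = maf, stringsAsFactors = FALSE)
  truth <- mk(gt_truth, 30, 60)
  test <- mk(gt_test, NA_real_, NA_real_)
  manifest <- list(seed = seed, n_sites = n_sites,
                   per_bin_error = as.list(stats::setNames(
                     error_rate, paste0("bin", seq_len(n_bins)))))
  out <- list(truth = truth, test = test, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$truth_vcf <- write_genotype_vcf(truth, file.path(out_dir, "truth.vcf"),
                                        with_format = TRUE)
    out$test_vcf <- write_genotype_vcf(test, file.path(out_dir, "test.vcf"),
                                       with_format = FALSE)
    af <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = ref,
                     alt = alt, af = maf)
    out$af_table <- file.path(out_dir, "panel_af.tsv")
    utils::write.table(af, out$af_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

write_genotype_vcf <- function(df, path, with_format = TRUE) {
  gt_str <- c("0/0", "0/1", "1/1")[df$gt + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Panel allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  info <- sprintf("AF=%s", format(df$maf, digits = 6, scientific = FALSE, trim = TRUE))
  if (with_format) {
    fmt <- "GT:DP:GQ"
    smp <- sprintf("%s:%d:%d", gt_str, as.integer(df$depth), as.integer(df$gq))
  } else {
    fmt <- "GT"; smp <- gt_str
  }
  body <- sprintf("%s\t%s\t.\t%s\t%s\t.\tPASS\t%s\t%s\t%s",
                  df$chrom, format_bp(df$pos), df$ref, df$alt, info, fmt, smp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate an SV callset with one exemplar per filter rule and category
#'
#' Builds five exemplar genes with a fixed exon/CDS/UTR architecture
#' (deterministically placed, with a seeded jitter) plus the target
#' design over them, then a callset containing at least one record per
#' false-positive elimination rule (off-primary contig, no breakend in
#' targets, contained in a margin-expanded simple repeat), one per
#' pathogenic category (deletion over CDS, CDS-amplifying duplication,
#' gene-disrupting inversion and translocation, intragenic single
#' breakend) and benign decoys (intergenic inversion, intronic deletion,
#' UTR-only duplication). The manifest records the intended outcome of
#' every record. Genes get a controlled architecture here -- rather than
#' reusing [make_gene_annotation()] -- so every exemplar position
#' (first intron, CDS midpoints, UTR interior) exists by construction at
#' any seed.
#'
#' @param seed Master seed.
#' @param chrom_sizes Named numeric vector (>= 2 chromosomes, first one
#'   >= 150000 bp).
#' @param margin Target-design margin around gene spans (default 10000).
#' @return List: `svs` (SV table), `genes` (the five exemplar
#'   `gene_model`s), `targets` (their merged target regions),
#'   `simple_repeats` (`region_set` containing the planted repeat),
#'   `primary_contigs`, `manifest` (data.frame sv_id/expected_kept/
#'   expected_reason/expected_pathogenic/expected_pathogenic_reason).
#' @export
make_sv_callset <- function(seed, chrom_sizes = c(chr1 = 200000, chr2 = 60000),
                            margin = 10000) {
  if (length(chrom_sizes) < 2L) stop("need at least 2 chromosomes")
  if (chrom_sizes[[1L]] < 150000) stop("first chromosome must be >= 150 kb")
  set.seed(substream_seed(seed, "sv_callset"))
  chr <- names(chrom_sizes)[1L]
  chr2 <- names(chrom_sizes)[2L]
  jitter <- sample.int(500, 5)

  ## fixed architecture per gene (relative coordinates, span 8000):
  ## exon1 [0,500) with 5'UTR [0,150); long first intron [500,2600);
  ## exon2 [2600,3200); exon3 [6000,8000) with 3'UTR [7700,8000)
  mk_exemplar_gene <- function(i) {
    base <- 5000 + (i - 1L) * 22000 + jitter[i]
    exons <- interval_df(base + c(0, 2600, 6000), base + c(500, 3200, 8000))
    utrs <- interval_df(base + c(0, 7700), base + c(150, 8000))
    cds <- interval_setdiff(exons, utrs)
    sym <- sprintf("SVGENE%d", i)
    tx <- list(tx_id = paste0(sym, ".T1"), exons = exons, cds = cds,
               utrs = utrs, tss = base + 1)
    new_gene_model(sym, sym, chr, "+", stats::setNames(list(tx), tx$tx_id))
  }
  genes <- lapply(1:5, mk_exemplar_gene)
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  targets <- build_target_regions(genes, margin = margin,
                                  chrom_sizes = chrom_sizes)$regions

  cds <- lapply(genes, gene_feature_intervals, "cds")
  utr <- lapply(genes, gene_feature_intervals, "utrs")
  base_of <- function(i) genes[[i]]$span[["start"]]

  ## planted repeat inside gene 1's first intron
  rep_start <- base_of(1) + 1000; rep_end <- rep_start + 60
  simple_repeats <- region_set(chr, rep_start, rep_end,
                               label = "simple_repeats")

  mid_cds <- function(j, i) {
    iv <- cds[[j]]
    floor((iv$start[i] + iv$end[i]) / 2) + 1  # 1-based
  }
  rec <- list(); man <- list()
  add <- function(id, type, c1, p1, c2, p2, kept, reason, path, path_reason) {
    rec[[length(rec) + 1L]] <<- data.frame(
      sv_id = id, sv_type = type, chrom1 = c1, pos1 = p1,
      chrom2 = ifelse(is.na(p2), "", c2), pos2 = p2,
      inserted_seq = NA_character_, stringsAsFactors = FALSE)
    man[[length(man) + 1L]] <<- data.frame(
      sv_id = id, expected_kept = kept, expected_reason = reason,
      expected_pathogenic = path, expected_pathogenic_reason = path_reason,
      stringsAsFactors = FALSE)
  }

  ## pathogenic exemplars
  add("DEL_CDS", "deletion", chr, mid_cds(1, 1), chr, mid_cds(1, nrow(cds[[1]])),
      TRUE, "", TRUE, "deletion_hits_cds")
  add("DUP_CDS", "duplication", chr, mid_cds(2, 1), chr,
      mid_cds(2, nrow(cds[[2]])),     # span covers the full middle CDS exon
      TRUE, "", TRUE, "duplication_alters_cds")
  add("INV_GENE", "inversion", chr, mid_cds(3, 1), chr,
      genes[[3]]$span[["end"]] + 1000,
      TRUE, "", TRUE, "disrupts_gene_body")
  add("TRA_GENE", "translocation", chr, mid_cds(4, 1), chr2, 1000,
      TRUE, "", TRUE, "disrupts_gene_body")
  add("SBE_GENE", "single_breakend", chr, base_of(5) + 4000, "", NA,
      TRUE, "", TRUE, "single_breakend_in_gene")   # second intron of gene 5

  ## false-positive exemplars
  add("TRA_DECOY", "translocation", chr, mid_cds(1, 1), "chrUn_decoy1", 500,
      FALSE, "off_primary_contig", FALSE, "none")
  offt <- complement_regions(targets, chrom_sizes)
  wide <- which.max(offt$end - offt$start)
  if (length(wide) == 0L || offt$end[wide] - offt$start[wide] < 200)
    stop("targets leave no off-target room for the outside-targets exemplar")
  off_mid <- floor((offt$start[wide] + offt$end[wide]) / 2)
  add("DEL_OFFTARGET", "deletion", offt$chrom[wide], off_mid,
      offt$chrom[wide], off_mid + 50,
      FALSE, "outside_targets", FALSE, "none")
  add("DEL_REPEAT", "deletion", chr, rep_start + 2, chr, rep_end - 2,
      FALSE, "in_simple_repeat", FALSE, "none")
  add("INS_REPEAT", "insertion", chr, rep_start + 10, chr, rep_start + 10,
      FALSE, "in_simple_repeat", FALSE, "none")

  ## benign decoys (kept, not pathogenic)
  add("INV_INTERGENIC", "inversion", chr, genes[[1]]$span[["end"]] + 100,
      chr, genes[[1]]$span[["end"]] + 300,
      TRUE, "", FALSE, "none")
  add("DEL_INTRON", "deletion", chr, rep_end + 100, chr, rep_end + 150,
      TRUE, "", FALSE, "none")
  utr_pos <- utr[[2]]$start[1L] + 50  # mid 5'UTR of gene 2
  add("DUP_UTR", "duplication", chr, utr_pos, chr, utr_pos + 40,
      TRUE, "", FALSE, "none")

  svs <- validate_sv_table(do.call(rbind, rec))
  list(svs = svs, genes = genes, targets = targets,
       simple_repeats = simple_repeats,
       primary_contigs = names(chrom_sizes),
       manifest = do.call(rbind, man))
}

#' Generate read-alignment summaries with planted enrichment
#'
#' Read lengths are log-normal (sdlog 0.25) with the log-mean chosen so
#' the length-weighted median -- the N50 -- matches the requested value
#' in expectation. The on/off read-count split is solved from the
#' requested enrichment, the region sizes and the expected read lengths;
#' each read is placed uniformly within one region interval (fitting
#' fully when the interval allows), so the measured enrichment matches
#' the request up to sampling noise. Defaults mirror typical adaptive
#' sampling magnitudes: 10x enrichment, on-target N50 about 9 kb,
#' off-target about 0.6 kb.
#'
#' @param seed Master seed.
#' @param targets Target `region_set`.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param enrichment Requested on/off depth ratio (default 10).
#' @param n50_on,n50_off Requested N50s (defaults 9000 / 600 bp).
#' @param n_reads Total reads (default 20000).
#' @return List: `alns` (alignment-summary data.frame), `manifest`.
#' @export
make_alignment_summaries <- function(seed, targets, chrom_sizes,
                                     enrichment = 10, n50_on = 9000,
                                     n50_off = 600, n_reads = 20000) {
  if (enrichment <= 0) stop("enrichment must be > 0")
  set.seed(substream_seed(seed, "alignment_summaries"))
  targets <- merge(targets)
  offt <- complement_regions(targets, chrom_sizes)
  sdlog <- 0.25
  ## N50 of a log-normal is the median of its length-weighted version:
  ## exp(meanlog + sdlog^2)
  mu_on <- log(n50_on) - sdlog^2
  mu_off <- log(n50_off) - sdlog^2
  mean_on <- exp(mu_on + sdlog^2 / 2)
  mean_off <- exp(mu_off + sdlog^2 / 2)
  T <- total_bp(targets); O <- total_bp(offt)
  r <- enrichment * T * mean_off / (O * mean_on)  # n_on / n_off
  n_off <- round(n_reads / (1 + r))
  n_on <- n_reads - n_off

  place <- function(rs, n, mu, prefix) {
    iv <- sample.int(length(rs), n, replace = TRUE,
                     prob = rs$end - rs$start)
    len <- round(stats::rlnorm(n, mu, sdlog))
    len <- pmax(len, 50)
    iv_start <- rs$start[iv]; iv_end <- rs$end[iv]
    max_start <- pmax(iv_start, iv_end - len)
    start <- floor(stats::runif(n, iv_start, max_start + 1))
    end <- pmin(start + len, iv_end)
    data.frame(read_id = sprintf("%s_%06d", prefix, seq_len(n)),
               chrom = rs$chrom[iv], start = start, end = end,
               read_length = len, stringsAsFactors = FALSE)
  }
  alns <- rbind(place(targets, n_on, mu_on, "on"),
                place(offt, n_off, mu_off, "off"))
  alns <- alns[sample.int(nrow(alns)), , drop = FALSE]
  rownames(alns) <- NULL
  list(alns = alns,
       manifest = list(seed = seed, enrichment = enrichment,
                       n50_on = n50_on, n50_off = n50_off,
                       n_reads_on = n_on, n_reads_off = n_off))
}

#' Generate an annotated SNV/indel VCF with planted category structure
#'
#' Writes a VCF whose INFO annotations plant a known prioritization
#' outcome: by default 2 ClinVar known-pathogenic variants, 5 LOFTEE HC
#' loss-of-function, 9 splicing (2 of the LoF variants also splicing --
#' two double-labelled variants, 14 distinct), plus decoys removed by
#' the quality, region and frequency filters.
#'
#' @param seed Master seed.
#' @param genes List of `gene_model`s (variants are placed inside gene
#'   spans).
#' @param simple_repeats `region_set` used to place an in-repeat decoy
#'   (may be empty).
#' @param path Output VCF path.
#' @return List: `path`, `manifest` (expected per-label counts and
#'   distinct total).
#' @export
make_annotated_snv_vcf <- function(seed, genes, simple_repeats = NULL,
                                   path = tempfile(fileext = ".vcf")) {
  set.seed(substream_seed(seed, "annotated_snv"))
  pick_pos <- function(g) {
    # inside the gene span (1-based), avoiding the repeat mask
    for (try in 1:100) {
      p <- floor(stats::runif(1, g$span[["start"]] + 10, g$span[["end"]] - 10)) + 1
      if (is.null(simple_repeats) || length(simple_repeats) == 0L ||
          !position_in_regions(g$chrom, p, simple_repeats))
        return(p)
    }
    stop("could not place a variant outside the repeat mask")
  }
  gs <- rep_len(genes, 30)
  rows <- list()
  add <- function(g, qual = 50, af = "", clnsig = "", lof = "", csq = "",
                  ds = NA, chrom = NULL, pos = NULL) {
    chrom <- if (is.null(chrom)) g$chrom else chrom
    pos <- if (is.null(pos)) pick_pos(g) else pos
    info <- c(af,
              if (nzchar(clnsig)) sprintf("CLNSIG=%s", clnsig),
              if (nzchar(lof)) sprintf("LoF=%s", lof),
              if (nzchar(csq)) sprintf("CSQ=%s", csq),
              if (!is.na(ds)) sprintf("SpliceAI_DS_AG=%.2f", ds))
    info <- paste(info[nzchar(info)], collapse = ";")
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = "A", alt = "G", qual = qual,
      info = if (nzchar(info)) info else ".", stringsAsFactors = FALSE)
  }
  ## 2 known pathogenic (ClinVar only)
  add(gs[[1L]], clnsig = "Pathogenic")
  add(gs[[2L]], clnsig = "Likely_pathogenic")
  ## 3 LoF only
  for (i in 3:5) add(gs[[i]], lof = "HC", csq = "stop_gained")
  ## 2 LoF + splicing (the double-labelled pair)
  add(gs[[6L]], lof = "HC", csq = "splice_donor_variant")
  add(gs[[7L]], lof = "HC", csq = "splice_acceptor_variant")
  ## 7 splicing only
  for (i in 8:11) add(gs[[i]], csq = "intron_variant", ds = 0.72)
  for (i in 12:14) add(gs[[i]], csq = "splice_donor_variant")
  ## decoys
  add(gs[[1L]], qual = 10, clnsig = "Pathogenic")              # quality <= 10
  add(gs[[2L]], af = "gnomAD_AF=0.02", lof = "HC")             # common
  add(gs[[3L]], af = "TOMMO_AF=0.01", clnsig = "Pathogenic")   # common (boundary)
  add(gs[[4L]], clnsig = "Benign")                             # no label
  add(gs[[5L]], chrom = gs[[5L]]$chrom,
      pos = gs[[5L]]$span[["end"]] + 5000, lof = "HC")         # outside spans
  if (!is.null(simple_repeats) && length(simple_repeats) > 0L)
    add(gs[[1L]], chrom = simple_repeats$chrom[1L],
        pos = simple_repeats$start[1L] + 1, lof = "HC")        # in repeat mask
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=gnomAD_AF,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=TOMMO_AF,Number=1,Type=Float,Description=\"ToMMo allele frequency\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar significance\">",
    "##INFO=<ID=LoF,Number=1,Type=String,Description=\"LOFTEE confidence\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence terms\">",
    "##INFO=<ID=SpliceAI_DS_AG,Number=1,Type=Float,Description=\"SpliceAI delta\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%s\t.\t%s\t%s\t%s\tPASS\t%s", df$chrom,
                  format_bp(df$pos), df$ref, df$alt,
                  format_bp(df$qual), df$info)
  writeLines(c(header, body), path)
  list(path = path,
       manifest = list(n_known_pathogenic = 2L, n_lof = 5L, n_splicing = 9L,
                       n_multi_label = 2L, n_distinct = 14L))
}

#' Write genome sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
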