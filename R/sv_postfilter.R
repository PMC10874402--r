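#' Read a structural-variant call table
#'
#' Accepts the tabular shape produced by long-read SV callers: one row
#' per junction with both breakends, the SV type, and any inserted
#' sequence. Columns (TSV with header): `sv_id`, `sv_type` (one of
#' deletion, insertion, duplication, inversion, translocation,
#' single_breakend), `chrom1`, `pos1`, `chrom2`, `pos2` (1-based; `pos2`
#' empty for single breakends), `inserted_seq` (may be empty).
#'
#' For intrachromosomal deletion/duplication/inversion records the
#' affected span is derived as `[min(pos1,pos2)-1, max(pos1,pos2))` in
#' internal coordinates.
#'
#' @param path TSV file.
#' @return data.frame of SV records with derived `span_start`/`span_end`.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(sv_id = "character",
                                         sv_type = "character",
                                         chrom1 = "character",
                                         chrom2 = "character"))
  validate_sv_table(df)
}

validate_sv_table <- function(df) {
  need <- c("sv_id", "sv_type", "chrom1", "pos1", "chrom2", "pos2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SV table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"inserted_seq" %in% names(df)) df$inserted_seq <- NA_character_
  ok_types <- c("deletion", "insertion", "duplication", "inversion",
                "translocation", "single_breakend")
  bad <- !df$sv_type %in% ok_types
  if (any(bad)) stop("unknown sv_type: ", paste(unique(df$sv_type[bad]), collapse = ", "))
  sbe <- df$sv_type == "single_breakend"
  if (any(!sbe & (is.na(df$pos2) | is.na(df$chrom2) | !nzchar(df$chrom2))))
    stop("non-single-breakend record without a second breakend")
  intra <- df$sv_type %in% c("deletion", "duplication", "inversion")
  if (any(intra & df$chrom1 != df$chrom2))
    stop("deletion/duplication/inversion with breakends on different chromosomes")
  if (any(df$sv_type == "translocation" & df$chrom1 == df$chrom2))
    stop("translocation with both breakends on one chromosome")
  df$span_start <- ifelse(intra, pmin(df$pos1, df$pos2) - 1, NA_real_)
  df$span_end <- ifelse(intra, pmax(df$pos1, df$pos2), NA_real_)
  df
}

#' False-positive SV elimination filter
#'
#' Drops a record iff any of three rules fires:
#' \describe{
#'   \item{off_primary_contig}{a breakend lies on a chromosome outside
#'     the primary contig set (unplaced contigs, decoys);}
#'   \item{outside_targets}{no breakend lies within the target regions;}
#'   \item{in_simple_repeat}{the record is a deletion, insertion or
#'     tandem duplication fully contained in one simple-repeat interval
#'     expanded by `repeat_margin` bp (both breakends -- or the single
#'     insertion point -- inside the same expanded interval).}
#' }
#' Containment (not mere overlap) is required for the repeat rule so that
#' large deletions extending beyond a repeat survive.
#'
#' @param svs SV table (see [read_sv_table()]).
#' @param targets Target `region_set`.
#' @param simple_repeats Simple-repeat `region_set`.
#' @param primary_contigs Character vector of allowed chromosome names.
#' @param repeat_margin Expansion applied to each repeat interval
#'   (default 10 bp).
#' @return `svs` with added columns `kept` (logical) and `fp_reasons`
#'   (comma-joined rule names, empty when kept).
#' @export
eliminate_false_positives <- function(svs, targets, simple_repeats,
                                      primary_contigs, repeat_margin = 10) {
  n <- nrow(svs)
  if (n == 0L) {
    svs$kept <- logical(0); svs$fp_reasons <- character(0)
    return(svs)
  }
  sbe <- svs$sv_type == "single_breakend"
  off_contig <- !svs$chrom1 %in% primary_contigs |
    (!sbe & !svs$chrom2 %in% primary_contigs)

  bp1_in <- position_in_regions(svs$chrom1, svs$pos1, targets)
  bp2_in <- rep(FALSE, n)
  bp2_in[!sbe] <- position_in_regions(svs$chrom2[!sbe], svs$pos2[!sbe], targets)
  outside <- !(bp1_in | bp2_in)

  in_repeat <- rep(FALSE, n)
  indel_dup <- svs$sv_type %in% c("deletion", "insertion", "duplication")
  if (any(indel_dup) && length(simple_repeats) > 0L) {
    rep_m <- merge(simple_repeats)
    ex_start <- pmax(0, rep_m$start - repeat_margin)
    ex_end <- rep_m$end + repeat_margin
    containing <- function(chrom, pos) {
      # indices of expanded repeat intervals containing the 1-based point
      which(rep_m$chrom == chrom & ex_start <= pos - 1 & ex_end >= pos)
    }
    for (i in which(indel_dup)) {
      h1 <- containing(svs$chrom1[i], svs$pos1[i])
      if (svs$sv_type[i] == "insertion") {
        in_repeat[i] <- length(h1) > 0L
      } else {
        h2 <- containing(svs$chrom2[i], svs$pos2[i])
        in_repeat[i] <- length(intersect(h1, h2)) > 0L
      }
    }
  }

  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "off_primary_contig", if (b) "outside_targets",
            if (c) "in_simple_repeat"), collapse = ",")
  }, off_contig, outside, in_repeat)
  svs$kept <- !(off_contig | outside | in_repeat)
  svs$fp_reasons <- as.character(reasons)
  svs
}

#' Putative pathogenic SV classification
#'
#' Applied to records surviving [eliminate_false_positives()]. A record
#' is putatively pathogenic iff one of four rules fires (the first
#' matching rule is recorded as the reason):
#' \describe{
#'   \item{deletion_hits_cds}{a deletion whose span intersects any CDS
#'     interval of a target gene;}
#'   \item{duplication_alters_cds}{a duplication with at least one
#'     breakend inside a target gene excluding its UTRs, whose amplified
#'     span covers at least one complete CDS interval;}
#'   \item{disrupts_gene_body}{an inversion or translocation with at
#'     least one breakend inside a gene region excluding UTRs;}
#'   \item{single_breakend_in_gene}{a single breakend lying within a
#'     target gene span (set `sbe_exclude_utr = TRUE` to restrict to
#'     non-UTR positions).}
#' }
#'
#' @param svs Output of [eliminate_false_positives()].
#' @param genes List of `gene_model`s (the target gene panel).
#' @param sbe_exclude_utr Restrict the single-breakend rule to non-UTR
#'   gene positions (default FALSE: full gene span).
#' @return `svs` with added columns `pathogenic` (logical; always FALSE
#'   for dropped records) and `pathogenic_reason`.
#' @export
classify_pathogenic_sv <- function(svs, genes, sbe_exclude_utr = FALSE) {
  n <- nrow(svs)
  pathogenic <- rep(FALSE, n)
  reason <- rep("none", n)

  gene_chrom <- vapply(genes, `[[`, "", "chrom")
  gene_start <- vapply(genes, function(g) g$span[["start"]], 0)
  gene_end <- vapply(genes, function(g) g$span[["end"]], 0)
  cds_list <- lapply(genes, gene_feature_intervals, "cds")
  utr_list <- lapply(genes, gene_feature_intervals, "utrs")

  in_gene_span <- function(chrom, pos) {
    # gene indices whose span contains the 1-based point
    which(gene_chrom == chrom & gene_start <= pos - 1 & gene_end >= pos)
  }
  in_gene_non_utr <- function(chrom, pos) {
    gi <- in_gene_span(chrom, pos)
    gi[vapply(gi, function(j) {
      u <- utr_list[[j]]
      nrow(u) == 0L || !any(u$start <= pos - 1 & u$end >= pos)
    }, FALSE)]
  }

  for (i in seq_len(n)) {
    if (!isTRUE(svs$kept[i])) next
    type <- svs$sv_type[i]
    if (type == "deletion") {
      hit <- any(vapply(seq_along(genes), function(j) {
        cds <- cds_list[[j]]
        gene_chrom[j] == svs$chrom1[i] && nrow(cds) > 0L &&
          any(cds$start < svs$span_end[i] & cds$end > svs$span_start[i])
      }, FALSE))
      if (hit) { pathogenic[i] <- TRUE; reason[i] <- "deletion_hits_cds" }
    } else if (type == "duplication") {
      gi <- unique(c(in_gene_non_utr(svs$chrom1[i], svs$pos1[i]),
                     in_gene_non_utr(svs$chrom2[i], svs$pos2[i])))
      covers <- any(vapply(gi, function(j) {
        cds <- cds_list[[j]]
        nrow(cds) > 0L &&
          any(cds$start >= svs$span_start[i] & cds$end <= svs$span_end[i])
      }, FALSE))
      if (length(gi) > 0L && covers) {
        pathogenic[i] <- TRUE; reason[i] <- "duplication_alters_cds"
      }
    } else if (type %in% c("inversion", "translocation")) {
      hit <- length(in_gene_non_utr(svs$chrom1[i], svs$pos1[i])) > 0L ||
        length(in_gene_non_utr(svs$chrom2[i], svs$pos2[i])) > 0L
      if (hit) { pathogenic[i] <- TRUE; reason[i] <- "disrupts_gene_body" }
    } else if (type == "single_breakend") {
      gi <- if (sbe_exclude_utr) in_gene_non_utr(svs$chrom1[i], svs$pos1[i])
            else in_gene_span(svs$chrom1[i], svs$pos1[i])
      if (length(gi) > 0L) {
        pathogenic[i] <- TRUE; reason[i] <- "single_breakend_in_gene"
      }
    }
  }
  svs$pathogenic <- pathogenic
  svs$pathogenic_reason <- reason
  svs
}

#' Full SV post-filtering pipeline
#'
#' [eliminate_false_positives()] followed by [classify_pathogenic_sv()].
#'
#' @inheritParams eliminate_false_positives
#' @inheritParams classify_pathogenic_sv
#' @return Classified SV table.
#' @export
filter_svs <- function(svs, targets, simple_repeats, primary_contigs, genes,
                       repeat_margin = 10, sbe_exclude_utr = FALSE) {
  out <- eliminate_false_positives(svs, targets, simple_repeats,
                                   primary_contigs, repeat_margin)
  classify_pathogenic_sv(out, genes, sbe_exclude_utr = sbe_exclude_utr)
}
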