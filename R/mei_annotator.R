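#' Construct a mobile-element insertion call
#'
#' Bundles a caller-reported insertion: reference insertion point,
#' inserted sequence, and reference flank windows adjacent to the site.
#' Insertions shorter than 50 bp are outside mobile-element scope and
#' rejected.
#'
#' @param chrom,pos Insertion site (1-based reference position of the
#'   base immediately right of the insertion point).
#' @param inserted_seq Inserted sequence as reported by the caller (may
#'   carry the target-site duplication at its 3' end; handled by
#'   [annotate_insertion()]).
#' @param left_flank,right_flank Reference windows adjacent to the site
#'   (default design: 100 bp each).
#' @return An `insertion_call` list.
#' @export
insertion_call <- function(chrom, pos, inserted_seq, left_flank, right_flank) {
  if (nchar(inserted_seq) < 50)
    stop("inserted sequence shorter than 50 bp: not in mobile-element scope")
  structure(list(chrom = chrom, pos = pos,
                 inserted_seq = toupper(inserted_seq),
                 left_flank = toupper(left_flank),
                 right_flank = toupper(right_flank)),
            class = "insertion_call")
}

#' Detect a target site duplication from the flanks
#'
#' Searches for the longest sequence `s` (between `min_tsd` and
#' `max_tsd` bp, at most `max_mismatch` mismatches) that is
#' simultaneously a suffix of `left_flank + inserted_seq` and a prefix
#' of `right_flank`. This is caller-agnostic: it finds the TSD whether
#' the caller placed the duplicated copy at the 3' end of the inserted
#' sequence or reported it in the flank.
#'
#' @param call An `insertion_call`.
#' @param max_tsd,min_tsd Length bounds in bp (defaults 50 / 5).
#' @param max_mismatch Allowed mismatches (default 1).
#' @return The TSD sequence (as found in the right flank), or `NULL`
#'   when no admissible duplication exists.
#' @export
detect_tsd <- function(call, max_tsd = 50, min_tsd = 5, max_mismatch = 1) {
  if (nchar(call$left_flank) < max_tsd || nchar(call$right_flank) < max_tsd)
    stop("flanks shorter than max_tsd (", max_tsd, " bp)")
  combined <- paste0(call$left_flank, call$inserted_seq)
  nc <- nchar(combined)
  for (len in seq(max_tsd, min_tsd)) {
    suf <- substr(combined, nc - len + 1, nc)
    pre <- substr(call$right_flank, 1, len)
    if (n_mismatch(suf, pre) <= max_mismatch) return(pre)
  }
  NULL
}

n_mismatch <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Measure a 3'-terminal poly-A tail
#'
#' Greedily extends a window from the 3' end while its non-A fraction
#' stays at or below `max_mismatch_frac`, then trims 5'-leading non-A
#' bases so the reported tail starts on an A. Returns 0 when the best
#' window is shorter than `min_len`.
#'
#' @param seq Sequence (poly-A is expected on the given strand; a minus
#'   strand 5' poly-T must be reverse-complemented first, which
#'   [annotate_insertion()] does).
#' @param min_len Minimum reportable tail (default 10 bp).
#' @param max_mismatch_frac Tolerated non-A fraction (default 0.1).
#' @return Tail length in bp.
#' @export
detect_polya <- function(seq, min_len = 10, max_mismatch_frac = 0.1) {
  n <- nchar(seq)
  if (n == 0L) return(0L)
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])  # 3' -> 5'
  non_a <- cumsum(chars != "A")
  lens <- seq_len(n)
  ok <- which(non_a <= max_mismatch_frac * lens)
  if (length(ok) == 0L) return(0L)
  best <- max(ok)
  while (best > 0L && chars[best] != "A") best <- best - 1L
  if (best < min_len) 0L else best
}

#' Detect the retrotransposition-competent hexamer head
#'
#' SVA elements begin with a (CCCTCT)n hexamer repeat required for
#' mobilization; a 5'-truncated insertion has lost it. Reports whether
#' at least `min_repeats` tandem copies of CCCTCT start within the first
#' 100 bp of the sequence.
#'
#' @param seq Element sequence, 5' first.
#' @param min_repeats Minimum tandem copies (default 2).
#' @return Logical.
#' @export
detect_hexamer_head <- function(seq, min_repeats = 2) {
  pat <- sprintf("(CCCTCT){%d,}", min_repeats)
  m <- regexpr(pat, seq)
  m[1L] != -1L && m[1L] <= 100L
}

#' Segment a sequence against a repeat consensus library
#'
#' Finds the maximal-scoring set of query-disjoint local alignments of
#' `seq` against the library consensus entries (greedy by score), then
#' tiles the remainder: every uncovered stretch is labelled
#' `unclassified`. Supports concatenated segments of the same or
#' different families (e.g. two adjacent SVA_F copies, or SVA_D + SVA_E).
#'
#' @param seq Sequence to segment.
#' @param lib Named character vector of consensus sequences (names are
#'   family labels, e.g. `SVA_F`, `L1`, `AluY`).
#' @param min_identity Minimum percent identity for a reported segment
#'   (default 80).
#' @param min_seg Minimum classified segment length in bp (default 100).
#' @param k Seed k-mer size (default 15).
#' @return data.frame of segments tiling `[0, nchar(seq))`: `start`,
#'   `end` (query, 0-based half-open), `label`, `cons_start`, `cons_end`
#'   (consensus coordinates, NA for unclassified), `identity`.
#' @export
segment_against_library <- function(seq, lib, min_identity = 80,
                                    min_seg = 100, k = 15) {
  if (length(lib) == 0L) stop("empty repeat library")
  if (is.null(names(lib)) || any(!nzchar(names(lib))))
    stop("library entries must be named")
  hits <- do.call(rbind, lapply(names(lib), function(fam) {
    h <- local_align_hits(seq, toupper(lib[[fam]]), k = k)
    if (nrow(h)) h$label <- fam
    h
  }))
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$n_match >= min_seg & hits$identity >= min_identity, ,
                 drop = FALSE]
  }
  segs <- if (is.null(hits) || nrow(hits) == 0L) {
    data.frame(start = numeric(0), end = numeric(0), label = character(0),
               cons_start = numeric(0), cons_end = numeric(0),
               identity = numeric(0))
  } else {
    sel <- select_disjoint_hits(hits)
    data.frame(start = sel$q_start, end = sel$q_end, label = sel$label,
               cons_start = sel$s_start, cons_end = sel$s_end,
               identity = sel$identity)
  }
  tile_with_unclassified(segs, nchar(seq))
}

## fill gaps between classified segments with 'unclassified' rows so the
## result tiles [0, n)
tile_with_unclassified <- function(segs, n) {
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- list(); cur <- 0
  add_gap <- function(from, to) {
    data.frame(start = from, end = to, label = "unclassified",
               cons_start = NA_real_, cons_end = NA_real_,
               identity = NA_real_)
  }
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cur) out[[length(out) + 1L]] <- add_gap(cur, segs$start[i])
    out[[length(out) + 1L]] <- segs[i, , drop = FALSE]
    cur <- segs$end[i]
  }
  if (cur < n) out[[length(out) + 1L]] <- add_gap(cur, n)
  res <- do.call(rbind, out)
  if (is.null(res)) res <- add_gap(0, n)[0, ]
  rownames(res) <- NULL
  res
}

#' Trace the source locus and 3' transduction of an insertion
#'
#' Aligns the insertion minus its poly-A tail to the reference genome
#' (both strands). The best-scoring locus is the source; the 3'-terminal
#' aligned stretch falling outside the repeat mask but genomically
#' contiguous (within `max_gap` bp) with the masked source element is
#' the 3' transduction -- unique downstream sequence carried along during
#' retrotransposition, diagnostic of the source. The canonical
#' polyadenylation signal AATAAA is searched within the transduction.
#'
#' @param seq Insertion sequence (strand-normalized, TSD-trimmed).
#' @param reference Named character vector of reference chromosome
#'   sequences.
#' @param repeat_mask `region_set` of annotated repeat loci in the
#'   reference.
#' @param polya_len Previously measured poly-A length (bp) to exclude.
#' @param min_score Minimum aligned bases to accept a source (default
#'   100).
#' @param max_gap Maximum separation between element and transduction in
#'   the reference (default 1000 bp).
#' @return List: `source_locus` (list chrom/start/end/strand or NULL),
#'   `transduction_len`, `transduction_ref` (reference interval or NULL),
#'   `transduction_seq`, `polya_signal_found`.
#' @export
trace_source_and_transduction <- function(seq, reference, repeat_mask,
                                          polya_len = 0, min_score = 100,
                                          max_gap = 1000) {
  none <- list(source_locus = NULL, transduction_len = 0L,
               transduction_ref = NULL, transduction_seq = "",
               polya_signal_found = FALSE)
  core <- substr(seq, 1, nchar(seq) - polya_len)
  if (nchar(core) < min_score) return(none)
  best <- NULL
  for (chrom in names(reference)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") core else revcomp(core)
      h <- local_align_hits(q, reference[[chrom]])
      if (nrow(h) == 0L) next
      h1 <- h[1L, ]
      if (is.null(best) || h1$n_match > best$n_match) {
        best <- h1; best$chrom <- chrom; best$strand <- strand
      }
    }
  }
  if (is.null(best) || best$n_match < min_score) return(none)
  src <- list(chrom = best$chrom, start = best$s_start, end = best$s_end,
              strand = best$strand)
  ## unmasked 3'-side of the aligned locus = candidate transduction
  mk <- merge(repeat_mask)
  sel <- mk$chrom == best$chrom & mk$start < best$s_end & mk$end > best$s_start
  if (!any(sel)) return(c(list(source_locus = src), none[-1L]))
  if (best$strand == "+") {
    mask_hi <- max(mk$end[sel])
    td_start <- min(mask_hi, best$s_end); td_end <- best$s_end
  } else {
    mask_lo <- min(mk$start[sel])
    td_start <- best$s_start; td_end <- max(mask_lo, best$s_start)
  }
  td_len <- max(0, td_end - td_start)
  if (td_len == 0L || td_len > max_gap)
    return(list(source_locus = src, transduction_len = 0L,
                transduction_ref = NULL, transduction_seq = "",
                polya_signal_found = FALSE))
  n_core <- nchar(core)
  td_seq <- substr(core, n_core - td_len + 1, n_core)
  list(source_locus = src,
       transduction_len = as.integer(td_len),
       transduction_ref = list(chrom = best$chrom, start = td_start,
                               end = td_end),
       transduction_seq = td_seq,
       polya_signal_found = grepl("AATAAA", td_seq, fixed = TRUE))
}

#' Annotate a mobile-element insertion
#'
#' Orchestrates the full characterization of an insertion call the way a
#' curator would read a retrotransposition event: target site
#' duplication from the flanks (trimming a TSD copy off the inserted
#' sequence's 3' end if the caller reported one there), strand
#' normalization (the strand with the better total library alignment
#' wins; a minus-strand event's 5' poly-T becomes a 3' poly-A), poly-A
#' tail measurement, repeat-family segmentation, source-locus /
#' 3'-transduction tracing with AATAAA signal check, and 5' hexamer-head
#' ((CCCTCT)n) truncation status.
#'
#' @param call An `insertion_call`.
#' @param lib Named character vector of repeat consensus sequences.
#' @param reference Named character vector of reference chromosomes.
#' @param repeat_mask `region_set` of repeat loci in the reference.
#' @param min_identity,min_seg Segmentation parameters (see
#'   [segment_against_library()]).
#' @param max_tsd,min_tsd,max_mismatch TSD parameters (see
#'   [detect_tsd()]).
#' @return A `mei_annotation` list: `segments` (tiling the analyzed
#'   sequence), `tsd_seq`, `tsd_len`, `polya_len`, `transduction_len`,
#'   `polya_signal_found`, `source_locus`, `hexamer_head_present`,
#'   `five_prime_truncated`, `strand`, `analyzed_seq`.
#' @export
annotate_insertion <- function(call, lib, reference, repeat_mask,
                               min_identity = 80, min_seg = 100,
                               max_tsd = 50, min_tsd = 5, max_mismatch = 1) {
  stopifnot(inherits(call, "insertion_call"))
  tsd <- detect_tsd(call, max_tsd = max_tsd, min_tsd = min_tsd,
                    max_mismatch = max_mismatch)
  seq <- call$inserted_seq
  if (!is.null(tsd)) {
    tl <- nchar(tsd)
    tail_seq <- substr(seq, nchar(seq) - tl + 1, nchar(seq))
    if (n_mismatch(tail_seq, tsd) <= max_mismatch)
      seq <- substr(seq, 1, nchar(seq) - tl)
  }
  ## strand: total library alignment score decides
  score_for <- function(s) {
    tot <- 0
    for (fam in names(lib)) {
      h <- local_align_hits(s, toupper(lib[[fam]]))
      if (nrow(h)) tot <- tot + sum(select_disjoint_hits(h)$n_match)
    }
    tot
  }
  strand <- "+"
  if (length(lib) > 0L) {
    rc <- revcomp(seq)
    if (score_for(rc) > score_for(seq)) { seq <- rc; strand <- "-" }
  }
  polya_len <- detect_polya(seq)
  core <- substr(seq, 1, nchar(seq) - polya_len)
  segs <- segment_against_library(core, lib, min_identity = min_identity,
                                  min_seg = min_seg)
  src <- trace_source_and_transduction(seq, reference, repeat_mask,
                                       polya_len = polya_len)
  n <- nchar(seq)
  td <- src$transduction_len
  if (td > 0L) {
    ## relabel the 3'-terminal td bases of the core as transduction
    cut <- nchar(core) - td
    keep <- segs[segs$start < cut, , drop = FALSE]
    if (nrow(keep)) keep$end[nrow(keep)] <- pmin(keep$end[nrow(keep)], cut)
    segs <- rbind(keep, data.frame(start = cut, end = nchar(core),
                                   label = "transduction",
                                   cons_start = NA_real_, cons_end = NA_real_,
                                   identity = NA_real_))
  }
  if (polya_len > 0L)
    segs <- rbind(segs, data.frame(start = n - polya_len, end = n,
                                   label = "polyA", cons_start = NA_real_,
                                   cons_end = NA_real_, identity = NA_real_))
  rownames(segs) <- NULL
  fam_rows <- which(!segs$label %in% c("unclassified", "transduction", "polyA"))
  elem_start <- if (length(fam_rows)) segs$start[fam_rows[1L]] else 0
  head_seq <- substr(seq, elem_start + 1, nchar(seq))
  hex <- detect_hexamer_head(head_seq)
  structure(list(
    segments = segs,
    tsd_seq = tsd,
    tsd_len = if (is.null(tsd)) 0L else nchar(tsd),
    polya_len = polya_len,
    transduction_len = td,
    polya_signal_found = src$polya_signal_found,
    source_locus = src$source_locus,
    hexamer_head_present = hex,
    five_prime_truncated = !hex,
    strand = strand,
    analyzed_seq = seq), class = "mei_annotation")
}

#' @export
print.mei_annotation <- function(x, ...) {
  src <- if (is.null(x$source_locus)) "none" else
    sprintf("%s:%s-%s(%s)", x$source_locus$chrom,
            format_bp(x$source_locus$start + 1),
            format_bp(x$source_locus$end), x$source_locus$strand)
  cat(sprintf(paste0("mei_annotation: %d bp analyzed [%s], TSD %d bp, ",
                     "polyA %d bp, transduction %d bp (AATAAA %s), source %s, ",
                     "hexamer head %s\n"),
              nchar(x$analyzed_seq), x$strand, x$tsd_len, x$polya_len,
              x$transduction_len, ifelse(x$polya_signal_found, "found", "absent"),
              src, ifelse(x$hexamer_head_present, "present", "absent (5' truncated)")))
  invisible(x)
}
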