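rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

test_that("a planted TSD is recovered from the flanks", {
  set.seed(100)
  L <- rand_seq(100); R_tail <- rand_seq(86)
  s <- "GATTACAGATTACA"  # 14 bp
  ins <- paste0(rand_seq(300), s)          # caller put the TSD copy 3'-terminal
  call <- insertion_call("chr1", 101, ins, left_flank = L,
                         right_flank = paste0(s, R_tail))
  expect_equal(detect_tsd(call), s)
})

test_that("unrelated flanks yield no TSD and short TSDs are rejected", {
  set.seed(4)
  call <- insertion_call("chr1", 101, rand_seq(300),
                         left_flank = rand_seq(100),
                         right_flank = rand_seq(100))
  # brute-force scan confirms no admissible duplication exists at this seed
  comb <- paste0(call$left_flank, call$inserted_seq)
  any_match <- FALSE
  for (len in 5:50) {
    suf <- substr(comb, nchar(comb) - len + 1, nchar(comb))
    pre <- substr(call$right_flank, 1, len)
    mm <- sum(strsplit(suf, "")[[1]] != strsplit(pre, "")[[1]])
    if (mm <= 1) any_match <- TRUE
  }
  expect_false(any_match)
  expect_null(detect_tsd(call))

  # a 4 bp duplication is below min_tsd
  set.seed(101)
  s4 <- "ACGT"
  call4 <- insertion_call("chr1", 101, paste0(rand_seq(300), s4),
                          left_flank = rand_seq(100),
                          right_flank = paste0(s4, rand_seq(96)))
  got <- detect_tsd(call4)
  expect_true(is.null(got) || nchar(got) >= 5)

  expect_error(detect_tsd(insertion_call("chr1", 1, rand_seq(60),
                                         "ACGT", "ACGT")),
               "flanks")
})

test_that("poly-A measurement is exact on planted tails", {
  set.seed(102)
  body <- paste0(rand_seq(200), "CGT")  # A-free junction
  expect_equal(detect_polya(paste0(body, strrep("A", 24))), 24)
  expect_equal(detect_polya(paste0(rand_seq(200), "TTTT")), 0)
  expect_equal(detect_polya("AAAA"), 0)        # below min_len
  expect_equal(detect_polya(strrep("A", 30)), 30)
  # one mismatch inside a long tail is tolerated
  tail <- paste0(strrep("A", 10), "G", strrep("A", 14))
  expect_gte(detect_polya(paste0(body, tail)), 14)
})

test_that("hexamer head detection honours the 100 bp window", {
  expect_true(detect_hexamer_head(paste0("CCCTCTCCCTCT", rand_seq(200))))
  expect_false(detect_hexamer_head(rand_seq(300)))
  expect_false(detect_hexamer_head(paste0(rand_seq(150), "CCCTCTCCCTCT")))
  expect_true(detect_hexamer_head(paste0(rand_seq(80), "CCCTCTCCCTCT",
                                         rand_seq(100))))
})

test_that("library segmentation recovers concatenated consensus slices", {
  set.seed(6)
  lib <- make_repeat_library(6)
  a <- substr(lib[["SVA_D"]], 201, 1200)   # consensus D [200, 1200)
  b <- substr(lib[["SVA_E"]], 1, 1000)     # consensus E [0, 1000)
  segs <- segment_against_library(paste0(a, b), lib)
  cls <- segs[segs$label != "unclassified", ]
  expect_equal(nrow(cls), 2L)
  expect_equal(cls$label, c("SVA_D", "SVA_E"))
  expect_lte(abs(cls$start[1] - 0), 10)
  expect_lte(abs(cls$end[1] - 1000), 10)
  expect_lte(abs(cls$cons_start[1] - 200), 10)
  expect_lte(abs(cls$end[2] - 2000), 10)

  # a random sequence maps to a single unclassified segment
  rnd <- segment_against_library(rand_seq(800), lib)
  expect_equal(rnd$label, "unclassified")
  expect_equal(c(rnd$start, rnd$end), c(0, 800))

  # an exact full-length copy is one segment at identity 100
  full <- segment_against_library(lib[["AluY"]], lib["AluY"])
  expect_equal(nrow(full), 1L)
  expect_equal(full$identity, 100)
  # segments always tile the query
  expect_equal(sum(segs$end - segs$start), 2000)
})

test_that("source tracing finds the locus and the unmasked transduction", {
  ev <- make_mei_event(8)
  ann_polya <- ev$manifest$polya_len
  core_plus_tail <- ev$call$inserted_seq
  # strip the caller-style TSD copy for direct tracing
  seq <- substr(core_plus_tail, 1, nchar(core_plus_tail) - ev$manifest$tsd_len)
  tr <- trace_source_and_transduction(seq, ev$genome$sequences,
                                      ev$genome$repeat_mask,
                                      polya_len = ann_polya)
  expect_equal(tr$transduction_len, ev$manifest$transduction_len)
  expect_equal(tr$source_locus$start, ev$manifest$source_locus$start)
  expect_equal(tr$source_locus$end, ev$manifest$source_locus$end)
  expect_true(tr$polya_signal_found)

  # no tail beyond the element: no transduction
  ev0 <- make_mei_event(8, transduction_len = 0)
  seq0 <- substr(ev0$call$inserted_seq, 1,
                 nchar(ev0$call$inserted_seq) - ev0$manifest$tsd_len)
  tr0 <- trace_source_and_transduction(seq0, ev0$genome$sequences,
                                       ev0$genome$repeat_mask,
                                       polya_len = ev0$manifest$polya_len)
  expect_equal(tr0$transduction_len, 0L)
  expect_false(tr0$polya_signal_found)
})

test_that("full annotation recovers the planted event structure", {
  # two SVA_F copies, 82 bp transduction, 24 bp polyA, 14 bp TSD
  ev <- make_mei_event(12)
  ann <- annotate_insertion(ev$call, ev$lib, ev$genome$sequences,
                            ev$genome$repeat_mask)
  m <- ev$manifest
  expect_equal(ann$tsd_len, m$tsd_len)
  expect_equal(ann$tsd_seq, m$tsd_seq)
  expect_equal(ann$polya_len, m$polya_len)
  expect_equal(ann$transduction_len, m$transduction_len)
  expect_equal(ann$source_locus$start, m$source_locus$start)
  expect_equal(ann$source_locus$end, m$source_locus$end)
  expect_true(ann$polya_signal_found)
  expect_false(ann$hexamer_head_present)   # 5' truncated by construction
  expect_true(ann$five_prime_truncated)
  fams <- ann$segments$label[!ann$segments$label %in%
                               c("unclassified", "transduction", "polyA")]
  expect_equal(fams, c("SVA_F", "SVA_F"))

  # SVA_D + SVA_E, 91 bp transduction, 55 bp polyA, 15 bp TSD
  ev2 <- make_mei_event(14, families = c("SVA_D", "SVA_E"), tsd_len = 15,
                        polya_len = 55, transduction_len = 91)
  ann2 <- annotate_insertion(ev2$call, ev2$lib, ev2$genome$sequences,
                             ev2$genome$repeat_mask)
  expect_equal(c(ann2$tsd_len, ann2$polya_len, ann2$transduction_len),
               c(15, 55, 91))

  # untruncated element keeps its hexamer head
  ev3 <- make_mei_event(15, truncation_5p = 0)
  ann3 <- annotate_insertion(ev3$call, ev3$lib, ev3$genome$sequences,
                             ev3$genome$repeat_mask)
  expect_true(ann3$hexamer_head_present)
})

test_that("segment lengths conserve the analyzed sequence", {
  ev <- make_mei_event(16)
  ann <- annotate_insertion(ev$call, ev$lib, ev$genome$sequences,
                            ev$genome$repeat_mask)
  expect_equal(sum(ann$segments$end - ann$segments$start),
               nchar(ann$analyzed_seq))
  # TSD accounting: analyzed + trimmed TSD = caller-reported insertion
  expect_equal(nchar(ann$analyzed_seq) + ann$tsd_len,
               nchar(ev$call$inserted_seq))
  ks <- ann$segments
  expect_true(all(ks$start[-1] == ks$end[-nrow(ks)]))  # contiguous tiling
  expect_equal(ks$label[nrow(ks)], "polyA")            # polyA is 3'-terminal
})

test_that("a reverse-complemented event is normalized back to plus strand", {
  ev <- make_mei_event(17)
  flip <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # an element inserted in reverse orientation: the body flips, the TSD
  # stays in reference orientation at the 3' end of the reported sequence
  ins <- ev$call$inserted_seq
  tl <- ev$manifest$tsd_len
  body <- substr(ins, 1, nchar(ins) - tl)
  tsd <- substr(ins, nchar(ins) - tl + 1, nchar(ins))
  call_rc <- insertion_call(ev$call$chrom, ev$call$pos,
                            paste0(flip(body), tsd),
                            ev$call$left_flank, ev$call$right_flank)
  ann <- annotate_insertion(call_rc, ev$lib, ev$genome$sequences,
                            ev$genome$repeat_mask)
  expect_equal(ann$strand, "-")
  expect_equal(ann$polya_len, ev$manifest$polya_len)
  expect_equal(ann$transduction_len, ev$manifest$transduction_len)
})

test_that("a non-MEI insertion yields one unclassified segment, no source", {
  set.seed(103)
  g <- make_genome(103, c(chr1 = 20000))
  lib <- make_repeat_library(103)
  call <- insertion_call("chr1", 5000, rand_seq(500),
                         substr(g$sequences[["chr1"]], 4900, 4999),
                         substr(g$sequences[["chr1"]], 5000, 5099))
  ann <- annotate_insertion(call, lib, g$sequences, g$repeat_mask)
  expect_null(ann$source_locus)
  expect_equal(ann$transduction_len, 0L)
  cls <- ann$segments[ann$segments$label != "polyA", ]
  expect_true(all(cls$label == "unclassified"))
})

test_that("insertions below 50 bp are rejected as out of scope", {
  expect_error(insertion_call("chr1", 100, "ACGT", rand_seq(100),
                              rand_seq(100)), "50 bp")
})
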