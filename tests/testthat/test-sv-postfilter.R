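sv_row <- function(sv_id, sv_type, chrom1, pos1, chrom2 = chrom1, pos2 = NA) {
  taslrs:::validate_sv_table(
    data.frame(sv_id = sv_id, sv_type = sv_type, chrom1 = chrom1,
                         pos1 = pos1, chrom2 = ifelse(is.na(pos2), "", chrom2),
                         pos2 = pos2, inserted_seq = NA_character_,
                         stringsAsFactors = FALSE))
}

test_that("elimination rules fire as specified", {
  targets <- region_set("chr1", 0, 10000, label = "targets")
  reps <- region_set("chr1", 500, 600, label = "simple_repeats")
  contigs <- c("chr1", "chr2")

  # deletion contained in a repeat (with the 10 bp margin), breakend on target
  del <- sv_row("d1", "deletion", "chr1", 495, "chr1", 608)
  out <- eliminate_false_positives(del, targets, reps, contigs)
  expect_false(out$kept)
  expect_equal(out$fp_reasons, "in_simple_repeat")

  # same span but extending beyond the expanded repeat: kept (containment,
  # not overlap)
  big <- sv_row("d2", "deletion", "chr1", 480, "chr1", 700)
  expect_true(eliminate_false_positives(big, targets, reps, contigs)$kept)

  # breakend on an unplaced contig
  tra <- sv_row("t1", "translocation", "chrUn_x", 100, "chr1", 1000)
  out <- eliminate_false_positives(tra, targets, reps, contigs)
  expect_false(out$kept)
  expect_match(out$fp_reasons, "off_primary_contig")

  # neither breakend in targets
  far <- sv_row("d3", "deletion", "chr1", 20000, "chr1", 20100)
  out <- eliminate_false_positives(far, targets, reps, contigs)
  expect_false(out$kept)
  expect_equal(out$fp_reasons, "outside_targets")

  # inversion with a breakend in the target, none in repeats: kept
  inv <- sv_row("i1", "inversion", "chr1", 2000, "chr1", 3000)
  expect_true(eliminate_false_positives(inv, targets, reps, contigs)$kept)

  # the repeat rule does not apply to inversions at all
  inv_rep <- sv_row("i2", "inversion", "chr1", 510, "chr1", 590)
  expect_true(eliminate_false_positives(inv_rep, targets, reps, contigs)$kept)
})

test_that("the filter is idempotent and output is a subset of input", {
  fx <- sv_fixture(7)
  out1 <- eliminate_false_positives(fx$svs, fx$targets, fx$simple_repeats,
                                    fx$primary_contigs)
  out2 <- eliminate_false_positives(out1[out1$kept, names(fx$svs)],
                                    fx$targets, fx$simple_repeats,
                                    fx$primary_contigs)
  expect_true(all(out2$kept))
  expect_lte(sum(out1$kept), nrow(fx$svs))
})

test_that("pathogenic classification follows the four category rules", {
  # gene A: two CDS exons; gene B: downstream neighbour
  gA <- toy_gene("A", "chr1", 1000, 5000,
                 exons = data.frame(start = c(1000, 4000),
                                    end = c(1500, 5000)),
                 cds = data.frame(start = c(1100, 4000),
                                  end = c(1500, 4800)),
                 utrs = data.frame(start = c(1000, 4800),
                                   end = c(1100, 5000)))
  gB <- toy_gene("B", "chr1", 7000, 9000)
  genes <- list(gA, gB)
  keptify <- function(sv) { sv$kept <- TRUE; sv$fp_reasons <- ""; sv }

  # deletion from A's intron through B, taking A's last CDS exon
  del <- keptify(sv_row("d", "deletion", "chr1", 2000, "chr1", 8000))
  out <- classify_pathogenic_sv(del, genes)
  expect_true(out$pathogenic)
  expect_equal(out$pathogenic_reason, "deletion_hits_cds")

  # intergenic inversion: benign
  inv <- keptify(sv_row("i", "inversion", "chr1", 5500, "chr1", 6500))
  expect_false(classify_pathogenic_sv(inv, genes)$pathogenic)

  # inversion with one breakend in CDS: pathogenic
  inv2 <- keptify(sv_row("i2", "inversion", "chr1", 1200, "chr1", 6500))
  expect_equal(classify_pathogenic_sv(inv2, genes)$pathogenic_reason,
               "disrupts_gene_body")

  # inversion breakend in a UTR only: not pathogenic
  inv3 <- keptify(sv_row("i3", "inversion", "chr1", 1050, "chr1", 6500))
  expect_false(classify_pathogenic_sv(inv3, genes)$pathogenic)

  # duplication anchored in the UTR with no CDS covered: benign
  dup <- keptify(sv_row("u", "duplication", "chr1", 1010, "chr1", 1080))
  expect_false(classify_pathogenic_sv(dup, genes)$pathogenic)

  # duplication anchored in CDS covering a full CDS exon: pathogenic
  dup2 <- keptify(sv_row("u2", "duplication", "chr1", 1200, "chr1", 4900))
  expect_equal(classify_pathogenic_sv(dup2, genes)$pathogenic_reason,
               "duplication_alters_cds")

  # single breakend inside the gene span (intron): pathogenic
  sbe <- keptify(sv_row("s", "single_breakend", "chr1", 2500))
  expect_equal(classify_pathogenic_sv(sbe, genes)$pathogenic_reason,
               "single_breakend_in_gene")

  # dropped records are never classified
  dropped <- sv_row("x", "single_breakend", "chr1", 2500)
  dropped$kept <- FALSE; dropped$fp_reasons <- "outside_targets"
  expect_false(classify_pathogenic_sv(dropped, genes)$pathogenic)
})

test_that("generated callset outcomes match the manifest exactly", {
  fx <- sv_fixture(7)
  out <- filter_svs(fx$svs, fx$targets, fx$simple_repeats,
                    fx$primary_contigs, fx$genes)
  cmp <- merge(out, fx$manifest, by = "sv_id")
  expect_equal(cmp$kept, cmp$expected_kept)
  expect_equal(cmp$fp_reasons, cmp$expected_reason)
  expect_equal(cmp$pathogenic, cmp$expected_pathogenic)
  expect_equal(cmp$pathogenic_reason, cmp$expected_pathogenic_reason)
  # every pathogenic call carries exactly one reason, and it matches type
  path <- out[out$pathogenic, ]
  expect_true(all(path$pathogenic_reason != "none"))
  expect_true(all(path$kept))
})

test_that("SV table validation rejects inconsistent records", {
  expect_error(sv_row("b", "deletion", "chr1", 100, "chr2", 200),
               "different chromosomes")
  expect_error(sv_row("b", "translocation", "chr1", 100, "chr1", 200),
               "one chromosome")
  expect_error(sv_row("b", "badtype", "chr1", 100, "chr1", 200),
               "unknown sv_type")
  expect_error(sv_row("b", "deletion", "chr1", 100), "second breakend")
})
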