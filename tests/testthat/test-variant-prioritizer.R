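vt <- function(quality = 50, af_gnomad = NA, af_tommo = NA,
               clinvar_sig = NA, loftee = NA, consequences = NA,
               spliceai_max = NA, chrom = "chr1", pos = 500) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             quality = quality, af_gnomad = af_gnomad, af_tommo = af_tommo,
             clinvar_sig = clinvar_sig, loftee = loftee,
             consequences = consequences, spliceai_max = spliceai_max,
             stringsAsFactors = FALSE)
}

test_that("quality boundary is strict: records at the cutoff are dropped", {
  expect_false(quality_filter(vt(quality = 10)))
  expect_true(quality_filter(vt(quality = 10.01)))
  expect_false(quality_filter(vt(quality = 0)))
  expect_warning(k <- quality_filter(vt(quality = NA)), "without quality")
  expect_false(k)
  expect_true(quality_filter(vt(quality = NA), missing_quality = "keep"))
})

test_that("frequency boundary is inclusive and absent sources count as 0", {
  expect_true(is_common_variant(vt(af_gnomad = 0.01)))
  expect_false(is_common_variant(vt(af_gnomad = 0.0099, af_tommo = 0.0099)))
  expect_false(is_common_variant(vt()))
  # either source suffices (OR semantics)
  expect_true(is_common_variant(vt(af_tommo = 0.5)))
})

test_that("analysis region requires gene span and excludes both masks", {
  spans <- region_set("chr1", 0, 1000, label = "gene_spans")
  reps <- region_set("chr1", 400, 450, label = "simple_repeats")
  sd <- region_set("chr1", 800, 900, label = "segdups")
  expect_true(in_analysis_region(vt(pos = 500), spans, reps, sd))
  expect_false(in_analysis_region(vt(pos = 420), spans, reps, sd))
  expect_false(in_analysis_region(vt(pos = 850), spans, reps, sd))
  expect_false(in_analysis_region(vt(pos = 5000), spans, reps, sd))
})

test_that("region membership battery matches the per-base oracle", {
  set.seed(21)
  len <- 10000
  spans <- merge(random_region_set(10, len))
  reps <- merge(random_region_set(5, len, max_width = 100))
  sd <- merge(random_region_set(5, len, max_width = 100))
  pos <- sample.int(len - 1, 300)
  v <- data.frame(chrom = "chr1", pos = pos)
  got <- in_analysis_region(v, spans, reps, sd)
  want <- vapply(pos, function(p) {
    orc_overlaps("chr1", p - 1, p, spans, 0, len) &&
      !orc_overlaps("chr1", p - 1, p, reps, 0, len) &&
      !orc_overlaps("chr1", p - 1, p, sd, 0, len)
  }, FALSE)
  expect_equal(got, want)
})

test_that("pathogenicity labels follow the three extraction rules", {
  known <- classify_variants(vt(clinvar_sig = "Pathogenic"))
  expect_true(known$known_pathogenic)
  expect_false(known$lof || known$splicing)
  # combined and case-insensitive ClinVar forms
  expect_true(classify_variants(
    vt(clinvar_sig = "Pathogenic/Likely_pathogenic"))$known_pathogenic)
  expect_true(classify_variants(
    vt(clinvar_sig = "likely pathogenic"))$known_pathogenic)
  expect_false(classify_variants(vt(clinvar_sig = "Benign"))$known_pathogenic)
  # SpliceAI threshold is inclusive at 0.50
  expect_true(classify_variants(vt(spliceai_max = 0.50))$splicing)
  expect_false(classify_variants(vt(spliceai_max = 0.49))$splicing)
  # essential splice-site consequence without any delta score
  expect_true(classify_variants(
    vt(consequences = "splice_donor_variant"))$splicing)
  # LOFTEE HC only
  expect_true(classify_variants(vt(loftee = "HC"))$lof)
  expect_false(classify_variants(vt(loftee = "LC"))$lof)
  # a variant can carry two labels
  two <- classify_variants(vt(loftee = "HC",
                              consequences = "splice_donor_variant"))
  expect_true(two$lof && two$splicing)
  expect_equal(two$n_labels, 2L)
})

test_that("summary distinct total obeys inclusion-exclusion", {
  # 2 known, 5 lof, 9 splicing with exactly two lof+splicing doubles
  rows <- rbind(
    do.call(rbind, replicate(2, vt(clinvar_sig = "Pathogenic"),
                             simplify = FALSE)),
    do.call(rbind, replicate(3, vt(loftee = "HC"), simplify = FALSE)),
    do.call(rbind, replicate(2, vt(loftee = "HC",
                                   consequences = "splice_donor_variant"),
                             simplify = FALSE)),
    do.call(rbind, replicate(7, vt(spliceai_max = 0.9), simplify = FALSE)))
  s <- summarize_calls(classify_variants(rows))
  expect_equal(s$n_known_pathogenic, 2L)
  expect_equal(s$n_lof, 5L)
  expect_equal(s$n_splicing, 9L)
  expect_equal(s$n_multi_label, 2L)
  expect_equal(s$n_distinct, 14L)
  expect_equal(summarize_calls(classify_variants(vt()[0, ]))$n_distinct, 0L)
})

test_that("random label assignments match an explicit set union", {
  set.seed(2)
  for (rep in 1:3) {
    n <- 50
    df <- do.call(rbind, lapply(seq_len(n), function(i) vt(
      clinvar_sig = sample(c(NA, "Pathogenic"), 1),
      loftee = sample(c(NA, "HC"), 1),
      spliceai_max = sample(c(NA, 0.8), 1))))
    cls <- classify_variants(df)
    s <- summarize_calls(cls)
    union_ids <- unique(c(which(cls$known_pathogenic), which(cls$lof),
                          which(cls$splicing)))
    expect_equal(s$n_distinct, length(union_ids))
    expect_lte(s$n_distinct, s$n_known_pathogenic + s$n_lof + s$n_splicing)
  }
})

test_that("the VCF pipeline recovers the planted category structure", {
  cs <- c(chr1 = 200000, chr2 = 60000)
  ga <- make_gene_annotation(7, cs, n_genes = 10)
  reps <- region_set("chr1", 10, 60, label = "simple_repeats")
  p <- withr::local_tempfile(fileext = ".vcf")
  fx <- make_annotated_snv_vcf(9, ga$genes, reps, path = p)
  v <- read_annotated_vcf(p)
  res <- prioritize_variants(v, merge(gene_spans(ga$genes)), reps,
                             region_set(label = "segdups"))
  m <- fx$manifest
  expect_equal(res$summary$n_known_pathogenic, m$n_known_pathogenic)
  expect_equal(res$summary$n_lof, m$n_lof)
  expect_equal(res$summary$n_splicing, m$n_splicing)
  expect_equal(res$summary$n_multi_label, m$n_multi_label)
  expect_equal(res$summary$n_distinct, m$n_distinct)
})

test_that("filter order does not change the surviving set", {
  cs <- c(chr1 = 200000, chr2 = 60000)
  ga <- make_gene_annotation(7, cs, n_genes = 10)
  p <- withr::local_tempfile(fileext = ".vcf")
  make_annotated_snv_vcf(3, ga$genes, NULL, path = p)
  v <- read_annotated_vcf(p)
  spans <- merge(gene_spans(ga$genes))
  reps <- region_set(label = "simple_repeats")
  sd <- region_set(label = "segdups")
  k1 <- quality_filter(v) & in_analysis_region(v, spans, reps, sd) &
    !is_common_variant(v)
  k2 <- !is_common_variant(v) & quality_filter(v) &
    in_analysis_region(v, spans, reps, sd)
  expect_equal(k1, k2)
})
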