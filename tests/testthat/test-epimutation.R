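test_that("methylation ratio handles zero coverage as undefined", {
  expect_equal(methylation_ratio(5, 5), 0.5)
  expect_equal(methylation_ratio(0, 7), 0)
  expect_true(is.na(methylation_ratio(0, 0)))
})

test_that("site classes demand the interval in every covered control", {
  lowm <- rep(1, 10); lown <- rep(9, 10)          # ratio 0.1, coverage 10
  expect_equal(classify_site(lowm, lown), "normally_unmethylated")
  expect_equal(classify_site(rep(9, 10), rep(1, 10)), "normally_methylated")
  # one control off the interval breaks the class
  expect_equal(classify_site(c(rep(1, 9), 5), c(rep(9, 9), 15)), "other")
  # one zero-coverage control breaks it too
  expect_equal(classify_site(c(rep(1, 9), 0), c(rep(9, 9), 0)), "other")
  # boundary 0.2 is inside the unmethylated class
  expect_equal(classify_site(rep(2, 10), rep(8, 10)), "normally_unmethylated")
})

test_that("two-sided Fisher p matches full enumeration", {
  expect_equal(fisher_two_sided(0, 10, 0, 90), 1)
  expect_equal(fisher_two_sided(9, 1, 5, 95), orc_fisher(9, 1, 5, 95),
               tolerance = 1e-12)
  # label-swap symmetry
  expect_equal(fisher_two_sided(9, 1, 5, 95), fisher_two_sided(1, 9, 95, 5),
               tolerance = 1e-12)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1)
  set.seed(30)
  for (i in 1:100) {
    t <- rpois(4, sample(c(2, 10, 40), 1))
    p <- fisher_two_sided(t[1], t[2], t[3], t[4])
    expect_equal(p, orc_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    # and agrees with the standard implementation
    expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("site calls respect class, ratio boundary and alpha", {
  p_oracle <- orc_fisher(9, 1, 5, 95)
  cc <- call_site(9, 1, 5, 95, "normally_unmethylated")
  expect_equal(cc$direction, if (p_oracle <= 0.05) "hyper" else "none")
  expect_equal(cc$p_value, p_oracle, tolerance = 1e-12)

  # ratio exactly 0.2 is NOT above the boundary
  cc2 <- call_site(2, 8, 5, 95, "normally_unmethylated")
  expect_equal(cc2$direction, "none")
  # class 'other' is never called
  expect_equal(call_site(10, 0, 5, 95, "other")$direction, "none")
  # zero-coverage target is never called
  expect_equal(call_site(0, 0, 5, 95, "normally_unmethylated")$direction,
               "none")
  # hypo at a methylated site: ratio 0.8 is at the boundary (called if p ok)
  cc3 <- call_site(8, 2, 95, 5, "normally_methylated")
  expect_true(cc3$direction %in% c("hypo", "none"))
  expect_equal(call_site(9, 1, 95, 5, "normally_methylated")$direction,
               "none")  # ratio 0.9 > 0.8
})

test_that("direction never contradicts the site class", {
  set.seed(31)
  for (i in 1:200) {
    cls <- sample(c("normally_unmethylated", "normally_methylated"), 1)
    cc <- call_site(rpois(1, 10), rpois(1, 10), rpois(1, 50), rpois(1, 50),
                    cls)
    if (cls == "normally_unmethylated") expect_true(cc$direction != "hypo")
    else expect_true(cc$direction != "hyper")
  }
})

test_that("promoter windows follow strand and clip at zero", {
  gp <- toy_gene("P", "chr1", 9999, 12000, strand = "+")
  expect_equal(promoter_window(gp)[c("start", "end")],
               list(start = 7999, end = 9999))
  gm <- toy_gene("M", "chr1", 5000, 9999, strand = "-")
  # 1-based TSS 9999 (internal end0), window downstream in genome terms
  expect_equal(promoter_window(gm)[c("start", "end")],
               list(start = 9999, end = 11999))
  gclip <- toy_gene("C", "chr1", 499, 3000, strand = "+")
  expect_equal(promoter_window(gclip)$start, 0)
})

test_that("gene flagging applies the mean and count disjunction", {
  g <- toy_gene("X", "chr1", 9999, 12000, strand = "+")
  mkcalls <- function(p, n) data.frame(
    chrom = "chr1", pos = seq(8500, by = 10, length.out = n),
    haplotype = "1", class = "normally_unmethylated",
    direction = "hyper", p_value = p, target_ratio = 0.9,
    stringsAsFactors = FALSE)

  # mean of -log10 over {1e-6, 1e-5, 1e-4} is exactly 5 >= 4.5
  r <- score_genes(mkcalls(c(1e-6, 1e-5, 1e-4), 3), list(g))
  expect_true(r$flagged[r$haplotype == "1"])
  expect_equal(r$mean_neg_log10_p[r$haplotype == "1"], 5)
  # 10 weak sites flag by count despite mean ~1.3
  r2 <- score_genes(mkcalls(rep(0.05, 10), 10), list(g))
  expect_true(r2$flagged[r2$haplotype == "1"])
  expect_lt(r2$mean_neg_log10_p[r2$haplotype == "1"], 4.5)
  # one modest site does not flag
  r3 <- score_genes(mkcalls(0.04, 1), list(g))
  expect_false(any(r3$flagged))
  # the unaffected haplotype is never flagged
  expect_false(r$flagged[r$haplotype == "2"])
  # sites outside the promoter window do not count
  far <- mkcalls(1e-8, 3); far$pos <- far$pos + 100000
  expect_false(any(score_genes(far, list(g))$flagged))
})

test_that("end-to-end screen flags exactly the planted gene x haplotype", {
  cs <- c(chr1 = 150000)
  g <- make_genome(40, cs)
  ga <- make_gene_annotation(40, cs, n_genes = 6)
  md <- make_methylation_dataset(40, ga$genes, genome = g,
                                 epimutated_gene = "GENE003",
                                 epimutated_haplotype = "2")
  res <- detect_epimutations(md$target, md$controls, ga$genes)
  fl <- res$gene_report[res$gene_report$flagged, ]
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$gene, "GENE003")
  expect_equal(fl$haplotype, "2")
  # null dataset: nothing flagged
  md0 <- make_methylation_dataset(41, ga$genes, genome = g, epimutate = FALSE)
  res0 <- detect_epimutations(md0$target, md0$controls, ga$genes)
  expect_false(any(res0$gene_report$flagged))
})

test_that("raising methylated counts never unflags the planted gene", {
  cs <- c(chr1 = 120000)
  g <- make_genome(42, cs)
  ga <- make_gene_annotation(42, cs, n_genes = 4)
  md <- make_methylation_dataset(42, ga$genes, genome = g,
                                 epimutated_gene = "GENE002",
                                 epimutated_haplotype = "1")
  res1 <- detect_epimutations(md$target, md$controls, ga$genes)
  f1 <- res1$gene_report$flagged[res1$gene_report$gene == "GENE002" &
                                   res1$gene_report$haplotype == "1"]
  expect_true(f1)
  # push every target haplotype-1 site to fully methylated
  t2 <- md$target
  sel <- t2$haplotype == "1"
  t2$n_meth[sel] <- t2$n_meth[sel] + t2$n_unmeth[sel]
  t2$n_unmeth[sel] <- 0
  res2 <- detect_epimutations(t2, md$controls, ga$genes)
  f2 <- res2$gene_report$flagged[res2$gene_report$gene == "GENE002" &
                                   res2$gene_report$haplotype == "1"]
  expect_true(f2)
})
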