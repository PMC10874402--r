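#' Methylation ratio of a CpG site
#'
#' `n_meth / (n_meth + n_unmeth)`; `NA` when the site has no coverage
#' (a value, not an error).
#'
#' @param n_meth,n_unmeth Methylated / unmethylated base-call counts.
#' @return Numeric ratio in `[0, 1]`, or `NA` at zero coverage.
#' @export
methylation_ratio <- function(n_meth, n_unmeth) {
  tot <- n_meth + n_unmeth
  ifelse(tot > 0, n_meth / tot, NA_real_)
}

#' Classify a CpG site from the control panel
#'
#' A site is `normally_unmethylated` iff every control sample has
#' coverage of at least `min_cov` there and a methylation ratio in
#' `[0, 0.2]`; `normally_methylated` iff every control has coverage and
#' ratio in `[0.8, 1]`; otherwise `other`. The coverage rule prevents
#' zero-coverage controls from vacuously satisfying the ratio interval.
#'
#' @param n_meth,n_unmeth Per-control counts at one site (parallel
#'   vectors, one element per control sample, haplotypes pooled).
#' @param min_cov Minimum per-control coverage (default 5).
#' @param low,high Class interval bounds (defaults 0.2 / 0.8, closed).
#' @return One of `"normally_unmethylated"`, `"normally_methylated"`,
#'   `"other"`.
#' @export
classify_site <- function(n_meth, n_unmeth, min_cov = 5,
                          low = 0.2, high = 0.8) {
  if (length(n_meth) == 0L) return("other")
  cov <- n_meth + n_unmeth
  if (any(cov < min_cov)) return("other")
  r <- n_meth / cov
  if (all(r <= low)) "normally_unmethylated"
  else if (all(r >= high)) "normally_methylated"
  else "other"
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` by the
#' point-probability method: the sum of hypergeometric probabilities
#' (margins fixed) of every table whose probability does not exceed that
#' of the observed one. This is the convention used for the
#' allele-specific methylation calls; two-sided Fisher conventions
#' differ, so the definition is fixed here. An all-zero table returns 1.
#'
#' @param a,b,c,d Non-negative counts: target methylated/unmethylated
#'   (`a`, `b`) vs pooled-control methylated/unmethylated (`c`, `d`).
#' @return p-value in `[0, 1]`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  p <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  ## relative tolerance guards against ties lost to floating point
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Call one CpG site in the target sample against pooled controls
#'
#' At a `normally_unmethylated` site, hypermethylation is called iff the
#' target haplotype's methylation ratio is strictly above `low` and the
#' two-sided Fisher p-value (target counts vs controls pooled over all
#' samples) is at or below `alpha`. At a `normally_methylated` site,
#' hypomethylation requires ratio at or below `high` and p at or below
#' `alpha`. Sites classed `other`, or with zero target coverage, are
#' never called.
#'
#' @param target_meth,target_unmeth Target-haplotype counts at the site.
#' @param pooled_meth,pooled_unmeth Control counts pooled over samples.
#' @param cls Site class from [classify_site()].
#' @param alpha Significance cutoff (default 0.05, inclusive).
#' @param low,high Ratio boundaries (defaults 0.2 / 0.8; hyper requires
#'   ratio > `low`, hypo requires ratio <= `high`).
#' @return List with `direction` (`"hyper"`, `"hypo"`, `"none"`),
#'   `p_value` (NA when not tested) and `target_ratio`.
#' @export
call_site <- function(target_meth, target_unmeth, pooled_meth, pooled_unmeth,
                      cls, alpha = 0.05, low = 0.2, high = 0.8) {
  ratio <- methylation_ratio(target_meth, target_unmeth)
  none <- list(direction = "none", p_value = NA_real_, target_ratio = ratio)
  if (is.na(ratio) || cls == "other") return(none)
  if (cls == "normally_unmethylated") {
    if (ratio <= low) return(none)
    p <- fisher_two_sided(target_meth, target_unmeth, pooled_meth, pooled_unmeth)
    if (p <= alpha)
      return(list(direction = "hyper", p_value = p, target_ratio = ratio))
    return(list(direction = "none", p_value = p, target_ratio = ratio))
  }
  # normally_methylated
  if (ratio > high) return(none)
  p <- fisher_two_sided(target_meth, target_unmeth, pooled_meth, pooled_unmeth)
  if (p <= alpha)
    return(list(direction = "hypo", p_value = p, target_ratio = ratio))
  list(direction = "none", p_value = p, target_ratio = ratio)
}

#' Promoter window of a gene
#'
#' The `width` bp immediately upstream of the gene-level transcription
#' start site, strand-aware, clipped at position 0. For a 1-based TSS
#' `t` on the plus strand the window is internal `[t - 1 - width,
#' t - 1)`; on the minus strand `[t, t + width)`.
#'
#' @param g A `gene_model`.
#' @param width Window size in bp (default 2000).
#' @return List `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(g, width = 2000) {
  tss1 <- gene_tss(g)
  if (g$strand == "-") {
    start <- tss1; end <- tss1 + width
  } else {
    start <- max(0, tss1 - 1 - width); end <- tss1 - 1
  }
  list(chrom = g$chrom, start = start, end = end)
}

#' Read a haplotype-resolved methylation frequency table
#'
#' TSV with header columns `chrom`, `pos` (1-based CpG position),
#' `haplotype` (1, 2 or `unassigned`), `n_meth`, `n_unmeth` -- the shape
#' of a per-haplotype split of an f5c-style meth-freq output.
#'
#' @param path TSV file.
#' @return data.frame of CpG counts.
#' @export
read_methfreq <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         haplotype = "character"))
  need <- c("chrom", "pos", "haplotype", "n_meth", "n_unmeth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("methylation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$n_meth < 0 | df$n_unmeth < 0)) stop("negative counts")
  df
}

#' Site-level allele-specific methylation calls for one target sample
#'
#' Classifies every site covered by the control panel (haplotypes pooled
#' within each control), then tests each target haplotype's counts at the
#' classed sites against the controls pooled over all samples. Reads
#' with unassigned haplotype are excluded from the haplotype calls.
#'
#' @param target CpG count table for the target sample (see
#'   [read_methfreq()]).
#' @param controls List of CpG count tables, one per control sample.
#' @param min_cov Per-control coverage floor for class assignment
#'   (default 5).
#' @param alpha Fisher significance cutoff (default 0.05).
#' @return data.frame of calls: `chrom`, `pos`, `haplotype`, `class`,
#'   `direction`, `p_value`, `target_ratio`.
#' @export
call_asm_sites <- function(target, controls, min_cov = 5, alpha = 0.05) {
  key <- function(df) paste(df$chrom, df$pos, sep = ":")
  ## per-control pooled counts per site
  ctl <- lapply(seq_along(controls), function(i) {
    d <- controls[[i]]
    agg <- stats::aggregate(cbind(n_meth, n_unmeth) ~ chrom + pos, d, sum)
    agg$sample <- i
    agg
  })
  ctl_all <- do.call(rbind, ctl)
  ctl_key <- paste(ctl_all$chrom, ctl_all$pos, sep = ":")
  ## keep sites seen in every control
  tab <- table(ctl_key)
  full <- names(tab)[tab == length(controls)]
  sel <- ctl_key %in% full
  ctl_all <- ctl_all[sel, , drop = FALSE]
  ctl_key <- ctl_key[sel]

  cls_by_site <- vapply(split(seq_len(nrow(ctl_all)), ctl_key), function(ix) {
    classify_site(ctl_all$n_meth[ix], ctl_all$n_unmeth[ix], min_cov = min_cov)
  }, "")
  pooled_meth <- vapply(split(ctl_all$n_meth, ctl_key), sum, 0)
  pooled_unmeth <- vapply(split(ctl_all$n_unmeth, ctl_key), sum, 0)

  tgt <- target[target$haplotype %in% c("1", "2"), , drop = FALSE]
  tkey <- key(tgt)
  idx <- match(tkey, names(cls_by_site))
  out <- data.frame(chrom = tgt$chrom, pos = tgt$pos,
                    haplotype = tgt$haplotype,
                    class = ifelse(is.na(idx), "other", cls_by_site[idx]),
                    direction = "none", p_value = NA_real_,
                    target_ratio = methylation_ratio(tgt$n_meth, tgt$n_unmeth),
                    stringsAsFactors = FALSE)
  testable <- which(out$class != "other")
  for (i in testable) {
    cc <- call_site(tgt$n_meth[i], tgt$n_unmeth[i],
                    pooled_meth[[idx[i]]], pooled_unmeth[[idx[i]]],
                    cls = out$class[i], alpha = alpha)
    out$direction[i] <- cc$direction
    out$p_value[i] <- cc$p_value
  }
  out
}

#' Flag genes with promoter epimutations
#'
#' For every gene x haplotype, collects the aberrant site calls (hyper
#' or hypo) falling in the gene's promoter window and flags the pair
#' when either the mean -log10(p) over those calls reaches
#' `mean_threshold` or their count reaches `count_threshold`. A gene
#' with no aberrant promoter sites is never flagged. No site-level
#' multiplicity correction is applied; the gene-level thresholds are the
#' stringency mechanism.
#'
#' @param calls Site calls from [call_asm_sites()].
#' @param genes List of `gene_model`s.
#' @param mean_threshold Mean -log10(p) cutoff (default 4.5).
#' @param count_threshold Aberrant-site count cutoff (default 10).
#' @param promoter_width Promoter window in bp (default 2000).
#' @return data.frame: `gene`, `haplotype`, `n_aberrant`,
#'   `mean_neg_log10_p`, `flagged`.
#' @export
score_genes <- function(calls, genes, mean_threshold = 4.5,
                        count_threshold = 10, promoter_width = 2000) {
  rows <- list()
  for (g in genes) {
    win <- promoter_window(g, width = promoter_width)
    for (hap in c("1", "2")) {
      sel <- calls$haplotype == hap & calls$chrom == win$chrom &
        calls$pos - 1 >= win$start & calls$pos - 1 < win$end &
        calls$direction != "none"
      n_ab <- sum(sel)
      mlp <- if (n_ab > 0) mean(-log10(calls$p_value[sel])) else NA_real_
      flagged <- n_ab > 0 &&
        (mlp >= mean_threshold || n_ab >= count_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$symbol, haplotype = hap, n_aberrant = n_ab,
        mean_neg_log10_p = mlp, flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' End-to-end epimutation screen
#'
#' [call_asm_sites()] followed by [score_genes()].
#'
#' @inheritParams call_asm_sites
#' @inheritParams score_genes
#' @return List with `site_calls` and `gene_report`.
#' @export
detect_epimutations <- function(target, controls, genes, min_cov = 5,
                                alpha = 0.05, mean_threshold = 4.5,
                                count_threshold = 10, promoter_width = 2000) {
  calls <- call_asm_sites(target, controls, min_cov = min_cov, alpha = alpha)
  report <- score_genes(calls, genes, mean_threshold = mean_threshold,
                        count_threshold = count_threshold,
                        promoter_width = promoter_width)
  list(site_calls = calls, gene_report = report)
}
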