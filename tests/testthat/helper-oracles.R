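# Brute-force oracles, independent of the package's interval/statistics code.

# per-base boolean coverage array for one chromosome (0-based half-open input)
orc_base_mask <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  mask
}

# per-base union size of a region_set (chromosomes bounded by len)
orc_union_bp <- function(rs, len) {
  total <- 0
  for (chr in unique(rs$chrom)) {
    sel <- rs$chrom == chr
    total <- total + sum(orc_base_mask(rs$start[sel], rs$end[sel], len))
  }
  total
}

# does [qs, qe) intersect rs expanded by margin? per-base check
orc_overlaps <- function(qchrom, qs, qe, rs, margin, len) {
  sel <- rs$chrom == qchrom
  if (!any(sel)) return(FALSE)
  mask <- orc_base_mask(pmax(0, rs$start[sel] - margin),
                        pmin(len, rs$end[sel] + margin), len)
  qe <- min(qe, len)
  qs >= len || qe <= qs || any(mask[(qs + 1):qe])
}

# per-base pileup mean depth of alignments over regions
orc_mean_depth <- function(alns, rs, len) {
  cov_bp <- 0; reg_bp <- 0
  for (chr in unique(c(alns$chrom, rs$chrom))) {
    depth <- integer(len)
    a <- alns[alns$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      s <- a$start[i] + 1; e <- min(a$end[i], len)
      if (e >= s) depth[s:e] <- depth[s:e] + 1L
    }
    sel <- rs$chrom == chr
    mask <- orc_base_mask(rs$start[sel], pmin(rs$end[sel], len), len)
    cov_bp <- cov_bp + sum(depth[mask])
    reg_bp <- reg_bp + sum(mask)
  }
  cov_bp / reg_bp
}

# N50 by explicit threshold scan
orc_n50 <- function(lengths) {
  tot <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  min(lengths)
}

# two-sided Fisher p by full enumeration with log-factorials
orc_fisher <- function(a, b, c, d) {
  lp_table <- function(x) {
    # P(table with top-left x | margins) via hypergeometric identity
    m <- a + b; n <- c + d; k <- a + c
    lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
      lfactorial(n) - lfactorial(k - x) - lfactorial(n - k + x) -
      (lfactorial(m + n) - lfactorial(k) - lfactorial(m + n - k))
  }
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  lp <- vapply(xs, lp_table, 0)
  p_obs <- exp(lp_table(a))
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}
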