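## Desk-scale local alignment: exact k-mer seeding on one strand with
## per-base extension. Intended for segmenting mobile-element insertions
## (a few kb) against consensus libraries and small reference genomes,
## where planted copies are exact or near-exact; not a general aligner.

## all maximal exact local matches >= k between query and subject,
## 0-based half-open coordinates in both. Returns a data.frame
## (q_start, q_end, s_start, s_end, n_match, identity).
local_align_hits <- function(query, subject, k = 15, max_kmer_hits = 100) {
  nq <- nchar(query); ns <- nchar(subject)
  empty <- data.frame(q_start = numeric(0), q_end = numeric(0),
                      s_start = numeric(0), s_end = numeric(0),
                      n_match = numeric(0), identity = numeric(0))
  if (nq < k || ns < k) return(empty)
  s_starts <- seq_len(ns - k + 1)
  s_kmers <- substring(subject, s_starts, s_starts + k - 1)
  idx <- split(s_starts, s_kmers)
  nhit <- lengths(idx)
  idx <- idx[nhit <= max_kmer_hits]  # skip hyper-repetitive seeds
  q_starts <- seq_len(nq - k + 1)
  q_kmers <- substring(query, q_starts, q_starts + k - 1)
  hit_list <- idx[q_kmers]
  nh <- lengths(hit_list)
  if (sum(nh) == 0L) return(empty)
  q <- rep(q_starts, nh) - 1          # 0-based
  s <- unlist(hit_list, use.names = FALSE) - 1
  diag <- s - q
  ord <- order(diag, q)
  q <- q[ord]; s <- s[ord]; diag <- diag[ord]
  new_run <- c(TRUE, diff(diag) != 0 | diff(q) > k)
  run_id <- cumsum(new_run)
  qs <- tapply(q, run_id, min)
  qe <- tapply(q, run_id, max) + k    # half-open
  dg <- tapply(diag, run_id, `[`, 1L)

  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1L]]
  out_qs <- numeric(length(qs)); out_qe <- numeric(length(qs))
  for (i in seq_along(qs)) {
    a <- qs[[i]]; b <- qe[[i]]; d <- dg[[i]]
    while (a > 0 && a + d > 0 && qc[a] == sc[a + d]) a <- a - 1
    while (b < nq && b + d < ns && qc[b + 1] == sc[b + d + 1]) b <- b + 1
    out_qs[i] <- a; out_qe[i] <- b
  }
  df <- data.frame(q_start = out_qs, q_end = out_qe,
                   s_start = out_qs + unlist(dg), s_end = out_qe + unlist(dg))
  ## extension can merge runs into duplicates
  df <- unique(df)
  df$n_match <- df$q_end - df$q_start
  df$identity <- 100
  df[order(-df$n_match), , drop = FALSE]
}

## greedy maximal-score selection of query-disjoint hits; a chance
## extension of one copy into the next can overlap a few bases, so small
## overlaps are trimmed off the lower-scoring hit instead of rejecting it
select_disjoint_hits <- function(hits, max_trim = 20) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(-hits$n_match), , drop = FALSE]
  acc <- hits[0L, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    ok <- TRUE
    for (j in seq_len(nrow(acc))) {
      ol <- min(h$q_end, acc$q_end[j]) - max(h$q_start, acc$q_start[j])
      if (ol <= 0) next
      if (ol > max_trim) { ok <- FALSE; break }
      if (h$q_start >= acc$q_start[j]) {        # trim candidate's left edge
        h$s_start <- h$s_start + (acc$q_end[j] - h$q_start)
        h$q_start <- acc$q_end[j]
      } else {                                  # trim candidate's right edge
        h$s_end <- h$s_end - (h$q_end - acc$q_start[j])
        h$q_end <- acc$q_start[j]
      }
      if (h$q_end - h$q_start <= 0) { ok <- FALSE; break }
    }
    if (ok) {
      h$n_match <- h$q_end - h$q_start
      acc <- rbind(acc, h)
    }
  }
  acc
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
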