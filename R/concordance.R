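#' Read genotype records from a VCF
#'
#' Extracts one biallelic record per row with the alt-allele dosage of
#' the first sample. Multi-allelic records must be split upstream
#' (`bcftools norm -m -any` style); unsplit records are rejected with an
#' error. Minor allele frequency is taken from the panel annotation:
#' either the INFO field named by `af_info` or a side TSV
#' (`chrom`, `pos`, `ref`, `alt`, `af`, with header) via `af_table`.
#' Panel AF above 0.5 is folded to the minor allele (`maf = min(af,
#' 1 - af)`).
#'
#' @param path VCF file.
#' @param af_info INFO key holding the panel allele frequency (default
#'   `"AF"`); ignored when `af_table` is given.
#' @param af_table Optional path to a side table of allele frequencies.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `gt` (dosage 0/1/2,
#'   NA if missing), `maf`, `depth` (FORMAT DP, NA if absent), `gq`
#'   (FORMAT GQ, NA if absent).
#' @export
read_genotypes <- function(path, af_info = "AF", af_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  alt <- fx[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic record found: split sites into biallelic records first")
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1L]
  dosage <- vapply(strsplit(gt_raw, "[/|]"), function(x) {
    x <- suppressWarnings(as.integer(x))
    if (any(is.na(x))) NA_integer_ else sum(x > 0L)
  }, 0L)
  num_fmt <- function(el) {
    x <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE)[, 1L],
                  error = function(e) rep(NA_real_, nrow(fx)))
    if (is.null(x)) rep(NA_real_, nrow(fx)) else as.numeric(x)
  }
  df <- data.frame(chrom = fx[, "CHROM"], pos = as.numeric(fx[, "POS"]),
                   ref = fx[, "REF"], alt = alt, gt = dosage,
                   depth = num_fmt("DP"), gq = num_fmt("GQ"),
                   stringsAsFactors = FALSE)
  if (!is.null(af_table)) {
    at <- utils::read.table(af_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
    m <- match(paste(df$chrom, df$pos, df$ref, df$alt),
               paste(at$chrom, at$pos, at$ref, at$alt))
    af <- at$af[m]
  } else {
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = af_info)))
  }
  df$maf <- pmin(af, 1 - af)
  df
}

#' Partition genotype records into minor-allele-frequency bins
#'
#' Half-open bins `[e_i, e_{i+1})` over the supplied edges, with the
#' last bin closed at its upper edge (MAF 0.5 falls in the last bin).
#' Records with MAF outside `[first edge, last edge]` (or missing) are
#' rejected and counted.
#'
#' @param records data.frame with a `maf` column.
#' @param edges Strictly increasing bin edges. The default is the
#'   standard imputation-accuracy binning: 0, 0.001, 0.002, 0.005, 0.01,
#'   0.05, 0.1, 0.2, 0.5.
#' @return List: `records` (with added `bin` factor,
#'   rejected rows removed), `n_rejected`, `bin_labels`.
#' @export
bin_by_maf <- function(records,
                       edges = c(0, 0.001, 0.002, 0.005, 0.010,
                                 0.050, 0.100, 0.200, 0.500)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  labels <- paste0("[", utils::head(edges, -1), ",", utils::tail(edges, -1),
                   c(rep(")", length(edges) - 2L), "]"))
  maf <- records$maf
  ok <- !is.na(maf) & maf >= edges[1L] & maf <= edges[length(edges)]
  idx <- findInterval(maf[ok], edges, rightmost.closed = TRUE)
  rec <- records[ok, , drop = FALSE]
  rec$bin <- factor(labels[idx], levels = labels)
  list(records = rec, n_rejected = sum(!ok), bin_labels = labels)
}

#' MAF-binned genotype concordance between two call sets
#'
#' Matches records on (chrom, pos, ref, alt), filters the truth side to
#' confidently-called sites (depth and genotype-quality-derived
#' probability floors), then reports per MAF bin the number of compared
#' sites, the genotype concordance (% identical dosage) and the
#' non-reference concordance (% identical among sites where either call
#' is non-reference). Bins with no comparable sites report `NA`, not 0.
#'
#' @param truth,test Genotype tables (see [read_genotypes()]); `maf` is
#'   taken from the truth side.
#' @param min_depth Minimum truth depth (default 8; sites with missing
#'   depth pass when `min_depth` is 0).
#' @param min_gq_prob Minimum truth call probability (default 0.9999);
#'   compared against `1 - 10^(-GQ/10)` when GQ is present.
#' @param edges MAF bin edges (see [bin_by_maf()]).
#' @return data.frame: `bin`, `n_sites`, `concordance_pct`,
#'   `nonref_concordance_pct`; plus attribute `overall_pct`.
#' @export
genotype_concordance <- function(truth, test, min_depth = 8,
                                 min_gq_prob = 0.9999,
                                 edges = c(0, 0.001, 0.002, 0.005, 0.010,
                                           0.050, 0.100, 0.200, 0.500)) {
  keep <- rep(TRUE, nrow(truth))
  if (min_depth > 0)
    keep <- keep & !is.na(truth$depth) & truth$depth >= min_depth
  if (min_gq_prob > 0 && any(!is.na(truth$gq))) {
    prob <- 1 - 10^(-truth$gq / 10)
    keep <- keep & !is.na(truth$gq) & prob >= min_gq_prob
  }
  truth <- truth[keep, , drop = FALSE]
  kt <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  ks <- paste(test$chrom, test$pos, test$ref, test$alt)
  m <- match(kt, ks)
  ok <- !is.na(m) & !is.na(truth$gt) & !is.na(test$gt[m])
  cmp <- data.frame(maf = truth$maf[ok], gt_truth = truth$gt[ok],
                    gt_test = test$gt[m][ok])
  binned <- bin_by_maf(cmp, edges = edges)
  rec <- binned$records
  per_bin <- lapply(binned$bin_labels, function(lb) {
    r <- rec[rec$bin == lb, , drop = FALSE]
    n <- nrow(r)
    conc <- if (n > 0) 100 * mean(r$gt_truth == r$gt_test) else NA_real_
    nonref <- r$gt_truth > 0 | r$gt_test > 0
    nr <- if (any(nonref)) 100 * mean(r$gt_truth[nonref] == r$gt_test[nonref])
          else NA_real_
    data.frame(bin = lb, n_sites = n, concordance_pct = conc,
               nonref_concordance_pct = nr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_bin)
  attr(out, "overall_pct") <-
    if (nrow(rec) > 0) 100 * mean(rec$gt_truth == rec$gt_test) else NA_real_
  attr(out, "n_rejected_maf") <- binned$n_rejected
  out
}
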