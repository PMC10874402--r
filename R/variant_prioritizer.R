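#' Read an annotated germline VCF into a variant table
#'
#' Consumes a VCF whose INFO field carries the annotations the
#' prioritization rules use: population allele frequencies, ClinVar
#' clinical significance, LOFTEE confidence, SpliceAI delta scores and
#' consequence terms. The INFO keys are configurable; the defaults match
#' a VEP-style custom annotation.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param info_map Named list mapping logical fields to INFO keys.
#'   Defaults: `gnomad = "gnomAD_AF"`, `tommo = "TOMMO_AF"`,
#'   `clinvar = "CLNSIG"`, `loftee = "LoF"`, `consequence = "CSQ"`,
#'   `spliceai = c("SpliceAI_DS_AG", "SpliceAI_DS_AL", "SpliceAI_DS_DG",
#'   "SpliceAI_DS_DL")`.
#' @return data.frame with one row per record: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `quality`, `af_gnomad`, `af_tommo`, `clinvar_sig`,
#'   `loftee`, `consequences` (comma-joined), `spliceai_max`.
#' @export
read_annotated_vcf <- function(path, info_map = list()) {
  im <- utils::modifyList(list(
    gnomad = "gnomAD_AF", tommo = "TOMMO_AF", clinvar = "CLNSIG",
    loftee = "LoF", consequence = "CSQ",
    spliceai = c("SpliceAI_DS_AG", "SpliceAI_DS_AL",
                 "SpliceAI_DS_DG", "SpliceAI_DS_DL")), info_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  info_num <- function(key) suppressWarnings(as.numeric(
    vcfR::extract.info(v, element = key)))
  info_chr <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fx)) else as.character(x)
  }
  ds <- vapply(im$spliceai, info_num, numeric(nrow(fx)))
  if (is.null(dim(ds))) ds <- matrix(ds, nrow = 1)
  spliceai_max <- apply(ds, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(
    chrom = fx[, "CHROM"],
    pos = as.numeric(fx[, "POS"]),
    ref = fx[, "REF"],
    alt = fx[, "ALT"],
    quality = suppressWarnings(as.numeric(fx[, "QUAL"])),
    af_gnomad = info_num(im$gnomad),
    af_tommo = info_num(im$tommo),
    clinvar_sig = info_chr(im$clinvar),
    loftee = info_chr(im$loftee),
    consequences = info_chr(im$consequence),
    spliceai_max = spliceai_max,
    stringsAsFactors = FALSE)
}

#' Variant caller-quality filter
#'
#' Keeps variants with quality strictly greater than `min_q` (records at
#' or below the threshold are discarded, i.e. quality 10 is dropped at
#' the default).
#'
#' @param variants Variant table (see [read_annotated_vcf()]).
#' @param min_q Quality cutoff (default 10).
#' @param missing_quality What to do with records lacking a quality value:
#'   `"drop"` (default, with a warning) or `"keep"`.
#' @return Logical keep vector.
#' @export
quality_filter <- function(variants, min_q = 10,
                           missing_quality = c("drop", "keep")) {
  missing_quality <- match.arg(missing_quality)
  q <- variants$quality
  keep <- !is.na(q) & q > min_q
  if (any(is.na(q))) {
    if (missing_quality == "keep") keep[is.na(q)] <- TRUE
    else warning(sum(is.na(q)), " variant(s) without quality dropped")
  }
  keep
}

#' Analysis-region filter
#'
#' A variant is in the analysis region iff its position lies within the
#' gene maximal-span set and in neither the simple-repeat nor the
#' segmental-duplication mask (no margin: these are the SNV/indel region
#' rules, distinct from the sequencing target design).
#'
#' @param variants Variant table.
#' @param gene_spans,simple_repeats,segdups `region_set`s.
#' @return Logical keep vector.
#' @export
in_analysis_region <- function(variants, gene_spans, simple_repeats, segdups) {
  inside <- position_in_regions(variants$chrom, variants$pos, gene_spans)
  in_rep <- position_in_regions(variants$chrom, variants$pos, simple_repeats)
  in_sd <- position_in_regions(variants$chrom, variants$pos, segdups)
  inside & !in_rep & !in_sd
}

#' Common-variant filter
#'
#' A variant is common iff any configured population source reports an
#' allele frequency at or above the threshold (inclusive: AF = 0.01 is
#' common at the default). Absent frequencies are treated as 0.
#'
#' @param variants Variant table.
#' @param threshold Allele-frequency cutoff (default 0.01).
#' @param sources Which AF columns to consult (default both gnomad and
#'   tommo, OR semantics). Use a single source for AND-style restriction
#'   by intersecting calls yourself.
#' @return Logical vector: TRUE where the variant is common (to be
#'   removed).
#' @export
is_common_variant <- function(variants, threshold = 0.01,
                              sources = c("gnomad", "tommo")) {
  afs <- lapply(sources, function(s) {
    x <- variants[[paste0("af_", s)]]
    if (is.null(x)) rep(0, nrow(variants)) else ifelse(is.na(x), 0, x)
  })
  Reduce(`|`, lapply(afs, function(a) a >= threshold))
}

#' Pathogenicity classification of filtered variants
#'
#' Assigns each variant a subset of three labels:
#' \describe{
#'   \item{known_pathogenic}{ClinVar significance "Pathogenic" or
#'     "Likely pathogenic" (case-insensitive; slash/comma-combined forms
#'     such as "Pathogenic/Likely_pathogenic" accepted).}
#'   \item{splicing}{Essential GT-AG splice-site consequence
#'     (`splice_acceptor_variant`/`splice_donor_variant`) or SpliceAI
#'     max delta score >= 0.50.}
#'   \item{lof}{LOFTEE high-confidence ("HC") loss-of-function.}
#' }
#' Apply [quality_filter()], [in_analysis_region()] and
#' [is_common_variant()] first; [prioritize_variants()] runs the full
#' chain.
#'
#' @param variants Variant table.
#' @param spliceai_threshold SpliceAI delta-score cutoff (default 0.50,
#'   inclusive).
#' @return data.frame of `variants` with added logical columns
#'   `known_pathogenic`, `lof`, `splicing` and `n_labels`.
#' @export
classify_variants <- function(variants, spliceai_threshold = 0.50) {
  sig <- tolower(ifelse(is.na(variants$clinvar_sig), "", variants$clinvar_sig))
  sig <- gsub("_", " ", sig)
  sig_parts <- strsplit(sig, "[/|,]")
  known <- vapply(sig_parts, function(p)
    any(trimws(p) %in% c("pathogenic", "likely pathogenic")), FALSE)
  csq <- ifelse(is.na(variants$consequences), "", variants$consequences)
  essential <- grepl("splice_acceptor_variant|splice_donor_variant", csq)
  ds <- ifelse(is.na(variants$spliceai_max), -Inf, variants$spliceai_max)
  splicing <- essential | ds >= spliceai_threshold
  lof <- !is.na(variants$loftee) & toupper(variants$loftee) == "HC"
  out <- variants
  out$known_pathogenic <- known
  out$lof <- lof
  out$splicing <- splicing
  out$n_labels <- known + lof + splicing
  out
}

#' Summarize pathogenicity calls
#'
#' Per-label counts, the number of multi-label variants, and the distinct
#' putative-pathogenic total (set union over labels, obeying
#' inclusion-exclusion).
#'
#' @param calls Output of [classify_variants()].
#' @return List with `n_known_pathogenic`, `n_lof`, `n_splicing`,
#'   `n_multi_label`, `n_distinct`.
#' @export
summarize_calls <- function(calls) {
  if (nrow(calls) == 0L)
    return(list(n_known_pathogenic = 0L, n_lof = 0L, n_splicing = 0L,
                n_multi_label = 0L, n_distinct = 0L))
  any_label <- calls$known_pathogenic | calls$lof | calls$splicing
  list(
    n_known_pathogenic = sum(calls$known_pathogenic),
    n_lof = sum(calls$lof),
    n_splicing = sum(calls$splicing),
    n_multi_label = sum(calls$n_labels >= 2L),
    n_distinct = sum(any_label))
}

#' Full SNV/indel prioritization pipeline
#'
#' Quality filter (> `min_q`), analysis-region restriction, common-variant
#' removal (AF >= `af_threshold` in any source), then pathogenicity
#' classification of the survivors.
#'
#' @inheritParams quality_filter
#' @inheritParams in_analysis_region
#' @inheritParams is_common_variant
#' @inheritParams classify_variants
#' @return List with `calls` (classified survivors carrying at least one
#'   label), `kept` (all survivors), and `summary`
#'   (see [summarize_calls()]).
#' @export
prioritize_variants <- function(variants, gene_spans, simple_repeats, segdups,
                                min_q = 10, af_threshold = 0.01,
                                spliceai_threshold = 0.50) {
  keep <- quality_filter(variants, min_q = min_q) &
    in_analysis_region(variants, gene_spans, simple_repeats, segdups) &
    !is_common_variant(variants, threshold = af_threshold)
  kept <- variants[keep, , drop = FALSE]
  cls <- classify_variants(kept, spliceai_threshold = spliceai_threshold)
  calls <- cls[cls$n_labels > 0L, , drop = FALSE]
  list(calls = calls, kept = kept, summary = summarize_calls(cls))
}
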