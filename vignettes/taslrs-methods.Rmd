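---
title: "Methods: downstream interpretation of targeted adaptive-sampling long-read sequencing"
author: "taslrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream interpretation of TAS-LRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taslrs)
```

This vignette documents the models, rules and numerical choices behind each
stage of the package, in the spirit of a methods supplement: what is
computed, under which assumptions, which parameters matter, and what the
synthetic-fixture tests do and do not demonstrate.

## Coordinates

Every user-facing interval in the package is **0-based half-open** (the BED
convention); VCF/GTF positions and printed 1-based inclusive coordinates are
converted at the I/O boundary only (`printed_to_internal()` /
`internal_to_printed()`), so interval length is always `end - start`. A
single convention removes the classic off-by-one failure class. Interval
algebra itself (merging, overlap queries, complements) is delegated to
IRanges/GenomicRanges, with the conversion confined to two internal helpers;
the test suite checks merging, overlap and depth against brute-force
per-base oracles rather than trusting either layer.

Chromosome names are compared as exact strings (`"chr6"` is not `"6"`).
Silent aliasing between naming schemes causes subtler bugs than an explicit
failure, so no rename heuristic is applied.

## Target design

The adaptive-sampling target list is built per gene from the maximal extent
over all annotated transcripts, expanded symmetrically by a margin (default
**10 kbp**, the practical flank that gives the pore's eject decision room on
both sides), clipped at chromosome bounds, unioned with manual extension
regions and merged. Manual extensions exist because gene annotation releases
can miss clinically relevant first exons; the extension BED generalizes
that fix. Whether overlapping genes are merged before or after margin
expansion does not change the final merged output, so the simpler
order (expand, then merge once) is used. Total size is monotone in the
margin, and margin 0 returns exactly the merged gene spans — both are
property-tested.

## Sequencing QC

Reads are classified on-target if the primary alignment's reference span
overlaps the target set by at least one base. Depth counts each primary
alignment's reference footprint once; secondary/supplementary alignments
are excluded to avoid double-counting split reads. Off-target space is the
genome complement of the targets over a supplied chromosome-sizes table.
Enrichment is mean on-target depth over mean off-target depth; a sample
with zero off-target coverage reports `Inf` with a warning rather than
failing. N50 is the largest length L such that reads of length at least L
contain half of all bases; it is computed over **full read lengths** by
default, with `n50_on = "aligned_length"` as a switch, because read-level
N50 is the common instrument-QC convention and the aligned variant is
sensitive to clipping.

## SNV/indel prioritization

The filter chain is a conjunction of pure predicates, so its order cannot
change the surviving set (tested):

1. **Quality**: keep QUAL strictly greater than 10 (records at the
   threshold are removed). Records without a quality value are dropped with
   a warning by default (`missing_quality = "keep"` to override).
2. **Region**: position inside the gene maximal-span set and in neither the
   simple-repeat nor segmental-duplication mask, margin 0. Note this is a
   different region set from the sequencing target BED: no 10 kb margin.
3. **Frequency**: common iff any configured source reports allele frequency
   at or above 0.01 (inclusive). Absent annotations count as frequency 0.
   With several population sources the semantics are OR (removal if common
   in either panel); restrict `sources` to change this.

Survivors are labelled by three rules: ClinVar significance
Pathogenic/Likely pathogenic (case-insensitive, slash- or comma-combined
values accepted; review stars are reported but never filtered on), LOFTEE
high-confidence (`HC`) loss of function, and splicing — an essential GT–AG
splice-site consequence term or SpliceAI delta at or above 0.50. The
SpliceAI "delta score" is taken as the maximum of the four published delta
scores (acceptor/donor gain/loss), the standard headline score. Splicing
database memberships (SAVNet/IRAVDB-style) are carried as informational
tags only. Essential splice sites are detected from consequence terms, not
re-derived from sequence, since the rule is annotation-driven. The distinct
prioritized-variant count obeys inclusion–exclusion over labels; variants
can carry several labels.

## SV post-filtering

The false-positive elimination filter drops a junction when (a) a breakend
lies on a non-primary contig, (b) no breakend lies in the targets, or
(c) a deletion/insertion/tandem-duplication is **contained** in one
simple-repeat interval expanded by 10 bp. Containment — both breakends (or
the single insertion point) inside one expanded interval — rather than mere
overlap is deliberate: large, real deletions frequently touch a repeat at
one end, and an overlap rule would discard them. For insertions the margin
applies to the single insertion point.

Putative pathogenic classification of the survivors, against the target
gene panel: deletions whose span intersects any CDS interval; duplications
with at least one breakend inside a gene excluding UTRs whose span covers
at least one complete CDS interval (the minimal reading of "amplifies the
coding sequence" that is decidable from breakpoints alone); inversions and
translocations with a breakend in a gene excluding UTRs; and single
breakends inside a gene span. Single breakends use the full span because
partially resolved junctions in introns are exactly the calls worth
reviewing; `sbe_exclude_utr = TRUE` restricts them like the other rules.
A position that is CDS in one transcript but UTR in another counts as UTR
(exclusion wins); the classification is conservative in that direction.
Matched-control/panel-of-normals subtraction belongs to the caller and is
out of scope here.

## Mobile-element insertion annotation

The annotator automates the curator's decomposition of a retrotransposition
event, in this order:

1. **TSD**: the longest sequence (5–50 bp, at most 1 mismatch) that is both
   a suffix of `left_flank + inserted_seq` and a prefix of `right_flank`,
   ties broken long. This is caller-agnostic: callers differ in whether the
   duplicated copy is reported inside the inserted sequence or left in the
   flank. If the insertion's terminal bases duplicate the TSD they are
   trimmed before further analysis.
2. **Strand**: the orientation with the better total library alignment
   score wins; a minus-strand event's 5′ poly-T becomes a 3′ poly-A after
   normalization.
3. **Poly-A**: the maximal 3′-terminal window with non-A fraction at most
   0.1, then trimmed so the reported tail starts on an A; tails under 10 bp
   report 0.
4. **Segmentation**: maximal-scoring query-disjoint local alignments
   against the consensus library, greedy by score, with small overlaps
   (chance extension of one copy into the next) trimmed from the
   lower-scoring hit; gaps are labelled `unclassified`. Defaults
   `min_identity = 80`, `min_seg = 100 bp` separate SVA subfamilies on
   synthetic consensus libraries; both are exposed.
5. **Source and transduction**: the insertion minus its tail is aligned to
   the reference (both strands); the best locus is the source, and the
   3′-terminal aligned stretch outside the repeat mask but contiguous
   (within 1 kb) with the masked element is the 3′ transduction. The
   polyadenylation signal search is the exact motif AATAAA within the
   transduction; variant signals are out of scope.
6. **Hexamer head**: at least 2 tandem (CCCTCT) copies starting within the
   first 100 bp of the element marks a retrotransposition-competent 5′ end;
   its absence sets the truncation flag.

Alignment is an internal exact k-mer (k = 15) seed-and-extend with
per-base extension — adequate for desk-scale sequences where planted copies
are exact or near-exact, and dependency-free. It is not a general-purpose
aligner: diverged elements (identity well below the high 90s) would need an
external local aligner, which can be substituted upstream of
`segment_against_library()`.

Segments always tile the analyzed sequence, so lengths conserve:
poly-A + transduction + repeat segments + unclassified = insertion length
(after TSD trimming). This is asserted on every annotated event.

## Allele-specific methylation

Per-CpG methylation ratio is methylated calls over total calls; zero
coverage is "undefined", a value, never an error. Site classes come from
the control panel (default 10 samples, haplotypes pooled within each
control): normally unmethylated iff **every** control has the ratio in
[0, 0.2], normally methylated iff every control is in [0.8, 1] — both
intervals closed — and additionally every control must have coverage of at
least `min_cov = 5` at the site. The coverage rule is needed because a
zero-coverage control would satisfy any ratio interval vacuously.

Target calls per haplotype: hypermethylation at a normally unmethylated
site requires ratio strictly above 0.2 **and** two-sided Fisher p at or
below 0.05 against the controls pooled over all samples and both
haplotypes (a switch for haplotype-matched pooling exists);
hypomethylation mirrors this at normally methylated sites with ratio at or
below 0.8. The two-sided Fisher p-value uses the **point-probability
method** — the sum of hypergeometric probabilities of all tables, margins
fixed, no more likely than the observed one (with a 1e-7 relative
tolerance for floating-point ties); two-sided Fisher conventions differ,
so the definition is fixed and tested against full enumeration to 1e-12.
An all-zero table has p = 1 by convention.

Gene-level flagging counts aberrant CpGs in the 2000 bp window upstream of
the gene's outermost TSS (strand-aware, clipped at zero) per haplotype and
flags when mean −log10(p) ≥ 4.5 or the count reaches 10. No site-level
multiple-testing correction is applied; the two gene-level thresholds are
the stringency mechanism. Reads with unassigned haplotype are excluded
from haplotype calls. The module scores whatever genes it is given;
restricting to a panel is done by supplying that panel's annotation.

## Genotype concordance

Records are matched on (chrom, pos, ref, alt); the truth side is filtered
to depth ≥ 8 and call probability ≥ 0.9999 (from GQ as 1 − 10^(−GQ/10))
before comparison. Comparison is on alt-allele dosage (0/1/2), not phased
genotypes — phase errors are not genotyping errors for this metric.
Genotype concordance is the percent of identical dosages per MAF bin;
non-reference concordance restricts to sites where either call is
non-reference (and is therefore not symmetric in the two call sets, unlike
the genotype metric). Bins are half-open on the standard edges 0, 0.001,
0.002, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5, the last bin closed; empty bins
report absent, not 0. MAF comes from the reference-panel annotation, not
from the sample itself (undefined at n = 1); multi-allelic records must be
split upstream and are rejected otherwise.

## Synthetic fixtures: what they emulate, and what they do not

Every generator draws from its own random stream derived from the master
seed via a stable labelled hash, so generators never perturb each other
and byte-identical regeneration is guaranteed (and tested). Default
magnitudes follow typical adaptive-sampling practice: ~10× enrichment,
on-target N50 around 9 kb, off-target around 0.6 kb, a 10-sample control
panel, 20× CpG coverage.

Design choices worth knowing when interpreting green tests:

* **MEI events**: the source element is a concatenation of consensus
  copies planted in a random genome; the transduction is the genome's own
  downstream sequence. The transduction's last 10 bases are drawn A-free so
  the transduction/poly-A boundary is identifiable — with a tolerant tail
  detector, a tail preceded by adenines has genuinely ambiguous length.
  Insertion sites where the local sequence makes the planted TSD ambiguous
  (a chance extension of the duplication) are resampled, reflecting the
  documented non-repetitive-flank assumption. Alignment identity is 100%
  by construction; the fixtures exercise the decomposition logic, not
  tolerance to sequencing error or element divergence.
* **Methylation**: promoter CpGs near ratio 0.05, gene-body near 0.85,
  the planted haplotype's promoter at 0.9, counts binomial with coverage
  split evenly across haplotypes. Real panels have bimodal but noisier
  ratios, covariate structure and missing sites; the fixtures demonstrate
  rule correctness and end-to-end recovery, not clinical sensitivity.
* **Genotypes**: MAF uniform within each bin, truth genotypes from
  Hardy–Weinberg proportions, planted per-bin flip errors. Real imputation
  error is MAF-dependent in shape, not flat.
* **SV callsets**: five exemplar genes with a fixed exon/CDS/UTR
  architecture (seeded jitter only) guarantee that every rule and category
  has a well-defined exemplar at any seed.
* **Alignment summaries**: read lengths are log-normal (sdlog 0.25) with
  the log-mean solved so the length-weighted median — the N50 — matches the
  request (N50 = exp(μ + σ²) for a log-normal); the on/off read split is
  solved from the requested enrichment and expected lengths. Reads are
  placed to fit inside one region interval when possible, so measured
  enrichment converges to the request.

## Check problem sizes

The shipped checks run at desk scale, chosen to exercise every rule while
keeping the suite quick: synthetic genomes of 60–300 kb; 100 seeded MEI
events (including the two SVA case analogs with TSD/poly-A/transduction of
14/24/82 and 15/55/91 bp) requiring exact recovery of all lengths and the
source locus; 20 seeded methylation datasets requiring exactly the planted
gene × haplotype flagged; ~8000 Fisher tables with margins up to 200
against full enumeration; 10⁴ genotype sites with a planted 2% error
checked against the binomial 99% interval per bin; and per-base brute-force
oracles for the interval engine.

## Known limitations

* The MEI aligner assumes near-exact copies; no affine-gap scoring.
* Poly-A length is ambiguous by nature when the upstream sequence is
  A-rich; the detector's trim rule resolves it toward the contiguous tail.
* The epimutation screen assumes the control panel is unaffected at every
  site; a contaminated panel shifts classes silently.
* Non-reference concordance in very rare MAF bins is dominated by a
  handful of sites and is reported but not meaningful at small n.
* BAM input for QC requires Rsamtools; the TSV path is the first-class,
  dependency-light route.
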