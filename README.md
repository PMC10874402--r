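# taslrs

Downstream interpretation toolkit for **targeted adaptive-sampling long-read
sequencing (TAS-LRS)** of hereditary cancer gene panels.

Adaptive sampling lets a nanopore device eject molecules that do not match a
target region list in real time, yielding deep coverage over a gene panel
(~10× enrichment) plus shallow genome-wide off-target coverage. Getting from
the resulting calls to a clinical-style interpretation takes a stack of small,
rule-driven analyses that are usually scattered across ad-hoc scripts. This
package implements that stack as a tested, deterministic library:

* **Target design** — build the adaptive-sampling BED from gene annotation:
  maximal transcript span per gene, symmetric margin (default 10 kbp),
  manual extension regions, merged output.
* **Sequencing QC** — on/off-target mean depth, enrichment ratio
  (depth_on / depth_off) and per-class read N50.
* **SNV/indel prioritization** — quality filter (QUAL > 10), gene-region
  restriction excluding simple-repeat and segmental-duplication masks,
  common-variant removal (population AF ≥ 0.01 in gnomAD/ToMMo-style
  sources), then three pathogenicity rules: ClinVar
  Pathogenic/Likely-pathogenic, LOFTEE high-confidence loss of function,
  and splicing (essential GT–AG site or SpliceAI delta ≥ 0.50).
* **SV post-filtering** — the false-positive elimination filter (breakend on
  non-primary contig; no breakend in targets; indel/duplication contained in
  a simple repeat ± 10 bp) and putative-pathogenic classification
  (CDS-hitting deletions, CDS-amplifying duplications, gene-disrupting
  inversions/translocations, intragenic single breakends).
* **Mobile-element insertion annotation** — the curator's reading of a
  retrotransposition event, automated: target-site duplication from the
  flanks, poly-A tail, repeat-family segmentation against a consensus
  library (supports concatenated SVA copies), source-locus tracing with 3′
  transduction and AATAAA polyadenylation-signal detection, and
  (CCCTCT)n 5′ hexamer-head / truncation status.
* **Allele-specific methylation (epimutation) screen** — classify CpG sites
  from a 10-sample control panel (normally unmethylated: ratio 0–0.2 in all
  controls; normally methylated: 0.8–1), call per-haplotype
  hyper/hypomethylation with a two-sided Fisher exact test (p ≤ 0.05), and
  flag a gene × haplotype when the promoter window (2000 bp upstream of the
  TSS) has mean −log10(p) ≥ 4.5 or ≥ 10 aberrant CpGs.
* **Genotype concordance** — MAF-binned genotype and non-reference
  concordance between an imputed call set and a truth call set, with the
  standard bins (0, 0.001, 0.002, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5) and
  truth-side depth/GQ filters.
* **Synthetic fixtures** — seeded generators for every input (genomes, gene
  annotation, MEI events, methylation count tables, genotype pairs, SV
  callsets, alignment summaries), each returning a manifest of the planted
  ground truth.

Patient data for this kind of study are controlled-access; every analysis
here runs on synthetic fixtures or on your own files in standard formats
(BED, GTF/GFF, VCF, FASTA, TSV).

## Worked example

Annotate a synthetic SVA insertion mirroring a germline event in a cancer
predisposition gene (two concatenated SVA_F copies, 82 bp 3′ transduction,
24 bp poly-A tail, 14 bp target-site duplication):

```r
library(taslrs)

ev  <- make_mei_event(12)   # plants the event; manifest records the truth
ann <- annotate_insertion(ev$call, ev$lib, ev$genome$sequences,
                          ev$genome$repeat_mask)
ann
#> mei_annotation: 2706 bp analyzed [+], TSD 14 bp, polyA 24 bp,
#> transduction 82 bp (AATAAA found), source chrS:5201-7882(+),
#> hexamer head absent (5' truncated)
ann$segments
#>   start  end        label cons_start cons_end identity
#> 1     0 1200        SVA_F        200     1400      100
#> 2  1200 2600        SVA_F          0     1400      100
#> 3  2600 2682 transduction         NA       NA       NA
#> 4  2682 2706        polyA         NA       NA       NA
```

Reading the output: the inserted sequence decomposes into two adjacent
SVA_F copies (the first 5′-truncated, so the element has lost the
(CCCTCT)n head it needs to remobilize), followed by 82 bp of unique
sequence carried over from downstream of the source locus (the 3′
transduction, which pins the source to `chrS:5201-7882` and contains the
AATAAA polyadenylation signal) and a 24 bp poly-A tail. The 14 bp
target-site duplication flanks the insertion point.

The same pattern works for every stage, e.g. the QC summary:

```r
cs  <- c(chr1 = 300000)
ga  <- make_gene_annotation(13, cs, n_genes = 10)
td  <- build_target_regions(ga$genes, chrom_sizes = cs)
sim <- make_alignment_summaries(13, td$regions, cs, enrichment = 10)
summarize_sample(sim$alns, td$regions, cs)
#> coverage_summary: on-target 495.42x (10907 reads, N50 9045),
#> off-target 49.170x (9093 reads, N50 598), enrichment 10.08
```

A thin command-line wrapper (`inst/cli/taslrs`) exposes the stages as
subcommands (`build-targets`, `qc`, `prioritize-snv`, `filter-sv`,
`annotate-mei`, `epimutation`, `concordance`, `simulate`); run it with
`--help` for usage.

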