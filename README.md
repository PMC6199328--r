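# tedeff

Scoring defective transcription elongation (TEdeff) in tumor cohorts.

A substantial fraction of tumors carries a genome-wide defect in RNA
polymerase II elongation.  Such tumors preferentially express short,
truncated transcript isoforms of switch-regulated (AT) genes, lose
gene-body exon expression while gaining at 3'-terminal exons in long
stimulus-responsive genes (Class I), retain introns, show
promoter-proximal polymerase stalling, and respond poorly to
immunotherapy.  This package implements the full quantitative pipeline
for calling the phenotype and its consequences from standard
transcriptomic and epigenomic inputs, for computational biologists
working with bulk RNA-seq, exon-level matrices, spliced alignments, ChIP
coverage, methylation arrays and clinical tables.

## What it computes

* **AT genes and TEdeff score** — per-gene isoform-switch score
  (mean across isoforms of Var over samples of
  log2(isoform+1) − log2(gene+1)), anti-correlated short/long isoform
  clusters, and the per-sample score
  log2((mean short + 1)/(mean long + 1)), classified TEdeff when
  strictly above −1.
* **Exon-bin profiles and gene classes** — per-exon Welch *t* (TEdeff −
  TEprof) mapped to 20 positional bins 5'→3'; Class I = body loss +
  terminal gain, Class II = overall overexpression; structural contrasts
  of the classes; a transcript-relative methylation meta-profile.
* **Intron retention** — exon–exon / exon–intron / intron–exon junction
  reads from SAM alignments (8 bp anchors, MAPQ > 20, ±150 bp windows);
  retention ratio (EI+IE)/EE over eligible junctions (EE ≥ 5, intron >
  500 bp); median split with ties to the low group.
* **Region enrichment** — observed overlap of gene-region sets
  (promoters (−1000,+1), exons, introns) with interval datasets against
  1000 length-matched permutation draws from a background pool; Z,
  two-sided p, and delta-Z between gene sets.
* **RNAP II profiles** — meta-gene coverage (2 kb flanks, 101-point
  length-normalized body, per-million scaling) and traveling ratios
  (body/TSS occupancy).
* **Outcomes** — Kaplan–Meier curves, Cox Wald + log-rank comparisons,
  GZMK/PRF1 TIL score, therapy-class mapping from a shipped drug
  vocabulary, and two-factor stratification.
* **Synthetic cohort** — a deterministic generator that plants all of the
  above (isoform shift, Class I/II structure, retention rates, traveling
  ratios, hazard ratio) and writes GTF / TSV / SAM / bedGraph / JSON, so
  the whole pipeline is testable without external data.

## Worked example

The `analysis/` directory is a numbered workflow over the package; step 1
simulates the default cohort (60 tumors, 25% TEdeff) and later steps
consume its files from `results/cohort/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_score_tedeff.R
Rscript analysis/04_junction_retention.R   # needs 02 for labels; 03 for classes
```

Step 2 prints, for the default simulation:

```
AT genes called: 12 of 120 scorable genes
TEdeff samples: 15 of 60 (score > -1)
score range: -3.10 .. -0.20
```

— exactly the 12 planted AT genes are recovered, and the 15 samples whose
short/long usage was shifted score above the −1 cutoff.  Step 4 then
prints:

```
retention ratio medians: TEdeff 0.303, TEprof 0.040
median split: 30 high / 30 low (median 0.042)
```

— TEdeff samples retain introns at roughly the planted rate (unspliced
reads are generated at 15% vs 2% of the spliced rate per boundary, and
the ratio counts both boundaries of each intron).  Step 5 reports the
permutation enrichment of Class I vs Class II gene regions against a peak
set planted over Class I promoters and first introns:

```
promoter  ClassI z =   7.19, ClassII z =  -2.02, delta-Z =   9.21
introns   ClassI z =   3.12, ClassII z =  -2.02, delta-Z =   5.14
```

In code, the same pieces are ordinary function calls:

```r
library(tedeff)
b <- generate_cohort(cohort_config(seed = 1), components = "expression")
isos <- unlist(lapply(b$models, `[[`, "isoforms"), recursive = FALSE)
lens <- setNames(sapply(isos, `[[`, "transcript_length"),
                 sapply(isos, `[[`, "isoform_id"))
at <- call_at_genes(b$iso_expr, b$gene_expr, lens)
score <- tedeff_score(b$iso_expr, at)
table(classify_tedeff(score), b$truth$labels[names(score)])
```

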