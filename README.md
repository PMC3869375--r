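# enhancerIslands

Histone H3K4 mono-/di-methyltransferases such as MLL4 (KMT2D) mark the
enhancers that drive cell-type-specific gene programs: during
adipogenesis and myogenesis, MLL4 binding shifts onto the enhancers of
the induced lineage, co-localizes there with the lineage-determining
transcription factors (C/EBPα/β and PPARγ, or MyoD), and its loss
removes H3K4me1/H3K27ac and the associated gene induction.
`enhancerIslands` implements the complete computational workflow behind
that kind of study, for analysts working from mapped ChIP-seq/RNA-seq
tag files (BED) and a TSS/exon annotation:

* **Island calling.** SICER-style identification of ChIP-enriched
  regions: non-overlapping windows of width *W* (200 bp for histone
  marks, 50 bp for TFs/MLL4/Pol II), Poisson background rate
  λ = *NW*/(*G*·f<sub>eff</sub>), eligible windows
  (P(X ≥ c; λ) < 0.2) merged across gaps of ≤ *g* windows, islands
  scored Σ −ln Poisson-pmf and tested against a control library with
  Benjamini–Hochberg FDR — all tails in log10 space, so p-values far
  below double-precision underflow stay exact.
* **Knockout specificity filter.** Islands are retained only where
  enrichment in control cells significantly exceeds the depth-scaled
  signal in knockout cells (one-sided Poisson, FDR < 10⁻¹⁵), removing
  antibody artifacts that appear in both genotypes.
* **Chromatin states.** Four mutually exclusive element classes from
  H3K4me1/H3K4me3/H3K27ac islands: active/silent promoters (±2.5 kb of
  a TSS) and active/silent enhancers; peak-to-class distribution;
  lineage-enhancer groups (C/EBP⁺PPARγ⁻, C/EBP⁻PPARγ⁺, C/EBP⁺PPARγ⁺)
  by ≥ 1-bp overlap with TF islands.
* **Co-localization statistics.** Venn-style overlap partitions,
  emergent regions across time points, top-*n* ranking by FDR,
  log-space hypergeometric and binomial enrichment tests, average
  profiles (5-bp bins, ±10 kb) and ranked heat-map matrices (50-bp
  resolution, ranked by the central 400-bp signal), Wilcoxon rank-sum
  comparisons.
* **Expression.** Exonic RPKM; up/down regulation and knockout
  dependence at a strict >2.5-fold cutoff; hypergeometric enrichment of
  dependent genes among up-regulated genes; nearest-TSS
  enhancer-to-gene assignment within 1,000 kb with category resolution;
  per-category fold-change summaries.
* **Recovery analysis.** The filtering chain for ectopic-C/EBPβ
  enhancer recovery (TF binding → MLL4 → H3K4me1 + H3K27ac), the
  premarked/de-novo split, and knockout dependence of H3K4me1 at
  recovered sites.
* **Synthetic data.** A fully seeded generator producing annotation,
  ChIP read libraries (planted islands over uniform background,
  knockout depletion, antibody-artifact sites) and expression counts
  with planted effects, plus ground-truth tables for parameter-recovery
  testing.

## Worked example

The numbered drivers under `analysis/` run the whole study on simulated
data (seed 42; one 10-Mb chromosome, 600 enhancers, 200k tags per
library):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_islands.R
Rscript analysis/03_classify_elements.R
Rscript analysis/04_colocalization.R
Rscript analysis/05_expression.R
Rscript analysis/06_recovery.R
```

Step 2 prints, among others:

```
mll4_control: 223 islands (W=50, FDR<1e-15)
MLL4 after specificity filter: 173 of 223 islands retained
recovery of planted MLL4 sites: precision 1.000, recall 1.000
```

223 MLL4 islands are called against input; the knockout filter removes
exactly the 50 planted antibody-artifact sites, and the 173 survivors
coincide perfectly with the planted MLL4⁺ enhancers. Step 3 classifies
all 1,050 planted elements into the correct classes and finds every
filtered MLL4 peak on active enhancers
(`binomial test ... log10 p = -164.2`); step 5 recovers the 40 planted
knockout-dependent genes with precision and recall 1.000 and prints the
per-category fold-change table, where only the C/EBP⁺PPARγ⁺/MLL4⁺ gene
group collapses in the knockout (median log2 FC ≈ −2.5, 67% induced at
day 2, all other groups flat). Step 6 walks the recovery chain
(155 → 104 → 18 → 15 recovered) and finds H3K4me1 significantly
decreased at 100% of recovered enhancers in the knockout.

Equivalently, `run_pipeline(pipeline_config(...))` executes the same
stages from a sample manifest (or its YAML form) and writes BED/TSV
tables, `summary.json` and a run log to an output directory.

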