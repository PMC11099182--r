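# bcrtrace

Clonal-family inference and signature projection for plasma-cell
repertoires.

After vaccination, newly formed antibody-secreting cells (ASC) circulate in
blood and some are recruited into the long-lived bone-marrow plasma-cell
(BMPC) compartment. Tracking that recruitment computationally requires two
linked analyses on paired single-cell data: (i) grouping cells into
**clonal families** from their B-cell-receptor (BCR) sequences and relating
families to transcriptional clusters and to antigen-specific reference
clones, and (ii) projecting **vaccination-time-point gene signatures** onto
individual plasma-cell transcriptomes. `bcrtrace` implements both ends of
that pipeline for R, together with seeded simulators that generate
ground-truthed inputs so every stage is testable without any external
download.

## What the package computes

**Repertoire side** (AIRR-style rearrangement tables, one contig per row):

- `select_contigs()` — keeps, per cell and chain, the most abundant
  productive and fully sequenced contig; drops unpaired cells and reports
  the counts.
- `reconstruct_germline()` — reverts the mutation-event table on the gapped
  observed sequence to recover the germline FR1-CDR1-FR2-CDR2-FR3 string.
- `mutation_rate()` — somatic-hypermutation load: (heavy + light mutation
  counts) / (heavy + light region length), for FR1–3 or CDR1–2.
- `partition_families()` — clonal families: same donor, V/J genes and CDR3
  lengths on both chains, with CDR3 nucleotide identity **strictly greater
  than 80%** on each chain, under deterministic complete-linkage
  agglomeration.
- `family_diversity()`, `simpson_index()`, `overlap_table()`,
  `permutation_overlap_test()` — per-cluster family counts, Gini–Simpson
  diversity, and shared-family overlap between clusters with a
  1000-permutation null on the family annotation.
- `match_public()` — putative antigen-specific ("public") cells: CDR3
  lengths equal on both chains and joint nucleotide identity
  `(matches_H + matches_L) / (len_H + len_L)` **at least 80%** against a
  reference clonotype table.

**Expression side** (Matrix Market UMI counts + GMT gene sets):

- `log_normalize()` — `ln(10000 * UMIsGene / UMIsTotal + 1)`.
- `derive_signature()` — marker genes with ROC AUC > 0.6 and adjusted
  Mann–Whitney p ≤ 0.05 (target group vs rest).
- `gsea_per_cell()` — pre-ranked GSEA per cell: genes ranked by deviation
  from the population mean, weighted Kolmogorov–Smirnov running-sum ES,
  1000 random same-size gene sets as null, NES/nominal p/FDR, and the
  significance rule FDR ≤ 0.50 with p < 0.05.
- `summarize_clusters()`, `cluster_expression_stats()` — per-cluster
  enrichment fractions, NES distributions with Mann–Whitney comparisons,
  z-scored mean expression and expressing fractions.

**Simulators** — `simulate_repertoire()`, `plant_public_clones()` and
`simulate_expression()` generate paired-chain repertoires with clonal
structure, SHM, decoy contigs and planted public clones, and
negative-binomial UMI matrices with planted cluster-specific gene modules,
all with explicit seeds and the generating truth returned alongside.

## Worked example

The `analysis/` directory holds the pipeline as five numbered drivers
(`01_simulate_data.R` … `05_gsea_projection.R`) that chain through
`results/`. Running them in order prints, among other things:

```
Contig selection: 193 of 200 cells paired ( 7 unpaired dropped, 23 contigs filtered )
Clonal partition: 193 cells in 30 families
  identity threshold > 0.8 | chain mode: per_chain | linkage: complete
Family diversity per cluster: BMPC1=19, BMPC2=23, BMPC3=27
Simpson diversity index (whole repertoire): 0.9149
Mean FR1-3 mutation rate: 0.0206
Matched 80 putative antigen-specific cells against 5 references
Planted truth recovered exactly: TRUE
Gene signature 'cluster1_signature': 50 genes (AUC > 0.6, adjusted p <= 0.05, bonferroni)
Planted-module recall: 1.00; false inclusions: 0
Fraction of cells significantly enriched (positive NES) per cluster:
  cluster 1: 0.985 (median NES 2.12 over 200 cells)
  cluster 2: 0.000 (median NES 0.00 over 200 cells)
```

Reading the output: 30 simulated clones are recovered as exactly 30
families; the mean framework mutation rate (0.0206) matches the planted
per-base SHM rate of 0.02; all cells related to the 5 planted reference
clonotypes — and no others — are flagged public; the 50-gene module planted
in cluster 1 is recovered in full by the AUC/Mann–Whitney screen with no
false inclusions, and the per-cell GSEA flags 98.5% of cluster-1 cells (and
almost nothing elsewhere) as significantly enriched with positive NES.

A minimal interactive session:

```r
library(bcrtrace)

sim  <- simulate_repertoire(repertoire_sim_config(n_cells = 60, n_clones = 10, seed = 1))
sel  <- select_contigs(sim$rearrangements)
part <- partition_families(sel$pairs)
part
#> Clonal partition: 58 cells in 10 families
#>   identity threshold > 0.8 | chain mode: per_chain | linkage: complete
simpson_index(part)
#> [1] 0.7990488
```

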