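---
title: "Methods: clonal-family inference and signature projection for plasma-cell repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal-family inference and signature projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`bcrtrace` implements the computational core of a workflow for tracking the
recruitment of antibody-secreting cells into the bone-marrow plasma-cell
(BMPC) compartment from paired single-cell B-cell-receptor (BCR) and
transcriptome data. Five pieces fit together:

1. selection of one analysis contig pair (heavy + light) per cell and
   reconstruction of gapped germline V-region sequences;
2. clonal-family inference from CDR3 nucleotide identity;
3. matching against experimentally validated antigen-specific reference
   clonotypes ("public" clones);
4. repertoire statistics — diversity, Simpson index, and a permutation test
   for clonal overlap between transcriptional clusters;
5. per-cell pre-ranked gene-set enrichment (GSEA) that projects
   vaccination-time-point signatures onto plasma-cell transcriptomes.

Because the workflow's real inputs (10x V(D)J assemblies annotated by
IMGT-style tools, and aggregated UMI matrices) are large and partly gated
behind manual QC steps, the package ships seeded simulators for both
modalities with planted ground truth. Every claim the test suite makes is a
claim about recovering that truth.

# Contig selection and the BCR data model

A cell sequenced with a 5' V(D)J assay often yields several contigs per
chain. The analysis keeps, per cell and locus, the most abundant contig
among those that are productive and fully sequenced, where "fully
sequenced" is operationalised as: complete V(D)J annotation, all five
regions FR1, CDR1, FR2, CDR2, FR3 present with non-zero length, and a
non-empty CDR3. Abundance is the UMI count (`duplicate_count`); ties break
by read count (`consensus_count`), then by the lexicographically smallest
contig identifier, so selection is fully deterministic. Cells that lack a
valid heavy or light contig after filtering are unpaired and are removed,
with the count recorded in the run report.

Each retained contig carries the IMGT-style gapped observed sequence over
FR1–FR3 and a mutation-event table (`region:gapped-position:germline>observed`).
`reconstruct_germline()` reverts the listed substitutions to reverse-engineer
the gapped germline string; the operation validates that positions fall in
their stated region, never at a gap, and that listed observed bases agree
with the alignment. On simulated data the reconstruction must equal the
generator's germline exactly, for every contig — this is one of the
package's acceptance properties.

Mutation rates are defined as the summed heavy + light mutation counts of a
region group divided by the summed nucleotide length of those regions.
Region lengths are gap-excluded; the gapped/ungapped choice is not fixed by
the underlying convention, and we flag it as a deliberate decision — with
i.i.d. substitutions the expected rate is unaffected. The framework group
pools FR1–FR3. The CDR group pools CDR1–CDR2 only: the CDR3 junction has no
reconstructed germline in this schema, so junction mutations are not
observable, and pretending otherwise would silently understate CDR
mutation loads.

# Clonal families

Two cells belong to the same clonal family when they come from the same
donor, use the same heavy and light V and J genes, have equal CDR3 lengths
on both chains, and their CDR3 nucleotide identity *exceeds* 80% on each
chain (equivalently, Hamming distance strictly below 20%). The strict
inequality matters: a 15-nt CDR3 pair with exactly 3 mismatches (identity
0.80) is *not* co-clustered. Public-clone matching below deliberately uses
the opposite convention (inclusive at 0.80) because the two procedures are
defined with different wordings, and both are honoured.

"Every pair of family members must satisfy the rule" is a clique condition;
minimum clique cover is NP-hard, so the package uses deterministic
complete-linkage agglomeration as the tractable surrogate (documented as
such): cells are sorted by identifier, cluster distances are the maximum
pairwise chain-aware distance, merges happen while the linkage distance is
strictly below the cutoff, and distance ties merge the smallest cluster-pair
index. Single linkage is available for users who prefer chained families.
The chain-aware distance is, in the default `per_chain` mode, the maximum of
the two chains' normalised Hamming distances (each chain must pass
independently); `joint` mode pools mismatches over both chains and is kept
because the narrative definitions in the field are ambiguous between the
two readings.

Two further definitional choices were genuinely open:

* **Germline key.** One reading of the family definition also requires
  identical germline FR1–FR3 sequences. On allele-free segment libraries
  the (donor, V, J, length) key already determines the germline, so the
  germline key defaults to off; setting `use_germline_key = TRUE`
  reproduces the literal reading.
* **Simpson index.** Whether the index was computed with or without
  replacement is unstated in typical descriptions; the default is the
  Gini–Simpson form with replacement, `1 - sum(p_i^2)`, with the unbiased
  without-replacement estimator available (`method = "unbiased"`). The two
  closed forms differ exactly as textbook formulas predict (e.g. N
  singletons give `1 - 1/N` vs 1).

Diversity per transcriptional cluster is the number of distinct families
with at least one member in the cluster; the overlap table counts families
shared between cluster pairs. Overlap significance comes from permuting the
clonal-family annotation across cells (cluster labels fixed), 1000
permutations by default, with the add-one estimator
`p = (1 + #{perm >= obs}) / (1 + n_perm)` so p-values never reach zero.

The permutation statistic is a small integer count, so its null
distribution is discrete and the test is conservative when the overlap has
few attainable values. The calibration study in the test suite therefore
uses a configuration with a reasonably fine-grained statistic — 600 cells
in 150 power-law-sized families over 3 random clusters — under which the
empirical type-I error at the 0.05 level over 500 simulated datasets falls
within [0.03, 0.07]. On very small repertoires users should expect the test
to be conservative, never anti-conservative.

# Public clones

A repertoire cell is a putative antigen-specific (public) clone when its
CDR3 lengths agree with a reference clonotype on both chains and the joint
nucleotide identity — identical nucleotides summed over both CDR3s divided
by their total length — is at least 0.80 (inclusive). Pairs with unequal
lengths on either chain are incomparable and can never match. V/J agreement
is *not* required by default (the defining criteria are length consistency
and identity only), but a `require_vj` flag adds it for users who want the
stricter variant; `per_chain` mode likewise requires each chain to reach
the threshold separately. Length-bucketing is purely an optimisation: the
test suite proves equality with a brute-force all-pairs scan on every
tested instance.

# Expression normalisation, signatures, and per-cell GSEA

Counts are normalised as `ln(10000 * UMIsGene / UMIsTotal + 1)` (natural
log). Marker signatures for a cell group are genes with ROC AUC
strictly above 0.6 (rank-based, midranks at ties) and a two-sided
Mann–Whitney p, adjusted across genes, at or below 0.05. Bonferroni is the
default adjustment — the conservative choice when a signature feeds a
downstream projection — with Benjamini–Hochberg available. The p-value uses
the normal approximation with tie correction and no continuity correction,
matching `wilcox.test(..., exact = FALSE, correct = FALSE)`.

For projection, each cell's genes are ranked by the difference between the
cell's log-normalised value and the mean over all cells of the analysed set
(joint centering across the whole matrix; per-sample centering is a
reasonable alternative the package does not default to). Ties break by gene
identifier. The enrichment score is the classic weighted Kolmogorov–Smirnov
running sum with weight exponent 1: member genes add
`|score|^w / sum(member |score|^w)`, non-members subtract `1/(N - |set|)`,
and the ES is the signed maximum deviation (positive branch preferred at
exact ties; if all member scores are zero the member increments fall back
to equal weights). The implementation evaluates the running sum only at
member positions in O(|set|) per set; the test suite checks it against the
full O(N) walk to 1e-12 on a thousand random instances.

The randomisation null draws `n_perm` (default 1000) random gene sets of
the same size. For efficiency one panel of random rank-positions per
distinct set size is drawn from the seeded generator and scored against
each cell's ranking — because the ranking is a permutation of the genes,
fixed random positions correspond to fresh random gene sets for every cell,
so the per-cell null is exact while the whole run stays reproducible and
fast. NES divides the ES by the mean magnitude of same-sign null scores;
the nominal p is the add-one same-sign tail fraction. The FDR q-value
follows the NES-based procedure of classic GSEA, computed within each cell
across gene sets and signs, with a BH-on-nominal-p alternative behind a
flag. A cell × set result is *significant* at the permissive rule
`FDR <= 0.50` and nominal `p < 0.05`; this rule is calibrated empirically
in the tests, where the per-set flag rate under a null simulation stays
below 10%.

One consequence of mean-centering deserves emphasis: when a module is
genuinely up in a subset of cells, the remaining cells see those genes
*below* the population mean and are systematically depleted (negative ES).
The recovery analyses therefore count "flagged" cells as significant with
positive NES — the enrichment direction that the workflow plots.

# The simulators: what they emulate and what they do not

**Repertoire.** Clone sizes follow a truncated power law (exponent 2) —
skewed like real plasma-cell repertoires while keeping families small
enough for exhaustive oracles — with one guaranteed cell per clone. Each
clone draws donor, V/J segments per chain from a bundled, fully synthetic
segment library (6 heavy V, 3 heavy J, 4 light V, 3 light J; IMGT-style
gapped V sequences with `.` characters inside CDR spans), and ancestor
CDR3s of random length (24–60 nt, multiples of 3). Within-clone CDR3
variation is confined to a per-clone mutable-position set of size
`floor(divergence * L)`, which *bounds pairwise* intra-clone distance by
`divergence` — so `divergence < 0.2` guarantees families are separable
under the 80% rule, and the generator rejects configurations that break
the guarantee. Decoy clones share donor/V/J/CDR3-length with a partner but
differ at a disjoint position block sized to cap cross-clone identity at a
stated ceiling (default 0.6). SHM is i.i.d. per-base substitution on
non-gap positions of the gapped V region (no indels, no hotspot bias, no
isotype dynamics — the downstream statistics consume substitution counts
only). Decoy *contigs* (unproductive with higher UMIs, lower-UMI
duplicates, partial assemblies) and heavy-only cells exercise the
selection and pairing filters.

**Expression.** Genes × cells negative-binomial counts with per-gene
log-normal baseline means (meanlog `log(0.5)`, sdlog 1), shared inverse
dispersion 2, and per-cell log-normal library-size multipliers (sdlog 0.3),
yielding median library sizes around 1,600 UMIs — the shallow end of
plasma-cell data. Planted modules multiply member-gene means by
`exp(effect)` in their target clusters only; module members' baselines are
redrawn from a moderately-expressed law (meanlog `log(1.5)`, sdlog 0.5)
because marker genes of real signatures are detectably expressed genes.
The simulator does not emulate batch effects, doublets, ambient RNA,
mitochondrial stress gradients, or correlated gene-gene noise — so passing
recovery tests demonstrates correctness of the statistics, not robustness
to every artefact of real data.

**Public references.** References are derived from repertoire cells by
substituting a controlled fraction of concatenated CDR3 positions, so the
joint identity of a planted pair is known by construction; the generator's
truth lists every cell at or above the 0.80 floor by direct scan.

# Problem sizes and numerical choices

The bundled analyses and acceptance checks run at deliberate desk scale:
repertoires of 60–200 cells (10–30 clones), expression matrices of 2,000
genes × 1,000 cells, 1,000 GSEA randomisations, 500-dataset calibration
studies at 200 permutations each. These sizes make every stochastic claim
re-computable in minutes on one core while keeping the estimators in the
regimes they were designed for.

Numerical conventions worth knowing: identity thresholds compare exact
mismatch-count ratios (`k/L`), never `1 - identity`, so the 0.80 boundary
is razor-sharp in floating point; agglomeration uses an explicit strict
cutoff with a 1e-12 tie tolerance; the GSEA weight exponent is fixed at 1
unless overridden; gene sets smaller than 5 members after filtering are
dropped with a warning; and every random stage takes an explicit integer
seed, with byte-identical reruns asserted in the tests.

# Known limitations

* Clonal families are a complete-linkage surrogate for the clique
  condition; pathological groups can exist where a true minimum clique
  cover differs from the agglomerative answer.
* The CDR mutation-rate group excludes CDR3 (no junction germline).
* The permutation overlap test is conservative on coarse statistics.
* The per-cell GSEA null resamples gene sets ("gene-permutation" flavour);
  phenotype permutation is out of scope, and the package makes no claim
  about inter-gene correlation robustness.
* The simulators are stand-ins with planted truth, not generative models of
  any particular dataset.
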