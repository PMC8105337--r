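---
title: "Methods: clonal tracing of multiple myeloma from single-cell and linked-read data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal tracing of multiple myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelotrace)
```

# Scope and model

`myelotrace` implements the bespoke computational steps of a longitudinal
multi-omics analysis of multiple myeloma (MM): linking bulk-derived somatic
mutations to individual cells of a droplet scRNA-seq library, phasing somatic
mutations onto germline haplotypes with linked reads, consensus filtering of
multi-caller somatic call sets, ancestry inference by thresholded genotypes
plus reference-panel PCA, ordered copy-number categorization, and tracking of
plasma-cell subpopulations across disease stages. External heavy machinery
(aligners, variant callers, expression-based CNV estimators) is deliberately
consumed as input, never re-implemented; this package owns the decision rules
applied to their outputs.

Every stage is exercisable on synthetic data with known truth. The
generators in the `gen_*` family are first-class, tested code: they define
the study conditions under which the pipeline's claims are verified.

## The clonal model

A patient's tumor is a rooted subclone tree. Subclone 1 is truncal with
cancer-cell fraction (CCF) 1 at every timepoint; each descendant's CCF never
exceeds its parent's, and the summed CCF of a node's children never exceeds
the node's own CCF, so the *exclusive occupancy* of each node — the fraction
of tumor cells belonging to that subclone and to no descendant — is
non-negative and well defined. Cells and DNA molecules are sampled from
these occupancies (scaled by purity, with a normal compartment of size
`1 - purity`). Each somatic SNV belongs to exactly one subclone and one
germline haplotype; a cell or molecule carries the variant iff the variant's
subclone lies on the lineage from the root to the cell's subclone (and, for
molecules, the haplotypes agree).

# Per-cell mutation mapping (scmap)

`extract_observations()` walks each read's CIGAR string to find the base
aligned at a somatic SNV position; only aligned (non-gap, non-clipped) bases
with mapping quality ≥ 10 count, and unmapped, secondary, supplementary and
duplicate reads, or reads lacking the cell-barcode/UMI tags, are skipped
with counts logged. `collapse_umis()` reduces reads to UMIs by strict
per-UMI majority (ties discard the UMI — a chimeric or error-laden molecule
carries no usable evidence) and classifies each (cell, variant) as
*alt-detected* (≥ 1 alt UMI), *ref-only*, or *no-coverage*.

The group-level single-cell VAF is defined at the **cell** level:
alt-detected cells over covered cells. The UMI-level fraction is also
reported as a secondary column; the cell-level definition is primary because
per-cell transcript counts vary over orders of magnitude and would otherwise
dominate the group statistic. Groups with zero covered cells are reported
missing (`NA`), never zero — absence of evidence is not reference evidence.

# Linked-read phasing (linkphase)

Observations sharing a barcode on one chromosome are chained into a molecule
while consecutive positions are ≤ 50 kb apart (`max_gap_bp`); larger gaps
indicate barcode reuse by a distinct fragment. Haplotype assignment lets
each alt-carrying molecule vote for the haplotype matching the majority of
its covered phased hets; the aggregate call requires ≥ 2 votes and a winning
fraction ≥ 0.8, else *ambiguous*.

For a somatic pair, only molecules whose consensus covers both positions are
informative. One both-alt molecule (configurable `min_cis`) forces *cis*;
otherwise *independent* requires each variant observed among the
both-covering molecules and ≥ 3 such molecules (`min_cover`). Three is
deliberately chosen over two — a single chimeric barcode should not be able
to flip a verdict — while the motivating use case (two hotspot mutations on
one haplotype, four covering molecules, zero co-occurrence) still resolves.
Pairs below the floor are *unresolved*, never guessed.

# Variant filtering (varfilter)

Somatic SNVs are kept when called by ≥ 2 of the SNV caller trio
(Mutect/VarScan/Strelka), indels by ≥ 2 of VarScan/Strelka/Pindel. Retained
records take the union of caller ids and the maximum of each depth/VAF field
across callers (the reconciliation rule is our choice; callers disagree and
a conservative merge should not discard the strongest evidence). The
coverage/VAF filter retains calls with tumor depth ≥ 14, normal depth ≥ 8,
tumor VAF ≥ 0.05 and normal VAF ≤ 0.02 — inclusive at the stated values,
since "a cutoff of 14×" conventionally admits 14×. SV events need somatic
score ≥ 30 and junction score ≥ 30.

Sample identity across timepoints is checked by Pearson correlation of
germline VAFs over a fixed locus panel (24 loci in the motivating design;
any panel is accepted). Pairs with r ≥ 0.8 over ≥ 5 shared covered loci are
flagged same-patient; fewer shared loci leave the pair unresolved. The 0.8 /
5 constants are our formalization: identical-genotype pairs sit near r = 1
and unrelated pairs near 0, so the margin is wide (the Monte-Carlo test in
the suite shows < 5% false same-patient flags on independent profiles).

# Ancestry (ancestry)

Genotypes are called from allele read counts by disjoint threshold rules
(hom-ref: ref ≥ 8 & alt < 4; het: ref ≥ 4 & alt ≥ 4; hom-alt: ref < 4 &
alt ≥ 8; otherwise missing), markers with > 5% missing calls are dropped,
and reference samples are embedded by PCA of dosages (missing imputed with
the per-marker mean, centered, scaled with an sd floor of 1e-8 — genotype
PCA is conventionally standardized; the floor guards monomorphic markers).
A random forest (500 trees) on the top 20 components, trained on a
stratified 80/20 split, provides ancestry classification; query samples are
projected with the *stored* reference statistics and never refit. Held-out
accuracy on the synthetic Balding–Nichols panel (3 populations, 200 samples
each, 2000 markers, Fst 0.1) exceeds 0.99; at Fst 0 the populations are
exchangeable and accuracy collapses to chance, guarding against label
leakage through the pipeline.

# Copy-number categories and subclustering (cnvcat)

Log2 copy ratios map to the ordered five-level scheme
deletion < loss < neutral < gain < amplification with platform cutoffs
(−1, −0.25, 0.2, 0.7) for bulk and (−1, −0.4, 0.3, 0.7) for
expression-derived ratios. Boundary values belong to the higher category
(the sources state the cutoffs without strictness; a half-open convention
makes the map total and monotone). Expression-derived intensities (linear,
neutral = 1) pass through `infercnv_to_log2()`: non-positive values clip to
1e-3 with a warning and the result clips to [−3, 3]. The chromosome-level
deletion flag is strict — mean relative copy < 0.76 — as printed; we read
the threshold on the relative scale where neutral = 1.

Subclustering restricts cells to a CNV-informative gene panel, reduces to
10 principal components, and runs DBSCAN over a grid (20 log-spaced eps
between the 5th and 95th percentile of pairwise distances × minPts
{5, 10, 15, 20}), choosing the parameters that maximize mean silhouette on
non-noise points with ≥ 2 clusters; ties break toward larger eps then larger
minPts (preferring the least fragmenting solution). We cluster in PCA space
rather than on a stochastic 2-D embedding so the result is deterministic.
Because DBSCAN leaves fringe points unassigned (label −1), accuracy against
planted truth is evaluated on non-noise cells; the planted-cluster ARI on
the synthetic three-subclone matrix is ≥ 0.9. Note the recoverable truth is
the *distinct copy-ratio profile*, not the subclone id: sibling subclones
with identical profiles are invisible to any CNV-only method.

# Subpopulations (subpop)

Counts are normalized to 10,000 per cell and log1p-transformed. DEGs use a
Wilcoxon rank-sum test (vectorized normal approximation with tie and
continuity corrections, cross-checked against `stats::wilcox.test`) of one
cluster against all other cells with Benjamini–Hochberg adjustment;
subcluster mode keeps fold change > 1.5 and FDR < 0.1, marker mode keeps
adjusted p < 0.05 with positive log fold change. The fold change is the
ratio of `expm1` of mean log-normalized expression (pseudo-count 1e-9).
The fold threshold is applied to up-regulation by default: fixed-budget
library normalization makes unaffected genes look spuriously *down* in a
cluster that up-regulates a program (a compositional artifact), and the
planted-program suites confirm FDR control only under the one-sided rule;
`positive_only = FALSE` restores the two-sided behaviour.

Pathway overrepresentation is an upper-tail hypergeometric test against a
gene universe with BH adjustment. Subpopulations are grouped by Pearson
correlation of −log10 q over pathways significant (q < 0.05) in at least
one subpopulation, followed by average-linkage hierarchical clustering on
1 − r (linkage and distance are our choice; the source states only
"hierarchically clustered").

Cross-timepoint tracking formalizes what the original analysis did by
visual co-clustering: similarity = 0.5 × Pearson(centroids over a shared
variable-gene panel) + 0.5 × (fraction of concordant per-chromosome CNV
categories), greedy best-first one-to-one matching, acceptance threshold
0.6. Matched pairs are *stable*; unmatched later subpopulations *gained*;
unmatched earlier ones *lost*. All three constants are exposed
configuration. The QC cross-check stratifies cells at 1000 expressed genes
and compares a gene program's per-cell score between strata within each
cell type, so program elevation that survives both strata cannot be a
library-quality artifact.

# What the synthetic data do and do not show

The generators emulate: clonally structured tagged reads (Poisson depth,
symmetric ref/alt flip errors, default rate 1%), linked-read molecules
spanning phased hets (unique 16-base barcodes, no collisions), multi-
population genotype panels (Balding–Nichols frequencies, Hardy–Weinberg
genotypes, binomial read counts), subclone CNV matrices (Gaussian noise on
log2 ratios), and negative-binomial expression with planted fold-change
programs and lognormal library sizes. They deliberately omit: realistic
error profiles and mappability structure, barcode collisions, doublets,
ambient RNA, batch effects, and linkage disequilibrium. Passing tests
therefore demonstrate correctness of the decision rules under their stated
models — not robustness to every artifact of real libraries.

Problem sizes in the test and acceptance runs (hundreds of cells or
molecules, hundreds to a few thousand markers/genes, tens to hundreds of
replicates) were chosen as the smallest scales at which the binomial/CLT
oracles have adequate power; all fixtures are regenerated from seeds at run
time.

# Numerical and degenerate-input choices

* All generators restore the caller's RNG state; identical (parameters,
  seed) give byte-identical output.
* Tied per-UMI and per-locus majorities are discarded, not broken.
* Genotype rules are disjoint by construction; anything else is missing.
* PCA scaling uses an sd floor of 1e-8; loadings are orthonormal to 1e-6.
* `categorize()` requires finite input; the intensity transform clips
  rather than errors.
* Degenerate clustering inputs (identical rows, no grid point with ≥ 2
  clusters) return a single cluster with a warning rather than failing.
* Zero-count cells are dropped at normalization with a warning; empty DEG
  sets yield q = 1 everywhere; empty strata yield `NA` entries.

# Known limitations

Indels are excluded from per-cell mapping (realignment around indels is not
modeled). The greedy matcher is not globally optimal (Hungarian assignment
would be; with the handful of subpopulations per sample the difference has
never mattered in testing). The cis/independent verdict treats any both-alt
molecule as cis evidence at the default `min_cis = 1`; noisy libraries may
warrant raising it. Ancestry accuracy figures on synthetic panels say
nothing about accuracy on any specific real reference resource.
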