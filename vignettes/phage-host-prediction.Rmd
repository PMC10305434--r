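---
title: "Predicting phage host genera from genome sequence: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage host genera from genome sequence: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

phagehost classifies a bacteriophage genome into one or more admissible
bacterial **host genera**. The underlying biological assumption is that
host specificity is carried by genes — receptor-binding proteins, lysins,
anti-restriction factors — and that phages infecting the same genus share
homologous copies of such genes even when no functional annotation exists.
The method therefore never looks at functions. It (1) extracts gene
products, (2) groups them into protein families by sequence similarity,
(3) represents each phage as an integer vector of family counts
*a(i, j)* = number of genes of phage *i* in cluster *j*, and (4) trains one
small, human-readable binary decision tree per genus. Prediction is
multi-label by construction: a vector is routed through every genus tree
and **all** positive trees contribute a host, because real phages can
infect several related genera and a training label set may legitimately
carry more than one genus per phage.

Per-genus evaluation uses the confusion counts TP/TN/FP/FN over the test
set, with sensitivity TPR = TP/(TP+FN), specificity TNR = TN/(TN+FP),
informedness BM = TPR + TNR − 1, and accuracy (TP+TN)/total. Informedness
is the headline number: it is insensitive to the extreme class imbalance a
rare genus has in a multi-genus test set, where raw accuracy is close to 1
for a classifier that never fires. A ratio with a zero denominator is
reported as `NA` and propagates into BM — a genus with no positive test
phages has no measurable sensitivity, and pretending otherwise (0 or 1 by
convention) would silently mislead.

## Pipeline stages and their tunables

**Gene calling** (`find_orfs`). A deterministic six-frame maximal-ORF
scanner: in each frame an ORF runs from the first start codon
(`ATG`/`GTG`/`TTG`) after a stop (or the sequence start) to the next
in-frame stop; the stop codon is included in the coordinates and excluded
from the translation; leading `GTG`/`TTG` is rendered `M` (bacterial code,
translation table 11). `min_aa = 30` residues suppresses the spurious
micro-ORFs any random DNA contains while keeping real phage genes (which
are almost always longer) intact. Codons containing `N` cannot be
translated; they terminate the ORF at that point exactly as a stop would,
which preserves the coordinate arithmetic (`aa` length =
span/3 − 1). This scanner deliberately has no coding-potential model: the
clustering downstream only needs *consistent* gene products across phages,
not perfect gene boundaries, and a user can substitute externally
predicted proteins (`run_pipeline(..., proteins = )`, CLI stage swap) keyed
as `genomeid_serial`.

**Similarity graph** (`dedup_proteins`, `candidate_pairs`, `build_graph`).
Deduplication is greedy in descending length order at 95 % global-alignment
identity (matches / alignment columns), a standard redundancy cut that
leaves biologically distinct variants separate. All-against-all alignment
is avoided with a shared-k-mer prefilter (k = 4, ≥ 2 distinct shared
4-mers) — a recall-oriented superset of the seeding a local-alignment
search engine performs, cheap enough to be exact at package scale.
Candidate pairs are then aligned with an exact affine-gap Smith–Waterman
(BLOSUM62, gap open 11, extension 1, a gap of length L costing 11 + L;
residues outside the 20-letter alphabet score −4, the matrix's worst
case). Edge weights are raw scores normalized by the **smaller**
self-alignment score, clipped to [0, 1]: this normalization is symmetric,
equals 1 for identical sequences, and makes one threshold meaningful
across protein lengths. Edges need normalized similarity ≥ 0.4
(inclusive); the same threshold later decides whether a novel gene
"significantly matches" a cluster, keeping training and classification
consistent.

**Markov clustering** (`mcl`). The classic alternation of expansion
(matrix squaring) and inflation (elementwise power 2 with column
renormalization), pruning entries below 1e-5, until the largest
elementwise change falls below 1e-6 (cap 200 iterations, with a warning
and best-effort interpretation on non-convergence). Clusters are the
connected components of the converged flow's nonzero pattern, which is a
partition by construction and cannot merge disconnected components.
Inflation 2 is the reference implementation's default granularity; it is
exposed (`phagehost_config(inflation = )`) and recorded in the model file
because granularity is the one genuinely free knob of this clustering.
Clusters present in fewer than **1 %** of training phages (strict `<`) are
removed: such families cannot generalize and mostly inflate the feature
space.

**Features** (`build_feature_matrix`, `variance_threshold_filter`,
`vectorize_novel`). The count matrix keeps all-zero rows (a phage whose
genes all fell into discarded clusters is still a data point). The
variance filter binarizes each column to presence/absence *for the test
only* and drops columns present in more than 99 % or absent in more than
99 % of phages (strict `>`): near-constant columns cannot split any
tree node usefully. The prevalence filter and the variance filter
overlap for rare clusters; both are implemented and separately switchable
because they act on different objects (clusters vs. matrix columns) and
compose idempotently. A novel gene is aligned to cluster
*representatives* (longest member, ties to the smallest id) rather than
every member — deterministic and linear in the number of clusters — and
counts once toward its best-scoring candidate (ties to the smallest
cluster id), so row sums always equal the number of assigned genes.

**Trees** (`train_tree`, `train_suite`, `predict_hosts`). Plain CART with
Gini impurity, exhaustive split search over midpoints between consecutive
distinct values, and fixed tie-breaking (smallest feature id, then
smallest threshold) — training is fully deterministic. The stopping rule
is the impurity-split threshold: **only nodes with impurity strictly
greater than 0.03 are divided**; there is no depth or leaf-size limit.
Class weights are balanced by default (total positive weight = total
negative weight). This matters: a genus with, say, 17 positives among
thousands of training phages has unweighted root impurity ≈ 2p(1−p) < 0.03
and would never split at all, so the stated threshold is only coherent
together with balancing; an unweighted mode remains available by flag.
A node whose best split has zero impurity decrease may still be divided
(only constant-feature nodes are unsplittable): Gini decrease is zero for
XOR-structured labels at the first level, yet the standard CART libraries
resolve such nodes over two levels, and this package follows that
behavior. Leaves store their weighted positive fraction; prediction calls
a genus when the reached leaf's fraction strictly exceeds 0.5.

## The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` is first-class, tested code, not a throwaway fixture.
It emulates exactly the structure the method assumes: each genus carries
`markers_per_genus` private marker gene families (the host-specificity
signal), every phage additionally draws `background_genes_per_phage` genes
from a pool shared **across** genera (the non-informative families the
prevalence/variance filters and the trees must ignore), and every gene
copy receives per-nucleotide substitutions at `mutation_rate` (within-family
divergence). The defaults — 5 genera × 40 phages, 3 markers per genus of
50–150 residues, a 20-family background pool with 5 genes per phage,
mutation 0.02, seed 42 — are sized so the full pipeline runs end to end in
about a minute on one core while leaving each genus enough phages for a
meaningful 80/20 split; 2 % per-nucleotide noise yields roughly 90–95 %
amino-acid identity within a family, comfortably inside the similarity
threshold but far from trivial identity.

Two constructions keep the generator's ground truth exact rather than
approximate:

* **Insulators.** Every planted gene is flanked by a fixed 22-nt block
  containing stop codons in all three frames of both strands and no start
  codon on either strand, and the random spacers (20–60 nt plus the
  insulators) sit between these blocks. No ORF of scanner-minimum length
  can therefore extend across a gene boundary.
* **Stop scaffolds.** Within a gene, the five non-coding frames of random
  codon sequence frequently stay stop-free for 30+ codons, which would
  plant systematic "shadow ORFs" — reverse-strand or off-frame copies of a
  marker that cluster on their own and compete with the real marker
  cluster for tree roots. Family proteins therefore include a fixed
  4-residue motif (LTNY, codons `CTA-ACT-AAC-TAC`, which carries a stop in
  all five non-coding frames) every 17 residues, capping every off-frame
  stop-free run at ~21 codons — below the 30-residue ORF minimum even with
  the ≤ 3 codons of slack the insulator allows. Substitution noise is
  applied afterwards and never touches start/stop codons nor introduces
  in-frame stops, so a mutated copy can at worst open a *private* shadow
  ORF in a single phage, which the 1 % prevalence filter removes.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: realistic phage genome architecture (operons,
overlapping genes, tRNAs, terminal repeats), horizontal gene transfer
between genera, uneven genus sizes, annotation noise in host labels, and
genes whose similarity structure is mosaic rather than family-like. On
real corpora the ORF caller is also cruder than a trained gene finder; the
escape hatch for external protein predictions exists for exactly that
reason.

## Numerical choices and degenerate inputs

* Threshold boundaries follow the stated rules and are implemented
  count-wise with a 1e-9 slack so that binary floating-point
  representation cannot flip a boundary case: prevalence removal is strict
  `<` (a cluster in exactly 1 % of phages survives), presence removal is
  strict `>` (a column present in exactly 99 % survives), similarity edges
  are inclusive `≥`.
* All alignment scores are integers end to end; the C++ kernels and the
  brute-force R test oracle must agree exactly, not approximately.
* Ties are always broken deterministically (alphabetical genera, smallest
  feature id, smallest threshold, smallest cluster id, lexicographically
  smallest member id), so rerunning any stage with the same seed is
  byte-identical.
* Degenerate inputs fail loudly: empty FASTA, duplicate record ids,
  non-IUPAC characters (with position), label rows with the wrong column
  count (with line number), an empty train or test partition, a model file
  with a foreign schema version or truncated JSON, prediction vectors with
  mismatched columns, and an all-removed cluster set all raise errors
  rather than degrade.
* Empty-but-valid cases stay valid: a genome with no ORFs yields a zero
  vector; a genus with no positive training phages trains a
  constant-negative leaf with a warning; a protein matching no cluster is
  simply unassigned.

## Open design points, decided

* **Corpus split.** Plain random sampling by default (stratification by
  genus available but off), with the seed a required, recorded parameter;
  the train size is `round(fraction × n)` and stratified allocation uses
  the largest-remainder method so both the total and every stratum are
  exact to ±1.
* **Novel-gene membership.** A gene counts toward its single best-scoring
  cluster rather than every matching cluster; multi-membership would break
  the row-sum identity between vectors and assigned genes. A flag-free
  representative-first search keeps classification deterministic and fast;
  the similarity threshold is shared with training.
* **Deduplication threshold** 0.95 keeps the step a redundancy cut rather
  than a clustering; exact-duplicate-only behavior is available via
  threshold 1.
* **Aggregate accuracy** is Σ(TP+TN)/Σ(total) over genus rows, which
  equals the mean of per-genus accuracies when all rows share a total (the
  tests assert this identity numerically).

## Problem sizes used by the test suite

Unit tests run on a reduced corpus (3 genera × 8 phages, 2 markers per
genus, 6 background families) chosen to exercise every code path in
seconds; the end-to-end recovery checks and the acceptance script use the
full default study conditions above, twice (with and without mutation
noise). Alignment oracles compare 200 random peptide pairs of length ≤ 40;
the Markov clustering invariants run over 50 random weighted graphs of up
to 12 nodes plus the two-triangle and bridged-clique fixtures, with an
independent dense reference implementation as the cross-check.

## Known limitations

* Genus-level labels only; species- or strain-level host range is out of
  scope, as are taxonomy reconciliation of labels and corpus
  deduplication across source databases (input corpora are taken as
  non-redundant, labels as given).
* The similarity pipeline reproduces no E-value statistics; "significant
  similarity" is operationalized purely through the normalized-score
  threshold.
* Trees are single CART models by design — interpretability over raw
  accuracy; there is no ensembling, pruning, or probability calibration.
* The ORF caller reports all sufficiently long ORFs, including overlapping
  ones; on real genomes it will over-call relative to a trained gene
  finder, which inflates the background of rare clusters (mitigated by,
  and one of the reasons for, the prevalence filter).
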