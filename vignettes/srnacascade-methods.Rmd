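---
title: "Methods: tiered sRNA-seq read classification, hairpin filtering and biomarker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered sRNA-seq read classification, hairpin filtering and biomarker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnacascade)
```

# Overview

`srnacascade` is a scriptable engine for small RNA sequencing (sRNA-seq)
analysis. A sample's reads (15–32 nt inserts sequenced with a 3' adapter) are
preprocessed and then partitioned by a strict four-tier alignment cascade:

1. **Known transcripts** of the target organism (miRNA, piRNA, snoRNA,
   snRNA, rRNA, previously registered novel miRNAs, sRNA families), forward
   strand.
2. **Target genome**, both strands, feeding novel miRNA hairpin prediction.
3. **Pathogen genomes**, screened by canonical 18-mers with lowest common
   ancestor (LCA) resolution.
4. **Cross-species miRNA precursors** of non-target organisms, exact match.

A read consumed at one tier never reaches the next, so the tier assignment
is a partition: tier-1 through tier-4 counts plus unaligned reads always sum
to the preprocessed read count. For organisms without a supported genome, a
non-model mode aligns reads exactly against the stored known+novel miRNA and
family catalog only.

Downstream of the cascade the package provides the three modules described
below: novel miRNA filtering, a ranked pathogen report with an evaluation
harness, and a balanced random-forest biomarker module. A deterministic
synthetic-data generator produces every input with known per-read provenance;
all claims in the test suite are made against that ground truth.

# Preprocessing

Adapter trimming truncates a read at the *leftmost* position where a prefix
of the configured 3' adapter matches with at least 6 bases of overlap and at
most a 10% mismatch rate (Hamming, no indels). An empty adapter string means
"already trimmed" and passes reads through unchanged. Barcode removal (for
randomized-base library kits) clips `barcode_n` bases — default 0 — from
*both* ends of the adapter-clipped read; the published description of the
trimming step does not say from which end the extra bases are removed, and
clipping both ends matches the randomized-base library designs this option
exists for. Finally only reads of 15–32 nt are retained, the union of the two
alignment length bands. Quality strings are carried along but never used for
filtering. Reads with more than 10% N bases are dropped at parse time.

# The alignment model

Mismatch handling follows the length-band rule: reads of 15–19 nt align with
0 mismatches, reads of 20–32 nt with at most 1 mismatch; only Hamming
mismatches are considered (no indels), which is how short-read aligners in
`-v`-style mode behave in this length regime. N never matches any base,
including another N.

The aligner is a pigeonhole-seeded substring index: each query is split into
two halves, so that with at most one mismatch at least one half — and hence
its leading 7-mer — occurs exactly; candidate starts from a hashed 7-mer
table are then verified by full-length Hamming distance. The unit tests hold
this index to equality with a position-by-position brute-force scan and with
an independent string-matching library on both strands.

Tier 1 counts use a two-step rule: a mapped read's best-stratum (minimum
mismatch) hits are first restricted to the highest-priority sRNA class
present (miRNA > piRNA > snoRNA > snRNA > rRNA > novel miRNA > family), then
its unit weight is split equally among the remaining distinct transcripts.
This rule is deterministic and conservation-preserving (column sums never
exceed the number of tier-1 reads); it is this package's resolution of a
counting procedure that is not fully specified in the published description.

Tier 2 searches both genome strands. Reads with more than 5 best-stratum
loci are still consumed by tier 2 but are excluded from novel miRNA
prediction — the 5-locus cap exists to keep prediction to high-confidence
loci, not to reject the reads as sequence evidence.

# Novel miRNA prediction and the three-criterion filter

Prediction-eligible tier-2 hits are clustered per chromosome and strand by
single linkage with a 30 nt gap; clusters with fewer than 2 reads are
dropped. The modal read interval of a cluster is taken as the putative
mature; two 110 nt candidate precursor windows are excised
(`[mature_start - 15, mature_start + 95)` and
`[mature_end - 95, mature_end + 15)`, i.e. mature on the 5' or the 3' arm),
clipped to chromosome bounds and reverse-complemented on the minus strand.
The window size is a documented package choice; published precursor windows
for this kind of excision are of comparable size.

**Folding.** Windows are folded by Nussinov base-pair maximization
(Watson–Crick plus GU wobble, minimum loop length 3) rather than free-energy
minimization: the permutation-test logic of the structure criterion is
preserved while avoiding thermodynamic parameter tables, and the statistic
"number of base pairs" replaces the folding energy throughout. The traceback
prefers pairings over skips and scans partners outside-in, which keeps stems
contiguous and deterministic. An exhaustive enumeration over nested
structures verifies optimality for short sequences in the tests. One
consequence worth knowing: pair maximization pairs a large fraction of the
bases of even a *random* window, so the signal that separates a real
hairpin from background is the margin above that baseline, not the raw pair
count.

**Scoring.** Each candidate gets an explicit, deterministic 5-term score
standing in for a probabilistic hairpin log-odds score:

$$ s = 2\log_2(1 + n_\text{mature}) + 3\,[\text{star read present}]
 + 8\,\text{pairedness} + 5\,\text{precision} - 10\,[\text{mature overlaps loop}] $$

where *pairedness* is the fraction of mature bases paired in the stem,
*precision* the fraction of mature-arm reads sharing the modal 5' start
(mature miRNA reads have characteristically homogeneous 5' ends), and a star
read is a non-mature-overlapping cluster read whose 3' end lies 0–4 nt
beyond the pairing partner of the mature 5' end — the 3' overhang signature
of a Dicer duplex. The acceptance threshold of 10 (strict) is kept; an ideal
cluster (31 identical mature reads, one star read, fully paired mature)
scores $2\cdot5 + 3 + 8 + 5 = 26$.

**Structure significance.** The shuffle p-value is
$p = (1 + \#\{s: \text{pairs}(s) \ge \text{pairs}(\text{orig})\}) / (n+1)$
over $n = 99$ dinucleotide-preserving shuffles (Altschul–Erickson Euler-path
sampling, preserving the dinucleotide multiset and both end bases), giving a
floor of $p = 0.01$ — fine enough to resolve the inclusive $p \le 0.05$
criterion. Homopolymers are fixed points of the shuffle and score exactly
$p = 1$.

**Decoy similarity.** "Sequence similarity to tRNA/rRNA" is operationalized
as sharing at least one exact 20-mer with the decoy set on either strand;
the published criterion names no definition, and an exact-k-mer rule is
deterministic and scale-free.

A candidate is registered iff score > 10 **and** no decoy similarity
**and** shuffle p ≤ 0.05. At most one candidate — the best-scoring passing
window — is registered per cluster, because both excision windows of a
well-covered hairpin can pass and would otherwise register the same locus
twice. Accepted precursors are deduplicated against the catalog by precursor
sequence (read counts merged, no re-scoring), serials are assigned in
genomic order, and entries are named `<org>-oasis-mir-<serial>` with
`-5p`/`-3p` mature arms. The catalog is written as GFF3 (1-based inclusive;
internal coordinates are 0-based half-open) plus a TSV sidecar with
sequence, structure, score, p-value and software version.

# Pathogen screen

The panel index maps canonical 18-mers (lexicographic minimum of a k-mer and
its reverse complement; k-mers containing N skipped) to taxa; a k-mer found
in several genomes is stored at the LCA of its taxa. Reads are classified by
the maximal root-to-leaf path rule: hit k-mers are counted per taxonomy
node, each root-to-leaf path is scored by the sum over its nodes, and the
read is assigned to the deepest counted node on the best path, with path
ties resolved by LCA. No minimum hit count is imposed by default (a
`min_hits`-style gate can be emulated upstream); reads shorter than k are
unclassified.

The report attributes reads classified at or below species rank to their
species, tallies above-species classifications separately, ranks species by
read count (ties broken by name for determinism) and truncates to the top 5.
The evaluation harness computes precision, recall and F-score of the top-n
list against a truth set per dataset and averages over datasets (unweighted
mean — the published figure does not state its pooling rule).

# Biomarker module

Counts are normalized to counts-per-million and log2(x+1)-transformed;
all-zero features are dropped and a zero-count sample is a hard error.

**Balanced forest.** Every tree's bootstrap draws exactly m samples with
replacement from each class, m being the minority class size, so majority
classes cannot dominate votes under imbalance. The tree learner is the
standard `randomForest` implementation (its stratified `sampsize` option
realizes exactly this bootstrap, assertable per tree from the in-bag
matrix); the balanced-sampling contract, pruning schedule and evaluation are
package code. Out-of-bag (OOB) error is the fraction of samples misvoted by
trees that did not draw them.

**Cross-validated AUC.** Stratified k-fold with k = min(10, minority class
size) — leave-one-out would degenerate stratification. Held-out class
probabilities are pooled across folds and the AUC is the rank (Mann–Whitney)
statistic with ties counting one half; the tests pin it to a concordant-pair
count. One seed governs fold assignment and every fold's forest through
documented substreams, so results are bit-reproducible.

**Pruning.** Features are ranked once by full-model impurity (Gini)
importance, and nested top-k subsets of geometrically halving size (p,
⌈p/2⌉, …, 1) are each evaluated by cross-validated AUC; the best model is
the subset with maximal AUC, ties going to the smaller subset. This O(log p)
schedule is the package's resolution of an unspecified published routine;
since the full feature set is itself one of the evaluated subsets, the best
model can never be worse than the full model on the selection metric.
Binary classification only.

# The synthetic-data generator

The generator emulates the study conditions end to end and is a pure
function of (spec, seed):

* **Host**: a 20 kb random genome with 5 planted miRNA hairpins (26 bp stem,
  6–10 nt loop, 22 nt mature starting 3 nt into the stem) and 5 planted
  non-hairpin decoy read clusters; a transcript reference over the sRNA
  classes; tRNA/rRNA decoys; cross-species precursors. Planted hairpins
  carry 1–2 single-base bulges near the stem centre: a perfect stem is a
  palindrome whose arm reads map to both genome strands, splitting one locus
  into twin clusters. Hairpins are rejection-sampled until they fold to at
  least 20 pairs, share no 20-mer with the decoys, and their excision window
  reaches the shuffle-null floor (p ≤ 0.01 over 99 internal shuffles) — a
  "planted hairpin" that its own null cannot distinguish from background
  would not be a meaningful plant. Symmetrically, decoy cluster windows are
  re-randomized until clearly unstructured (both excision windows at p ≥
  0.3): a random window in the bottom 5% of its own shuffle null *is* a
  chance hairpin, not a negative control.
* **Pathogen panel**: 8 viral (5 kb) and 4 bacterial (10 kb) random genomes
  under a root/domain/genus/species taxonomy, with sibling species sharing a
  configurable sequence fraction (default 10%) to exercise the LCA rule.
* **Samples**: reads drawn from transcripts (tier-1 truth), hairpin arms
  (~Poisson(20) mature and ~Poisson(3) star reads each) and decoy clusters
  (tier-2), one designated pathogen (tier-3), cross-species precursors
  (tier-4), and uniform random sequence of 20–32 nt (unaligned; at those
  lengths chance alignments against the reference set have probability
  below 1e-5 per read). Per-base substitution errors at 1% by default; the
  3' adapter is appended and reads clipped to 50 nt so preprocessing is
  always exercised. With the error rate set to 0 every read is recovered at
  its provenance tier, and the tests assert exactly that.
* **Classification tables**: negative-binomial counts (dispersion 0.2, the
  usual overdispersion scale for sRNA-seq), optional log2-fold-change
  informative features, and a perfect-separator option forcing disjoint
  per-group ranges on one feature (6 vs 6 samples, 300 background features
  by default). A 22-vs-48 option mirrors a typical imbalanced case-control
  cohort.

What passing these tests does **not** show about real data: real sRNA-seq
has non-uniform base composition, expression-dependent error profiles,
isomiR 5'/3' heterogeneity, adapter chemistry artifacts and cross-mapping
between paralogous miRNA families; random genomes have no repeat structure,
so the 5-locus multimapper cap is exercised only by construction. The
pipeline's thresholds are the published defaults, not values fitted to these
fixtures.

# Numerical and design choices

* Internal coordinates 0-based half-open everywhere; conversion to 1-based
  inclusive happens only at the GFF3 boundary.
* U→T normalization on input, so RNA-space references and DNA genomes
  interoperate; every sequence handed between modules matches `^[ACGTN]+$`.
* Best-stratum hit reporting (1-mismatch hits only when no exact hit
  exists) prevents double counting and matches seed-and-extend defaults.
* Ranking ties (pathogen report: by name; pruning: smaller subset;
  traceback: outside-in pairing) are all broken deterministically, so a
  fixed seed reproduces byte-identical outputs.
* Problem sizes in the tests (20 kb genomes, ~1,000-read samples, 12-genome
  panels, 5 × 2,000-read infection samples, 10-seed sweeps) are chosen so
  the whole suite and the acceptance script each run in minutes on one CPU
  while still giving the binomial margins the pass criteria need.

# Known limitations

Hamming-only alignment (no indels); binary classification only; no isomiR
resolution; the Nussinov statistic ignores stacking energies, so the
structure p-value is conservative for GC-poor stems; per-sample novel miRNA
prediction with catalog-level deduplication, not cross-sample joint
prediction; the pathogen screen reports read-count ranks, not abundance
estimates.
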