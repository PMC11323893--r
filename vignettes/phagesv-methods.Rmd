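---
title: "Methods: consensus phage SV calling and genetic-exchange analysis"
author: "phagesv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus phage SV calling and genetic-exchange analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagesv)
```

# Scope and model

`phagesv` analyses structural variation (SV) in bacteriophage genomes at
cohort scale. Its inputs are the products of upstream tools — per-sample
VCF callsets from several long-read SV callers, phage and bacterial
genome FASTA, alignment hit tables, rooted gene trees, CRISPR spacer
libraries, taxonomy and abundance tables — and its outputs are a
nonredundant cohort SV catalog and the downstream biology: which SVs
look like phage–bacteria genetic exchange, in which direction genes have
moved, which bacteria host which phages, and how SV load differs between
phage lifestyles.

Four SV types are handled: insertions (INS), deletions (DEL),
duplications (DUP) and inversions (INV), all longer than 50 bp.
Coordinates are 0-based half-open internally; VCF POS (1-based) is
converted only at the I/O boundary. An insertion's effective end is
defined as its start plus its length, which lets all four types share
one interval algebra during merging.

# Consensus merging (CAST)

The core computation merges multi-caller callsets in two stages.

**Within a sample.** Records are partitioned by contig and SV type and
split into positional overlap groups (connected components of the
"overlaps by ≥ 1 bp" relation). Within a group, two SVs are connected
when their mutual (reciprocal) overlap — intersection length divided by
the longer SV's length — is at least 0.8. Because callers miss edges,
this graph is a *corrupted clique* graph, and we partition it with the
Cluster Affinity Search Technique (CAST): open a cluster with the
maximum-degree unassigned node, repeatedly add the unassigned node of
highest affinity (edge count into the cluster) while its affinity is at
least $t\,|C|$, then remove any member whose affinity falls below that
bound, and close the cluster when stable. We use the canonical
$t = 0.5$; the value is exposed in `merge_params()`.

Three numerical choices deserve note:

* **Determinism.** All ties (seed choice, add/remove order,
  representative election) break by smaller start, then shorter length,
  then caller-priority rank, then record id. The partition is therefore
  invariant to input record order, which the tests assert.
* **Oscillation.** The add/remove loop of CAST can cycle on
  unfavourable graphs (e.g. a star: a peripheral node is added, the
  cluster grows, the node's relative affinity drops below $t|C|$, it is
  removed, re-qualifies, and so on). We close the cluster at the first
  recurrence of a membership state, which is deterministic, terminates
  on every finite graph, and leaves well-behaved graphs untouched.
* **Filters on the representative.** A cluster is reported only when at
  least two distinct callers contributed, and its representative — the
  member from the highest-priority caller present (Sniffles, then
  cuteSV, pbsv, SVIM, reflecting their relative benchmark performance) —
  has read support ≥ 2, length > 50 bp, and lies ≥ 100 bp from both
  contig ends. Filtering on the representative rather than on every
  member is a deliberate choice: the representative *is* the reported
  SV, and member-level jitter should not veto an otherwise
  well-supported cluster.

**Across samples.** Per-sample representatives are pooled and the same
grouping + CAST machinery is applied. Each cross-sample cluster is
reduced to its most *prevalent* member: the record whose interval recurs
(reciprocal overlap ≥ 0.8) in the largest number of distinct samples.
The result is the nonredundant SV set, annotated with a per-sample
presence matrix. Re-merging the nonredundant set is a fixed point.

INS records are merged on position and length only; inserted-sequence
similarity is not compared. This matches the positional semantics of the
merging rule and avoids an alignment dependency.

# Reference prefiltering (MinHash/Mash)

Before calling, each sample is restricted to catalog genomes within
Mash distance 0.10 of the sample — the sketch-based analogue of
requiring about 0.90 sequence identity, since the Mash distance
approximates one minus identity. Sketches are bottom-$s$ MinHash sets
over canonical k-mers (k = 21, s = 1000, the conventional genomic
defaults) with a fixed, versioned 64-bit hash, so sketches are portable
across runs. The distance is
$d = -\tfrac{1}{k}\ln\tfrac{2j}{1+j}$ with $j$ the Jaccard index
estimated from the merged bottom-$s$ sketch; $j = 0$ is capped at
$d = 1$. At these parameters the sketch distance tracks the exact
canonical-k-mer Jaccard distance within 0.02 on 10–100 kb sequences at
0–10% divergence, which the test suite verifies against a string-based
oracle. The pipeline sketches whatever FASTA it is given per sample
constituent; read-level sketching is out of scope.

# Benchmarking

Callsets are compared to a truth set by greedy one-to-one matching:
a truth record and a call are eligible when they share contig and type,
their starts differ by ≤ 500 bp, and their size ratio is ≥ 0.7;
eligible pairs match in order of ascending start distance (ties by
length difference, then ids). Greedy matching is transparent and, on the
well-separated implants the simulator produces, attains the maximum
bipartite matching — asserted against an augmenting-path oracle. Note
that one-to-one accounting counts a duplicate consensus record of a real
event as a false positive; `calls_with_truth_support()` provides the
complementary many-to-one view, which is the right notion when asking
whether caller-private false positives leaked through the merge.
Precision, recall and F1 follow the usual definitions with zero
denominators mapped to 0.

# Genetic-exchange (GE-like) classification

An SV longer than 200 bp whose sequence aligns to a bacterial genome at
more than 80% identity over more than 80% of the SV length is GE-like;
shorter SVs are not assessed. Coverage is computed on the SV length, not
the subject span, because the question is how much of the exchanged
sequence is bacterial. SVs whose sequence also aligns to a predicted
prophage region at 80% identity and 50% coverage are flagged, since
phage-on-prophage homology is not evidence of exchange. The interaction
range of a GE-like SV is the taxonomic rank of the last common ancestor
of all bacterial genomes it matches — species when they agree at
species, genus when they diverge below genus, and so on.

# HT index (codon-neighbour typicality)

To score whether a gene's composition is native to its genome, a
first-order Markov chain over the 64 codons is trained on all the
genome's genes: adjacent in-frame codon pairs are pooled, Laplace-
smoothed (pseudocount 1) and row-normalised. A gene of $L$ codons then
scores

$$\mathrm{HT} = \frac{1}{L-1}\sum_{i=1}^{L-1}\log_2 P(c_{i+1}\mid c_i),$$

the mean per-transition log-probability. Genes with codon-neighbour
usage typical of the genome score high; horizontally acquired genes
score low. Under a uniform model every gene scores exactly
$\log_2(1/64) = -6$, a useful calibration point. The index is defined
here as a mean rather than a raw log-likelihood so that genes of
different lengths are comparable. Training includes the query gene by
default (leave-one-out is a flag-level change), and the score is
invariant to the order of the training corpus.

# HGT directionality from tree topology

Given a rooted gene tree whose leaves are labelled bacterial or viral,
a horizontal transfer is read from nesting: a maximal clade of one
kingdom whose sibling leaves (under its parent's other children) and
aunt leaves (under its grandparent's other children) all belong to the
other kingdom. Bacterial leaves nested in a viral context give a
phage-to-bacteria event and vice versa. Requiring *both* sibling and
aunt purity is the conservative reading of "nested": a clade merely
adjacent to the other kingdom does not qualify. Events are counted per
maximal nested clade; a per-leaf counting mode is available because the
two conventions differ when a transferred clade has several leaves.
Node support can gate events (`min_support`); the default 0 imposes no
filter.

# CRISPR spacer host prediction

Spacers are matched against phage genomes as full-length, gap-free
windows with at most two substitutions, on both strands; `N` never
matches. For spacers of 41 bp and longer the full-length ≤ 2-mismatch
rule automatically enforces > 95% identity; for shorter spacers the
per-hit mismatch count is reported so a caller can tighten it. This
substitution-only rule replaces a short-read aligner with a single
auditable criterion; the implementation is verified against a
brute-force two-strand Hamming scan on a thousand random fixtures.

# Cohort statistics

SV density is SVs per megabase of genome. A gene lies in an SV region
when its interval intersects a DEL/DUP/INV by ≥ 1 bp or contains an INS
breakpoint (half-open conventions throughout, property-tested against a
per-base oracle). Functional enrichment uses a one-sided Fisher's exact
test per level-2 category (over-representation among SV-region genes)
with Benjamini–Hochberg FDR across the categories of one run; runs
(e.g. per SV type) are not pooled. Lifestyle comparisons use the
two-sided Mann–Whitney U test, exact when the combined sample is ≤ 20
without ties, normal approximation with tie correction otherwise. The
enrichment background is all genes of genomes carrying at least one SV;
this choice is configurable by subsetting the gene table. The sharing
network has one edge per (phage, bacterial genus) pair weighted by the
number of GE-like SVs linking them — genus because abundance profiles
aggregate naturally at that rank — and edges are annotated with the
Pearson correlation of the pair's abundance rows across samples.

# The synthetic cohort

`simulate_cohort()` generates every input with known truth. Its defaults
define the study conditions the acceptance checks run under: 50
reference phage genomes of 30–60 kb at GC 0.45 (typical gut-phage
scale), 400 implanted truth SVs (150 INS, 150 DEL, 50 DUP, 50 INV — the
3:3:1:1 type ratio of the benchmarking design) of 100–1000 bp, five
samples, and four simulated callers each with Gaussian start jitter
(sd 10 bp), 5% multiplicative length jitter, a 10% miss rate, two
caller-private false positives per genome (Poisson), and shifted-Poisson
read support with mean 8. Forty of the long insertions carry segments
copied from 20 simulated bacterial genomes at 5% substitution — the
ground truth for GE-like classification — and the emitted hit table is
truth-exact (identity = 100 × one minus the realised substitution
fraction), standing in for an external aligner so the package needs no
alignment dependency. Gene trees (100 per cohort, 12 background leaves,
one planted cross-kingdom clade) are built by grafting an
opposite-kingdom clade as the new sibling of a background leaf, with at
most one graft per parent so planted events cannot mask each other.
The spacer library plants 30 spacers of 32 bp with exactly one
substitution plus 10 decoys verified to have no ≤ 2-mismatch window
anywhere. Abundances are lognormal (σ = 0.5 on the log scale) across 91
samples with exchange pairs coupled through a shared latent Gaussian at
ρ = 0.8; note that exponentiation attenuates the Pearson correlation on
the abundance scale (to ≈ 0.78 at these parameters), which is why σ is
kept moderate. Temperate phages (half the catalog) receive twice the SV
load of virulent ones, giving the lifestyle comparison a planted signal.

What the simulator does *not* emulate: read-level error and coverage
structure (callsets are synthesised directly from truth), caller
breakpoint biases beyond Gaussian jitter, repeat-induced false
positives, real codon usage, and real taxonomic structure. Passing
tests on this cohort therefore demonstrate the correctness of the
algorithms under controlled noise, not caller behaviour on real
long-read data.

# Problem sizes and reproducibility

Every generator is a pure function of its seed; the cohort driver
derives per-stage seeds from one master seed, so a cohort is fully
reproducible from a single integer. The shipped test suite and the
acceptance script use the default cohort (50 genomes × 5 samples, 400
SVs), 200 random graphs for the clustering oracle, 50 genome pairs for
the sketch-accuracy bound, 100 trees per direction-recovery check and
1000 random spacer fixtures — sizes chosen so the whole suite runs in a
few minutes on one CPU while keeping every statistical band (binomial,
Poisson, Fisher-z) comfortably away from its boundary.

# Known limitations

* Breakends, translocations and genotypes are out of scope; so is
  running the upstream callers.
* The GE-like rule depends on the supplied hit table; the package does
  not compute alignments (the simulator's truth-exact hit table stands
  in for an aligner on synthetic data).
* Greedy truth matching can in principle fall short of the maximum
  matching on adversarially dense callsets; the tests compare the two
  and the shipped conditions attain equality.
* CAST with binary affinities is order-of-magnitude faster than exact
  corrupted-clique recovery but is a heuristic; the state-recurrence
  stopping rule makes it deterministic, not optimal.
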