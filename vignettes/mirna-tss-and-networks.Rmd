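---
title: "Methods: miRNA TSS prediction, coTFBS statistics and network expansion"
author: "mirRegNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA TSS prediction, coTFBS statistics and network expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices made where reasonable alternatives existed. Nothing stated here as
an empirical result goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

# The TSS classification model

## Assumptions

The model rests on the observation that plant miRNA genes are
predominantly class II genes, transcribed by RNA polymerase II under the
same chromatin regime as protein-coding genes. It therefore assumes that

* active TSSs carry locally enriched H3K4me3 and H3K9ac, locally depleted
  nucleosome H3, and a pile-up of 5'-cDNA TSS tags;
* the five core promoter motif classes (Y patch, Inr, CA, GA, REG)
  concentrate within roughly a hundred bases of the TSS;
* verified unique TSSs of protein-coding genes are a valid positive
  training class for miRNA TSSs.

These are assumptions about shared transcriptional machinery, not about
miRNAs specifically; if a genome's miRNA promoters behaved differently from
coding-gene promoters, the transfer would silently degrade.

## Feature representation

Every anchor position is described by binned sums of each evidence type
over a window of ±`span` bases, `binSize`-base bins, ordered 5'→3' with
respect to the anchor strand (minus-strand anchors mirror the bin order);
the anchor base starts the first downstream bin. Defaults are
`span = 1000`, `binSize = 200`, i.e. 10 bins per feature and 90 inputs for
the full feature set (4 tracks + 5 motif classes). The compact ±1 kb
window describes the candidate position itself; the wider ±5 kb, 200-bp
geometry is reserved for meta-profiles, where the cumulative (summed, not
averaged) profile over many anchors is the quantity of interest. The bin
statistic is the **sum** so that profiles remain additive: the meta-profile
of a union of anchor sets is the element-wise sum of the parts, a property
the tests exercise directly.

Feature blocks are concatenated in a fixed canonical order (tracks, then
motif classes, then custom features alphabetically), so a feature set given
in any order produces the same vector. Before classification every column
is z-scaled with the training mean and standard deviation; both vectors are
stored in the model and re-applied verbatim at prediction time. Scaling is
needed because track totals and motif counts live on very different scales
and the RBF kernel is distance-based.

## Classifier, negatives, and validation

The classifier contract is "anything with a monotone decision score";
the shipped implementation is a soft-margin SVM with RBF kernel,
`cost = 1`, `gamma = 1/n_features` (`e1071::svm`), trained on z-scaled
vectors with a fixed seed. Decision values are oriented at training time so
that larger always means more TSS-like.

No negative-set recipe accompanies the verified TSSs, so the package
samples its own: uniform random genomic positions at least 1 kb (default)
from every positive, matched 1:1 in count, strands assigned at random.
Distance-matched random background is the standard choice for this kind of
binary promoter model and every piece of it is configurable
(`sampleNegatives()`).

Validation is stratified k-fold cross-validation (default 5). Fold
assignment happens after ordering samples by id, so storage order cannot
change the folds — permuting the training set leaves the metrics
identical, which is asserted in the tests. Reported metrics are
sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP) and
accuracy (TP+TN)/total, per fold and as fold means. Feature-combination
selection (`selectFeatures()`) evaluates arbitrary candidate subsets by the
same CV and picks the subset maximizing mean accuracy, breaking ties
toward fewer features and then lexicographically; the original study's
exact 22 combinations are not reproduced in its text, so the package
deliberately exposes arbitrary subsets instead of guessing.

## Scanning and candidate reporting

The upstream window of each precursor is 10 kb, strand-aware (upstream of
the start for `+` loci, of the end for `-` loci), clipped at contig
boundaries rather than erroring. The scan scores every 20th position
(default); 20 bp is well below the 200-bp bin width, so finer steps buy
little. Candidate lists are produced by greedy non-maximum suppression
with a 200-bp exclusion radius (one bin), keeping at most `topK = 10`
candidates ranked by decreasing decision value; exact ties resolve toward
the position closer to the precursor 5' end, a weak proximal-promoter
prior. Intragenic miRNAs — precursor embedded on the same strand of an
annotated gene — are represented by their host gene's recorded TSS
(`resolveIntragenic()`), tagged `host_gene`. EST starts and conservation
blocks, when supplied, are report-only overlays (overlap within ±100 bp),
never classifier features: they are supporting evidence in the output, not
part of the trained model.

# Coexpression groups

Correlation is Pearson by default (Spearman available), computed on
condition-aligned matrices; the package requires identical condition
labels rather than guessing an alignment between heterogeneous expression
compendia. Genes join a miRNA's group when |corr| ≥ 0.9 (default); the
sign is retained in the output since co-regulation can be activating or
repressive, and downstream filters can restrict. A high threshold can
leave a degenerate group, so groups smaller than `minGenes = 10` are
relaxed to the top-`minGenes` genes by |corr| and flagged. Zero-variance
entities are excluded (with a warning) under z-score normalization;
quantile normalization delegates to limma; control-gene normalization
divides each condition by the control's value, the classical
internal-control convention.

# Match-style PWM scanning and the coTFBS statistic

Scoring uses information weights `I(i) = Σ_b f(i,b)·ln(4 f(i,b))`
(0·ln 0 = 0), the matrix similarity score
`MSS = (Current − Min)/(Max − Min)` and the core similarity score — the
same ratio over the 5 consecutive positions of maximal summed information,
leftmost on ties. Ambiguous bases contribute the column minimum, the
conservative choice. Columns containing an exact zero receive a 0.01
pseudocount before normalization so the information weights stay finite. A
PWM that is uniform everywhere has zero information; its score is defined
as 0 with a warning rather than 0/0. Hits require CSS ≥ 0.75 **and**
MSS ≥ 0.85 (defaults mirroring common false-positive-minimizing Match
profiles; both configurable), on either strand; minus-strand hits are
reported at forward coordinates, and the tests assert that the minus-strand
hit set equals the forward-strand hit set of the reverse-complemented
promoter exactly.

The coTFBS counts feeding the hypergeometric test are
**promoter-presence** counts: each (promoter, PWM) pair contributes 0 or 1,
making the urn draws exchangeable and guaranteeing k ≤ n. `N` and `K`
count detections over *all* coexpressed groups in the run (which is why the
statistic refuses to run on fewer than two groups), `n` and `k` within the
group of interest. The reported p-value is the upper tail P(X ≥ k),
computed through `phyper(k − 1, …, lower.tail = FALSE)` — the printed
point-mass formula alone cannot measure over-representation, and the
stable log-space tail is what the formula's own cited machinery provides.
The point mass stays available. The candidate filter is strict on both
sides: frequency > 0.5 and p < 0.1; a frequency of exactly 0.5 or a p of
exactly 0.1 is excluded. The group frequency is computed over the union of
the miRNA's own promoter and its coexpressed genes' promoters; a flag
could restrict it to genes only, but co-occurrence *including* the miRNA
promoter is what makes a motif a shared regulatory signature.

# Targets, DFS expansion, GO enrichment, networks

Direct miRNA–target interactions are ingested as verified or putative,
annotated with the Pearson correlation of the two expression profiles;
missing expression is a flagged value, never an error, because an
interaction's existence does not depend on the compendium. Duplicate
(miRNA, target) pairs merge, verified evidence dominating putative.

Indirect targets are the genes reachable from any direct target through
directed gene–gene edges, computed by an iterative-safe DFS that visits
children in lexicographic order (determinism), visits every node once
(cycles and self-loops terminate), and records depth and tree edges — the
spanning forest. Undirected interaction input can be expanded to both
directions, flagged. Expansion depth is unbounded by default; a display
depth limit is a presentation concern, not a semantic one. The tests
compare the reachable sets against an independent transitive-closure
oracle on hundreds of random digraphs.

GO enrichment reuses the identical hypergeometric implementation (one
shared code path, asserted by a test) with the background defaulting to
all genes bearing at least one annotation; Benjamini–Hochberg adjustment
is available but off by default, the raw hypergeometric p being the
conventional report here. Networks are typed (TF, miRNA, direct target,
indirect target) with provenance on every edge, and export to SIF
(`regulates`/`targets`/`interacts`), GraphML (round-trips exactly,
including attributes) and Cytoscape JSON.

# The synthetic-data generator

The generator emulates the full input universe with planted truth:

* **Genome and annotations** — uniform-composition chromosomes (2 × 300 kb
  by default), 20 pre-miRNAs placed with ≥ 14 kb spacing so that no true
  TSS falls inside a neighbor's scan window, true TSSs 500–3000 bp
  upstream of the precursor 5' end, 15% of miRNAs intragenic inside
  dedicated host genes whose TSS is the miRNA's true TSS; 500 genes, of
  which 150 carry a unique verified TSS record on a spaced grid kept out
  of all miRNA scan windows.
* **Signal** — Gaussian intensity bumps at every true TSS (tags: height 30,
  sd 50 bp; H3K4me3: 20/300; H3K9ac: 15/200) and a floored baseline-minus-
  bump for H3 (8 − 7.5, sd 150), with per-base Poisson draws mimicking
  read-count coverage (`trackNoise = "none"` gives the deterministic
  limit). Motif sites appear at an elevated rate within ±100 bp of TSSs
  and at 5·10⁻⁴ per base elsewhere.
* **Regulatory layer** — one sharp 10-mer PWM per planted TF (dominant
  frequency 0.91) plus decoys; each TF's consensus is inserted into 80% of
  its group's promoters *in the genome itself*, so promoters extracted
  from predicted TSSs carry the signal; 5% cross- and decoy-insertion
  rates provide background.
* **Expression** — 11 conditions; each coexpression block (20 genes per
  planted group) shares its miRNA's latent profile plus Gaussian noise
  (sd 0.1); planted targets get the negated profile plus noise (sd 0.05);
  all other entities are independent standard normals.
* **Downstream** — guaranteed 3-gene chains from each of 3 direct targets
  per group miRNA inside an Erdős–Rényi digraph (p = 0.03, occasional
  self-loops), and one planted GO term covering 90% of the first miRNA's
  mediated gene set against 20 background terms at a 5% annotation rate.

Every stage draws from its own seed derived from the single configuration
seed, so runs are byte-identical and stages are independently
reproducible.

**What passing tests do and do not show.** The generator's bumps are clean,
isolated, and strong relative to Poisson noise; real chromatin data have
correlated noise, copy-number and mappability artifacts, overlapping genes,
and TSS clusters. Recovery of planted structure therefore demonstrates
correctness of the machinery — feature extraction, training, scanning,
scoring, counting, statistics — not expected field performance on real
tissue data. Likewise the uniform base composition makes motif background
statistics simplest-case; GC-skewed genomes will yield more background
hits at the same thresholds.

# Numerical and representational choices

* **Coordinates** are 1-based closed `GRanges` throughout — the native
  convention of the GenomicRanges stack the package is built on; BED and
  bedGraph conversion happens inside rtracklayer on read/write, so no
  hand-written off-by-one conversion exists anywhere in the code.
* Overlapping bedGraph records **sum** (coverage semantics, not
  last-wins).
* The organelle exclusion for TSS training is a configurable seqid
  blacklist defaulting to `ChrC`, `ChrM`, `Pt`, `Mt`.
* The hypergeometric tail is computed in log-space by `phyper`; tests
  verify agreement with exact rational arithmetic to 10⁻¹² for all valid
  tuples with N ≤ 20 and unit support mass up to N = 60.
* z-scaling guards zero-variance columns by substituting a unit scale.
* Degenerate inputs resolve to warnings plus well-defined values wherever
  a value exists (clipped windows, truncated promoters, empty groups,
  empty networks) and to errors where none does (empty upstream space,
  inconsistent hypergeometric counts, layout mismatches).
* Trained models serialize via RDS with layout, scaling, hyperparameters
  and seed inside; a model applied to vectors with a different layout
  fails loudly.

# Problem sizes

The test suite and acceptance script run entirely on generated data: the
full generator defaults (600 kb genome, 20 miRNAs, ~300 training vectors,
~10,000 scanned positions) for the recovery checks; 20 seeded simulations
each for the coTFBS and GO recovery rates; 200 random digraphs for the
reachability oracle; exhaustive hypergeometric sweeps to N = 60. These
sizes were chosen as the smallest at which the planted-recovery statistics
are stable.

# Known limitations

* Real-data performance depends on inputs the package does not produce:
  read mapping, coverage normalization between ChIP libraries, and the
  alignment of heterogeneous expression compendia are upstream of its
  interfaces.
* The SVM is the only shipped classifier; the contract admits others, but
  no gradient-boosted or deep alternative is bundled.
* TRANSFAC matrices are licensed and not shipped; the package reads
  JASPAR-style and plain TSV matrices.
* GO enrichment expects ancestor-propagated annotations; no ontology
  traversal is performed internally.
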