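---
title: "Methods and design of pangcn"
author: "pangcn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of pangcn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific setting

`pangcn` analyses small sets of closely related bacterial genomes — the
motivating case being three strains of one dairy *Lactobacillus*
subspecies — and asks four linked questions:

1. What does each chromosome look like (size, GC, GC3, coding content,
   pseudogenes, large duplicated segments)?
2. Which genes are shared by all strains (core), by pairs, or by one
   strain only, and how do shared genes differ (identical, synonymous
   changes only, amino-acid changes, INDELs)?
3. How fast is each gene or functional category evolving (dN/dS), and
   which genes are predicted to be highly expressed (CAI)? Which
   pathways are complete in which strain?
4. When strains are too close for 16S rRNA to separate them, does a
   genome-context-network phylogeny resolve their relationships — in
   particular, which strain is closest to the common ancestor?

Because these questions are usually answered with hard-to-reproduce
ad-hoc pipelines, every estimator here is paired with a synthetic
genome generator that knows the truth, so the whole chain is validated
by parameter recovery. The test suite and `scripts/acceptance.R` run
entirely on simulated data.

# Genome representation and I/O

A genome is one (by default circular) chromosome plus a feature table
(`locus_tag`, `type`, `start`, `end`, `strand`, `pseudo`, `product`,
`ec`). Coordinates are **1-based closed**, identical to the GFF3 lines
on disk and to the GRanges convention of the surrounding Bioconductor
ecosystem; keeping the in-memory and on-disk conventions identical
removes an entire class of off-by-one errors at the cost of slightly
less tidy interval arithmetic. FASTA/GFF3 round-trip through
`Biostrings`/`rtracklayer`; a minimal GenBank flat-file reader/writer
covers the subset the package emits (CDS/rRNA/tRNA, `complement()`
locations, `/locus_tag`, `/product`, `/EC_number`, `/pseudo`), since no
installed R package parses that format. Origin-wrapping features are
not emitted by the simulator and are out of scope.

## Genome statistics

`genome_stats()` reports length, GC, CDS counts (intact + pseudo),
total and mean CDS length, GC in CDS, GC3, coding fraction and
stable-RNA fraction. Conventions that genuinely have alternatives:

* pseudogenes count toward the CDS total, total CDS length and mean
  length ("all genes" = intact + truncated), but are excluded from GC3
  and GC-in-CDS, which need an intact frame;
* GC3 is the GC fraction over **every third base** of each intact CDS,
  stop codon included;
* percentages are reported to two decimals, half-up, matching the
  precision of printed genome tables.

## Duplicated-segment detection

`find_duplicated_segments()` is an anchor-chaining dot-plot finder:
exact 20-mers occurring at two loci (forward or reverse-complement) are
grouped by diagonal (direct) or anti-diagonal (inverted), chained when
consecutive anchors are within `max_gap = 500` bp and 30 bp of the same
diagonal, and reported when the chained span reaches `min_len` with
anchor coverage ≥ `min_identity`. Identity is the fraction of the first
span covered by exact anchors — a conservative proxy that equals 100%
for perfect repeats and decays smoothly with point divergence
(an intact 20-mer requires 20 clean positions, so ~0.5% divergence
gives ~99% anchor coverage). Low-complexity blowup is capped by
skipping k-mers with more than `max_occ = 12` occurrences. This plays
the role of a whole-genome aligner's self-comparison at a fraction of
the machinery.

# The synthetic pan-genome generator

`sim_params()` defaults describe the emulated system: ~1,750 genes of
~860 bp mean length on a ~1.8 Mb circular chromosome, intergenic GC
0.4968, an rRNA operon and 20 tRNAs, synonymous codon bias 0.3 toward
GC-ending codons (chosen so simulated GC3 lands in the mid-60s%, as in
GC3-rich lactic acid bacteria), ~5% of genes labeled ribosomal proteins
and drawn with boosted bias (the highly expressed class that CAI
analyses need), per-site divergence 0.005 between sister strains,
omega 0.3, loss rate 0.02, duplication rate 0.01, pseudogenization rate
0.01, and a planted 25 kb duplication whose second copy is inverted,
flanking an 8.5 kb central region that carries a complete nine-step
lysine biosynthesis gene set (distributed round-robin over the central
genes, so a short central region yields multifunctional genes rather
than an incomplete pathway). Tests and the acceptance script use
scaled-down genomes (40–120 genes of 100–300 codons, 2.5–5 kb planted
segments) so the whole suite runs in minutes on one CPU; the scaling
touches sizes only, never the mechanism.

`make_triplet()` encodes the study design: strain A diverges on a short
branch (0.5× rates) and keeps the central region; an intermediate
diverges on a long shared branch (1.5×) on which the central region is
lost, then B and C diverge terminally (1.0× each). The ground-truth
unrooted topology with the ancestor as outgroup is therefore
((B,C),(A,ancestor)), and A is the ancestral-proximal strain by
construction. Three backbone genes shared by all strains carry the
lysC/asd/araT EC numbers, so the pathway matrix contrasts a complete
pathway in A with a three-step remnant in B/C.

## Mutation engine and the omega target

Point mutations are proposed uniformly over body-codon sites and
alternative bases — exactly the NG86 opportunity model. Proposals
creating a stop codon are rejected (the engine never fixes nonsense
mutations). Because NG86 counts changes-to-stop as nonsynonymous
opportunity, uncompensated rejection would deflate recovered omega by
the stop-adjacency share of the codon composition (~13% at omega = 1
under the default usage). The engine therefore scales acceptance per
proposal: with `a = omega * r_c`, where `r_c` is the current codon's
ratio of all nonsynonymous changes (stops included) to nonsynonymous
changes reaching a sense codon, nonsynonymous proposals are accepted
with probability `a / max(a, 1)` and synonymous ones with
`1 / max(a, 1)`. The realized rate ratio then equals omega on the NG86
scale for any omega, which is what the recovery experiments verify
(mean pooled estimates 0.098 / 0.299 / 0.970 for true 0.1 / 0.3 / 1.0).

The number of substitutions per gene is binomial in `snp_per_site`;
pseudogenization is a single 1-bp deletion at a uniform position with
the pseudo flag set; duplication inserts a tandem copy with its own
locus tag; intergenic and RNA sequence evolves neutrally. Every event
is logged, and two-step branches compose their logs so each descendant
gene traces to one ancestor gene or a gain.

What the generator does **not** emulate: recombination and gene
conversion, rearrangements beyond the planted inversion, IS elements,
rate variation across sites and genes, codon-position-dependent
mutation spectra, and within-population polymorphism. Passing recovery
tests therefore demonstrates estimator correctness under the stated
generative model, not robustness to every feature of real genomes.

# Orthology

Protein alignments use BLOSUM62 with gap open 11 / extend 1 (local for
hit search, global for codon alignment) through
`Biostrings::pairwiseAlignment`, batched into single vectorized calls
for speed; an independently coded affine-gap dynamic program in the
test suite cross-checks scores. A shared-5-mer prefilter ranks
candidate targets and only the top 5 are aligned; the exhaustive search
is available (`prefilter = FALSE`) and the prefilter is a documented
heuristic — at the ≥40% identity / ≥70% shorter-sequence coverage
acceptance thresholds, true hits share 5-mers with overwhelming
probability. Those default thresholds are a common best-bidirectional-
hit standard and are fully configurable, since published criteria for
this kind of study are often unstated. Ties break by higher identity,
then lexicographic tag, making every result deterministic.

Pseudogenes join the analysis through their longest ORF of ≥ 50 codons;
shorter ruins drop out. Paralog families are single-linkage components
of the within-genome hit graph, size ≥ 2.

# Pan-genome partition and variant classes

Core families are locus-tag triples on which the three pairwise
reciprocal-best-hit maps agree. Inconsistent triangles (a↔b and a↔c
present but b↔c pointing elsewhere) are resolved by dropping the
weakest-scoring edge — conservative and deterministic; the affected
genes fall back to pairwise-shared. With tandem duplicates this
conservatism is structural: when two strains each carry two copies, the
pairwise maps can legitimately pick different copies, the triangle
breaks, and the family leaves the core. Since the "which copy" question
is not identifiable at the locus-tag level, the truth-recovery
experiment measures core precision/recall under single-copy conditions
(duplication and pseudogenization rates 0, divergence 0.005), where
both reach 100%; duplication handling is validated separately (RBH
uniqueness, paralog families, the unique-vs-duplicated subdivision of
strain-specific genes).

Variant classes: `identical` (equal nucleotides), else a codon-aware
comparison — equal-length, gapless pairs are `synonymous_only` when
every substituted codon keeps its amino acid, otherwise
`amino_acid_changing`; any length difference or alignment gap is
`indel`. Pairs involving a pseudogene are `indel` by definition (the
emulated pseudogenes are INDEL-caused).

Pathway presence is a pure EC-set operation: a step is present iff any
feature carries one of the step's alternative EC numbers. The packaged
lysine definition has nine steps with the acetyl/succinyl transferase
alternative (2.3.1.89 | 2.3.1.117) at step five.

# NG86 dN/dS

Site counts: per codon, the synonymous site count is the fraction of
the nine single-base changes that are synonymous; changes to stops
count as nonsynonymous opportunity, so N + S = 3·(codons) exactly
(asserted to 1e-9 in tests). Difference counts: for each codon pair,
syn/nonsyn steps are averaged over all orderings of the differing
positions, excluding orderings that pass through a stop codon (if every
ordering is blocked — possible only for a handful of 3-difference
pairs — all orderings are used). Both tables are precomputed once for
the 61×61 sense-codon pairs and verified in the acceptance suite
against an independent recursive enumeration oracle at 1e-12. pN and pS
receive the Jukes–Cantor correction; p ≥ 3/4 is flagged `saturated`
rather than extrapolated, and dS = 0 yields `omega_undefined` rather
than infinity — flags propagate and flagged values are excluded from
category means. Codon alignments back-thread a global protein alignment
onto codons; equal-length CDS pairs shortcut to direct codon pairing.

The per-category summary reports arithmetic means of dN, dS and defined
omegas per label plus a two-sided Mann–Whitney U test of each label's
omega values against the complement — deliberately simple machinery for
"is this category evolving faster" questions.

# Codon adaptation index

Relative adaptiveness follows Sharp & Li: codon counts pooled over a
reference set; within each synonymous family `w = count / max(count)`
with zero counts replaced by 0.5 beforehand; completely unobserved
families carry no information and get weight 1. For real genomes the
reference set defaults to CDSs whose product contains "ribosomal
protein" — a standard choice for the highly expressed class when a
study's own reference list is unavailable; the simulator plants exactly
such a class. CAI is the geometric mean of weights over a gene's
codons, excluding ATG, TGG and stops (their families admit no choice).

# Genome context networks and the GCN tree

Three evidence channels are computed per strain against a reference
panel (≥ 3 annotated genomes; the simulator evolves a stand-in panel
from the ancestor with elevated, varied gene loss so presence/absence
vectors are informative):

* **profiles** — presence bit per panel genome from the best hit under
  the homology criteria; edges between genes whose informative vectors
  (neither all-0 nor all-1) differ in ≤ 1 position (a mutual-information
  rule is selectable);
* **neighbors** — edge when the two genes' homologs lie within 3 genes
  of each other in the circular gene order of ≥ 2 panel genomes;
* **fusion** — edge when one panel protein is hit by both genes on
  footprints overlapping ≤ 10% of either footprint.

All three rules and their thresholds are configuration keys
(`gcn_params()`), because the cited methodology for this family of
analyses leaves them unspecified; the defaults are the simplest rules
that recover planted structure reliably in the tests.

The network distance is `1 − Jaccard` between edge sets after
translating one network's tags through the pairwise ortholog map. A
design point worth stating explicitly: restricting both edge sets to
ortholog-mapped node pairs before the Jaccard (the obvious "aligned
subnetwork" choice, available as `restrict_distance = TRUE`) is blind
to gene content, and on close strains the edges among shared genes are
nearly identical — the restricted distance collapses toward zero and
carries almost no phylogenetic signal. The default therefore keeps
edges with unmapped endpoints in the union as automatic disagreements,
so shared gene losses (the signal that makes B and C sisters) pull
strains together. The measure is symmetric for one-to-one maps, zero
on identical networks, and its set arithmetic is pinned by a hand-
computed fixture in the tests. Two empty edge sets give distance 0.

Trees are built by neighbor joining on the pairwise distance matrix.
The bootstrap resamples **panel genomes** with replacement — the panel
is the stochastic evidence base, and each channel's per-panel-genome
evidence is cached so replicates reweight evidence without re-aligning
anything — then rebuilds networks, distances and trees and reports
split frequencies. Over 20 simulated triplets the ((B,C),(A,ancestor))
topology is recovered in 100% of runs with mean (B,C) support ≈ 99%.

# Trees

Jukes–Cantor distances (`d = -(3/4) ln(1 - 4p/3)`) with pairwise
deletion of gap/ambiguity columns; p ≥ 3/4 is an error, since upstream
marker choice (near-identical 16S-like rRNA) should preclude it. K80 or
other models were not added: at intra-subspecies divergence the model
choice is immaterial, and the distance slot accepts any user matrix.
Neighbor joining delegates to `ape::nj` (the field-standard
implementation of Saitou–Nei agglomeration) behind validation (symmetry
to 1e-8, finiteness) and clamps negative branch-length estimates to
zero with a count attribute. Newick I/O wraps `ape` with support-label
and quoted-label normalization. NJ exactness on additive matrices is
verified on 100 random 4–10-taxon trees.

# Pipeline and reproducibility

`run_pipeline()` runs the full chain on a simulated triplet and writes
per-stage outputs plus `manifest.tsv` (file, md5, producing stage) and
`report.json`. Every stochastic stage receives
`derive_seed(master, k) = (101·master + k) mod (2^31 − 1)`, so a master
seed fixes every byte of output; the tests assert manifest equality
across repeated runs. A stage failure aborts with the stage named and
partial outputs retained. The exported functions plus
`scripts/acceptance.R` / `scripts/validation.R` are the package's
command surface.

# Problem sizes and runtime

The test-suite and acceptance experiments use: 61×61 codon-pair oracle
comparison; omega recovery at 50 genes × 300 codons × 20 seeds per
omega level; 100 random additive matrices of 4–10 taxa; pan-genome
recovery at 120 genes; GCN recovery at 50 genes × 120 codons, 6 panel
genomes, 50 bootstrap replicates × 20 seeds. These sizes were chosen so
a complete validation runs in a few minutes on a single CPU while
keeping every binomial bound and rank test adequately powered.

# Known limitations

* The repeat finder reports anchor-coverage identity, not an alignment
  identity, and merges over ≤ 500 bp gaps only; highly diverged or
  heavily rearranged repeats will fragment.
* RBH orthology with weakest-edge triangle resolution is conservative
  under tandem duplication (see above); a family-level clusterer is the
  standard alternative when paralog-rich genomes dominate.
* NG86 is a counting estimator; it underestimates rates at high
  divergence relative to ML codon models and is flagged, not corrected,
  at saturation.
* The CAI reference set is a product-string heuristic on real
  annotations.
* GCN edge rules and the network distance are deliberately simple,
  configurable defaults; absolute branch lengths of the GCN tree have
  no calibrated interpretation — only the topology and supports are
  analysed.
* The simulator's independence assumptions (no recombination, no rate
  heterogeneity) bound what recovery tests can claim about real data.
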