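---
title: "Pangenome-graph SV genotyping, benchmarking and rare-variant prioritization with pansv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome-graph SV genotyping, benchmarking and rare-variant prioritization with pansv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

## The problem

Reference-based structural-variant (SV) callers compare each genome to a
single linear reference, which makes alleles from different genomes hard to
compare with each other and biases discovery against sequence absent from
the reference.  A pangenome graph solves both problems: a reference
*backbone* is progressively augmented with the SV-sized differences
(>= 50 bp) of many haplotype-resolved assemblies, so that every polymorphic
locus becomes a *bubble* — a subgraph between a *source* node, where genome
paths diverge, and a *sink* node, where they coincide again — and every
distinct source-to-sink path is an *allele* of that locus.

`pansv` implements the analysis layer of this approach for a rare-disease
setting: it parses the graph, detects bubbles, builds a binary
allele-by-haplotype genotype matrix under assembly-validity filtering,
partitions alleles between a patient cohort and a population panel,
annotates them, benchmarks the graph genotypes against a reference-based
callset, analyses families, and ranks rare exonic SVs by phenotype fit.
Because the data such studies use are restricted, the package ships a
seeded synthetic-cohort generator whose complete truth set makes every
stage testable.

## Graph model and bubble detection

The graph is rGFA: GFA1 whose segments carry the stable name (`SN`), stable
offset (`SO`) and rank (`SR`) of the contig that introduced them; rank 0 is
the backbone.  Coordinates are 0-based half-open everywhere inside the
package and only converted to 1-based at the VCF boundary (the BED/GFA
convention).  Traversals are restricted to the forward strand: an inversion
is representable as a complex allele whose interior node carries
reverse-complement sequence, not as a reverse-orientation walk, because
genotyping never requires bidirected traversal.

`detect_bubbles()` anchors bubbles on the backbone.  *Anchor* nodes are the
backbone nodes through which every end-to-end path passes; bubbles are the
intervals between consecutive anchors containing variation.  Operationally
the implementation forms connected components of off-backbone nodes plus
backbone-skipping (deletion) edges, takes each component's backbone span,
and merges spans that properly overlap — two spans sharing only an anchor
remain separate bubbles.  This is equivalent to the anchor definition, and
the test suite proves the equivalence against an exhaustive path-enumeration
oracle on 500 random graphs.  Nested bubble structure is deliberately not
represented: a detour spanning an inner polymorphism removes the inner
anchors, so only the outer (maximal) bubble is reported.  Cyclic regions,
components touching two chromosomes, and dead-end components cannot be
expressed as source/sink bubbles and are returned in an `unresolvable`
attribute rather than silently dropped.

A degenerate locus where source and sink are joined both by a direct edge
and by interior nodes is handled by treating the direct edge itself as an
allele — the *star deletion* — with interior length 0.

All returned tables are sorted by `(stable_name, start, allele_key)` so
results are bit-reproducible.  `anonymize_nodes()` replaces every stable
name with the sha256 hash of the name concatenated to a fresh per-node
salt; this intentionally severs the link between nodes of one assembly, so
an anonymized graph written back to rGFA can no longer be re-grouped into
backbone chains by stable name (the in-memory object keeps its backbone).

## Genotyping and the allele-frequency spectrum

Per-haplotype call tracks (one record per traversed bubble, with a node
path or `"."` for the reference path, plus the supporting interval on the
sample assembly) are combined into a binary matrix: rows are
`(bubble, allele)` pairs, columns are haplotypes, within one bubble each
column carries at most one `1`.

Genotypes are only as reliable as the assembly under them.  A validity
track labels assembly regions `haploid` (reliable) or
`error`/`collapsed`/`duplicated`; a call is kept only when its support lies
entirely within haploid sequence, and is otherwise flagged by the worst
overlapping label (precedence `error > collapsed > duplicated > unknown` —
the precedence order is this package's choice, the source tooling only
states that non-haploid labels are invalid).  Low-coverage regions are
folded into `unknown` and treated as invalid under filtering.  Flagged
calls are retained in the call table, never deleted.

Missing loci (a bubble unassembled in a haplotype) are distinguished from
reference calls: the matrix stores 0 either way, but a companion
missingness mask records data presence per bubble and haplotype, and
frequencies default to carriers over haplotypes-with-data.  Conflating
missing with reference would bias frequencies downward for poorly assembled
samples; both conventions are exposed (`missing_aware`).

`partition_and_spectrum()` classifies each non-reference allele as shared
between the two sub-cohorts or private to one, enforcing the conservation
identity `shared + A_only + B_only = total` on every run, and bins the
frequency spectrum (default edges include the 10% and 90% thresholds used
for rare/near-fixed summaries).  Columns labelled `reference` (backbone
pseudo-samples) are excluded from every denominator.

## Annotation

Allele classes come from path topology, not sequence length: the direct
edge against a reference interior is a deletion, interior sequence against
a direct reference edge is an insertion, everything else is complex.  Full-
length mobile-element calls require strictly more than 80% of the interior
sequence covered by merged SINE (or LINE) repeat hits *and* a length within
250-400 bp (or 5,000-10,000 bp); both length bounds are inclusive, the
coverage inequality strict — a literal reading of "more than 80%".

For positional analyses, every allele inherits its bubble's backbone
interval; insertion-point bubbles are anchored at a 1 bp interval so that
breakpoint-style overlap behaves uniformly.  The overlap predicate is
any-bp intersection (exposed as `min_overlap`).  Compartments are assigned
most-specific-first: OMIM exon over exon over gene body over intergenic.
Novel-sequence accounting surveys non-reference nodes longer than 100 bp,
subtracts the union of repeat hits and reference alignments, and ignores
remaining fragments under 10 bp.  Hotspots are fixed 1 Mbp tiles whose SV
count reaches the 90th percentile of nonzero tile counts; the threshold is
a type-1 (observed-value) quantile and the comparison is inclusive, so a
single loaded window is itself a hotspot.

## Benchmarking against a reference-based callset

Graph calls enter the benchmark only from biallelic bubbles; the less
common of the two alleles is the ALT (ties prefer the non-reference
allele), and the star-deletion subset is flagged.  Calls lying less than
100 bp from a reference assembly gap are omitted.  A reference-based call
(non-BND, `|SVLEN| > 50`) matches a graph call of the same sample when the
gap distance between their breakpoint intervals is at most 100 bp (0 when
they overlap); the distance anchor is the minimal interval gap, a
documented convention since "within 100 bp" does not define one.  Matching
is one-to-one, nearest-first with leftmost tie-break, making the matched
count symmetric and order-invariant; recall is matched over total reference
calls and precision matched over total graph calls, with `NA` (never 0) on
empty denominators.  Region-stratified averages are restricted to regions
with at least one call from each caller.

## Family analysis

Sibling sharing uses presence/absence only.  Reference-based calls are
merged across samples when both start and end breakpoints agree within 10%
of the longer SV's length (calls under 50 bp discarded first); clusters are
the connected components of this pairwise predicate, computed by a sorted
sweep with union-find.  Single-linkage components were chosen over greedy
left-to-right seeding because only they are order-independent and equal to
the brute-force transitive closure the tests demand.  Graph calls are
merged by bubble identity — the same source and sink delimit the same
locus — mirroring the asymmetric treatment of the two callsets.  Sharing is
clusters-in-both over clusters-in-either (the denominator is exposed);
permutation nulls re-pair siblings uniformly while forbidding true pairs
(falling back to a rotation when no derangement is drawn within 100
attempts), with a fixed seed.

Mendelian verdicts depend only on the three ALT copy numbers: the minimum
transmissible count is the number of homozygous parents, the maximum the
number of carrier parents; a proband below the minimum is a false negative,
above the maximum a false positive.  The 27-case table is verified against
an exhaustive transmission enumeration.

## Phenotype-driven prioritization

Candidates are alleles private to the patient cohort, replicated by the
reference-based caller (the *concordant* consensus), and overlapping an
exon.  The phenotype score is an information-content sum over the terms
shared between the ancestral closure of the patient's ontology terms and
the gene's propagated annotations, with IC = -log2(annotation frequency) —
a Phrank-style score in bits.  Because the published score's normalization
is not recoverable, the absolute threshold (default 5 bits) is meaningful
only relative to this implementation; externally computed scores can be
supplied instead, and the top-quartile rule is applied in conjunction
(AND) with the absolute threshold.  Exons carrying common non-reference
alleles in more than 5% of cohort haplotypes are treated as highly
polymorphic and excluded ("highly polymorphic" being undefined in the
source, the cutoff is a documented flag).  Survivors are ordered by score,
then allele rarity, then position — a total, reproducible order.
Inheritance-based deprioritization is available as an optional flag when
parental calls exist.

## The synthetic cohort generator

`simulate_cohort()` emits, from one seed, everything the pipeline consumes,
with complete truth.  What it emulates — and what it does not — determines
what a green test suite can and cannot say about real data.

Default conditions (chosen once; every value is a `cohort_config()` field):

* two 1 Mbp chromosomes of uniform random sequence;
* 200 SV loci in per-chromosome slots (guaranteeing >= 300 bp between
  loci), class mix 35% insertion, 35% deletion, 20% complex substitution
  block, 10% tandem-repeat copy-number series — the last two modelling the
  complex bubbles that dominate real graphs;
* allele frequencies drawn from Beta(0.2, 2), the rare-skewed spectrum;
  per-allele cohort partition shared/A-only/B-only with probabilities
  0.50/0.35/0.15;
* cohort A ("patient-like"): 30 diploid samples — 4 sequenced trios, 3
  sibling-pair families and 1 identical-twin family with unsequenced
  parents, 10 singletons; cohort B ("panel-like"): 10 unrelated samples.
  Children inherit whole parental haplotypes per chromosome (independent
  assortment, no intra-chromosomal recombination);
* 15% of insertions are mobile-element cassettes (SINE ~300 bp, LINE
  5.2-6 kbp, 5% divergence) with planted repeat-hit coverage 0.9, and a
  quarter of them decoys at coverage 0.7 that the full-length rule must
  reject;
* per-call noise: 3% missing loci, 5% of calls from invalid assembly
  regions (labels drawn from error/collapsed/duplicated), and 1% spurious
  private-allele calls whose support is flagged invalid 80% of the time —
  assembly errors fabricating singletons is the honest mechanism behind
  the observed excess rejection of singleton alleles;
* two independent reference-based caller emulations: the primary one with
  5% false positives, 8% false negatives and 10 bp breakpoint jitter, and
  a noisier independent one (30%/15%/20 bp) used as the replication truth
  for consensus precision.  Their errors are drawn independently so
  consensus enrichment is a real signal, not a construction;
* gene models (30 genes x 4 exons), 30% OMIM-flagged; a 17-term toy
  phenotype ontology with per-gene annotations;
* one planted causal 800 bp exonic deletion in an OMIM gene, maternally
  inherited by the first trio's proband, whose phenotype terms match that
  gene's annotations.

Three generator choices deserve emphasis.  First, the graph is emitted
directly from the truth (every observed allele becomes a bubble path)
rather than via progressive alignment; graph construction itself is out of
scope, and direct emission gives exact truth.  Second, every planted allele
differs from the reference by at least 60 bp, so all loci are genuinely
SV-sized and the caller emulations — which cover exactly the biallelic loci
and report carriers of the minor allele, the same ALT convention the
benchmark uses — correspond one-to-one with the benchmark callset in the
noiseless limit (R = P = 1 exactly, verified).  Third, the causal locus is
kept clean: it is exempt from planted missingness, invalidity, spurious
alleles and caller false negatives, because the scenario models a real
variant with unambiguous sequence support, and the rank-1 recovery property
is about prioritization, not caller noise.

What the generator does **not** emulate: alignment and assembly artefacts
with positional structure, nested and overlapping bubbles, inversions and
translocations, segmental-duplication hotspots, linkage between loci,
population structure, and realistic repeat sequence.  Passing tests
therefore demonstrate the correctness of the bookkeeping, the rules and the
statistics under a faithful but idealized data-generating process — not
caller performance on real genomes.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
as the package's own choice of experiment size: the default cohort
(80 haplotypes, 200 loci) for end-to-end checks; 200 haplotypes and 2,000
loci for frequency-spectrum recovery within 95% binomial confidence
intervals; 500 random graphs for the bubble oracle; and 100 seeded
replicates of a reduced cohort (36 + 14 haplotypes, 80 loci on two 400 kbp
chromosomes, default noise rates) for the causal rank-1 recovery property,
where a two-carrier allele still sits below the 5% rare-MAF cutoff.

Numerical conventions collected in one place: coverage thresholds strict,
length windows inclusive; hotspot threshold an observed count, comparison
inclusive; matching window inclusive (gap 101 bp fails a 100 bp window);
gap exclusion strict (< 100 bp); merge tolerance inclusive; quantiles
type 1 where a threshold must be an observed value, default type
otherwise; all list outputs sorted by genomic position then key; every
stochastic routine takes an explicit seed and restores the caller's RNG
state where it seeds internally.

## Known limitations

Bubble detection assumes variation is anchored on a single backbone; pure
inter-chromosomal events (translocations) are reported unresolvable, not
genotyped.  The genotype matrix is unphased beyond the haplotype columns
the assemblies provide.  The phenotype score implements one defensible
Phrank-style normalization; thresholds do not transfer to other
implementations.  The published cohort-scale results (overall R/P against
the reference-based caller, sibling-sharing deltas, consensus precisions)
depend on restricted patient data and are reproduced here only as effect
directions on synthetic cohorts, never as numbers.
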