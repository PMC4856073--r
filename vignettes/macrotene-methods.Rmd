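---
title: "Reconstructing macrotene chromosomes: models and methods"
author: "macrotene package"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In budding yeast placed under severe fitness stress, selection on a single
transgene (a *Yarrowia lipolytica* asparagine tRNA-synthetase gene
integrated ~70 kb upstream of the *CUP1* locus on chromosome VIII) can be
answered not by point mutation but by wholesale chromosome remodeling:
grossly enlarged "macrotene" chromosomes appear, carrying low-order
segmental amplifications of the region around the selected gene together
with a massive tandem expansion of the 2 kb *CUP1* repeat unit — hundreds
of copies per cell, far beyond anything the selection itself requires.
Reconstructing what these chromosomes look like from short-read sequencing
is a composite inference problem:

* **copy number** — read depth, normalized to copies per cell, read off as
  an integer staircase of amplicon levels;
* **breakpoints** — novel junctions that by construction cannot be mapped,
  only *assembled* from the reads the mapper rejects;
* **repeat counts** — two independent estimators for the tandem-array
  size: total coverage over the repeat unit, and the sizes of restriction
  fragments that contain the arrays (the repeat unit carries no EcoRI or
  BamHI site, so an array travels as a single fragment);
* **topology** — the set of linear chromosome structures consistent with
  all of the above, found by enumeration rather than by hand.

The package implements this pipeline end to end and exercises it on a
scaled synthetic genome that reproduces the structures and the two
confounders that shaped the original analysis (dispersed identical delta
elements, and a chromosome I subtelomere identical to chromosome VIII's
except for one unique marker gene).

# The synthetic reference and what it emulates

`build_reference(scale)` emits four chromosome analogs:

* **chrVIII** (563 kb x scale): carries the CUP locus — a 2.5 kb flank
  plus, in the *mapping reference*, only two copies of the 2 kb unit (the
  historical reference assembly carried two; parental cells carry 16) —
  the Asn-RS marker 70 kb (scaled) upstream of it, delta elements at the
  amplicon boundaries (116.5 kb, 133.8 kb, and upstream of 549.5 kb), and
  a 13 kb (scaled) right subtelomere.
* **chrXVI** (300 kb x scale): its left 56.5 kb (scaled) is the XVI-A
  amplicon, delta-bounded on the right.
* **chrI** (230 kb x scale): its right subtelomere is sequence-identical
  to chrVIII's except for the unique IMD2 marker present only on chrVIII —
  the designed mis-mapping confounder.
* **chrII** (400 kb x scale): neutral background.

Scaling rule: positions scale as `round(x * scale)`, but the elements that
carry arithmetic never scale — the 2 kb repeat unit, the 2.5 kb flank
(EcoRI sites are planted so that a locus of *n* units yields a fragment of
exactly `2n + 2.5` kb), 300 nt delta elements and telomeric runs, and the
marker genes. Chromosome VIII keeps its total of `round(563000 * scale)`;
because the CUP region keeps its physical size, right-arm landmarks are
mapped affinely into the remaining span (exactly at scale 1). The non-VIII
chromosome lengths are package choices sized so that haploid positions
dominate the genome-wide median in every mutant while keeping desk-scale
runtimes low; chrI matches the real chromosome.

Background base composition is seeded i.i.d. uniform ACGT. Real coverage
fluctuates with GC content; that bias is not simulated, so a smooth
profile here does not demonstrate robustness to GC waves. Delta copies are
*sequence-identical* by design: junctions falling inside them must defeat
assembly, as they do in real data. Telomeric runs are degenerate
`(C1-3A)n` repeats drawn deterministically per chromosome end.

The repeat unit is constructed once, seeded: it contains the two inverted
near-identical 16 nt motifs 745 nt apart (the microhomology substrate), no
EcoRI/BamHI site, and pinned bases at the motif edges so that junction-arm
alignments terminate exactly at the biological breakpoint. The same
pinning is applied to the non-palindromic loop sequences of strand-switch
junctions (their terminal bases cannot extend the palindrome arms); loops
are also checked to be non-palindromic. Without this the classifier could
over- or under-call loop lengths by one or two bases whenever a loop
boundary base matched the reference continuation by chance.

## Read simulation

`simulate_reads()` draws single-end reads uniformly over the realized cell
(chromosomes plus circular episomes, which may wrap the origin), on either
strand, with i.i.d. substitution errors and constant quality strings.
Defaults: 50x coverage, 100 nt reads, 0.1% error, deterministic under a
seed. There is no paired-end, indel, duplicate or adapter modeling; the
junction evidence in this system is substitution-scale. The study's
sequencing was 50-cycle single-end at 384-834x; 100 nt at 50x is the
desk-scale stand-in, and read length is configurable because junction
detection power depends on it.

# Coverage pipeline

`map_reads()` assigns each read its best ungapped placement: an exact
multi-pattern pass (both strands) resolves error-free reads; the rest are
seeded with 21-mers and verified by full-length mismatch counting, with
reads above 10% mismatches reported unmapped. Ties among repeat copies are
resolved by the multi-map policy: the default `"first"` keeps the first
placement in chromosome-then-coordinate order with weight 1 — the
deterministic behavior that reproduces the shared-subtelomere artifact
(chrI reads piling onto chrVIII, depressed but non-zero coverage over a
deleted region, zero reads over the unique marker) — and `"split"` spreads
weight 1/k over the k tied placements. Chromosome VIII is first in the
reference order so that the artifact lands where the original analysis
saw it.

`normalize_to_copies()` divides depth by the genome-wide median. In the
real 16-chromosome genome the amplified loci are a negligible length
fraction, so the whole-genome median is haploid depth; in this compact
synthetic genome chrVIII is ~38% of positions, so the pipeline anchors the
median on the other chromosomes (the `exclude` argument), which is also
how the original figure legends describe the normalization. Smoothing is a
centered moving average (1500 nt windows in the original analysis; 200 nt
for subtelomere zooms) with shrinking windows at the edges.

## Segmentation and amplicon decomposition

`segment_levels()` computes non-overlapping windowed means and applies
binary changepoint segmentation with a BIC-like penalty
(`penalty_mult * sigma^2 * log(n)`, sigma estimated robustly from first
differences), then merges short segments and rounds each segment to its
nearest integer level; means more than 0.35 from any integer are flagged
`non_integer` rather than forced (a guard against mixed colonies). The
analysis window defaults to the smoothing scale of the coverage analysis
(1500 nt) multiplied by the genome scale, i.e. 150 nt at desk scale; the
pipeline uses a 2-window minimum segment so that the narrow interval
between the 116.5 kb delta and the 123.2 kb boundary survives.

The CUP array is masked during segmentation (its level is two orders of
magnitude above the segmental scale and is handled by the repeat
quantifier), and so are delta elements and telomeric runs: under a
deterministic multi-map policy all reads falling entirely inside a
dispersed repeat pile onto its first copy, spiking one instance and
zeroing the others. Only the repeat bodies are masked — positions outside
are anchored by unique sequence.

`staircase_decompose()` turns the integer staircase into a
minimum-cardinality multiset of amplicons with integer multiplicities by
exact dynamic programming over integer partitions of each level; among
minimum solutions it keeps calls open as long as possible, which yields
the right-aligned nesting of the observed amplicon ladders (amplicons
sharing their right boundary at the CUP locus edge). `call_deletions()`
flags terminal sub-unit segments and confirms them when a region-unique
marker gene has zero covering reads (an overlap of at least 10 nt counts
as covering — a one-base graze with a coincidentally identical base is not
marker evidence).

# Junction discovery

Unmapped reads are assembled by a greedy de Bruijn assembler at word sizes
21, 51 and 71 (the multi-k schedule of the original reassembly), with
k-mers below depth 2 clipped and the pool augmented with reverse
complements. Contigs contained in longer ones are collapsed. The large
word size matters structurally: near a quasi-palindromic junction the two
arms are locally identical, so at small k the graph branches at the
junction point; a word longer than the covered arm span resolves the
branch and lets one contig run through the junction.

Contig support is normalized to copies per genome. Because only
junction-spanning reads are unmapped, read placements concentrate at the
junction; the normalization window is therefore the span of observed
supporting placements, not the contig length, and contigs at or below 0.5
copies per genome are discarded (the original contig-support rule).

`classify_junction()` maps the contig prefix and suffix to the reference
on both strands by seed-and-extend (up to 2 mismatches, extension trimmed
to the last 4-match anchored position, so a single palindrome-arm
substitution does not derail the arm end):

* opposite strands, arms meeting at (nearly) the same reference position
  with an unaligned middle: **strand-switch palindrome**, loop = the gap;
* opposite strands overlapping in the contig by >= 8 nt with separated
  reference positions: **inverted microhomology**, reporting motif length
  and reference spacing;
* a telomeric `(C1-3A)n` run (>= 15 nt, either phase) on one side:
  **telomere fusion**, with the fusion point left-aligned across the run
  (a chance base match can otherwise shift it);
* arm placements tied across dispersed delta copies, or junction points
  inside delta elements: **repeat-ambiguous** — reported but marked
  unresolvable, exactly the class the original analysis could not
  assemble. Arm placements tied only across CUP repeat units are
  translation-collapsed to the first unit instead (the junction geometry
  is unit-periodic).

Junction copy number counts reads spanning the junction point with at
least 10 nt anchored on each side, scaled by
`read_length / (window * haploid_depth)`. Two details matter: candidates
are drawn from the *full* read set, because reads that straddle the
junction by only a little beyond the margin are force-placed on the
reference with mismatches and would otherwise be missed; and for
microhomology junctions the left anchor must clear the shared motif,
since reads touching only the motif are not junction evidence. At 50x the
estimator's sampling error is roughly 0.15 copies; calling "one vs two
occurrences per cell" is comfortable, finer distinctions are not.

# Repeat quantification

Two estimators, deliberately independent:

* **coverage**: mean copies-per-cell over the reference repeat-unit
  positions times the number of unit copies in the reference (two), so a
  100-fold haploid excess is 200 units per cell;
* **restriction fragments**: the preserved normal locus follows
  `round((fragment - 2.5 kb) / 2 kb)`; expanded loci follow
  `floor(fragment / 2 kb)` with no flank term — the convention
  reverse-engineered from the published per-locus counts; note it can
  overcount by one unit when the physical fragment carries the full
  flank. Internal arithmetic is in nt to keep one-decimal kb values
  exact.

`strain_estimate()` reconciles the two and reports their ratio to two
decimals; across the nine published strains the ratios span 1.31-1.59.
The package exposes both proposed explanations of that systematic excess
as knobs without adjudicating between them: episomal arrays in the
simulator (coverage counts them, chromosomal fragments do not) and the
multi-map policy. PFGE band sizes interpolate log-linearly in migration
distance between ladder points and refuse to extrapolate.

# Topology enumeration

`enumerate_structures()` searches over molecules built as chains: the
centromere-bearing left arm, then oriented blocks (maximal reference
intervals between breakpoints) and tandem arrays, ending at a telomere.
Adjacency requires an array end at a CUP-locus edge, or two delta ends
(wildcard junctions, mirroring the "hypothetical" dotted junctions of the
deduced structures), and a molecule may end at its native telomere, at a
captured XVI-A subtelomere, or by telomeric-repeat addition at a
breakpoint where a telomere-fusion junction was observed. Solutions must
reproduce the observed copy-number vector exactly, place every observed
palindromic junction in an expanded array, match the PFGE band sizes when
given (expanded-array sizes are assigned to slots as a multiset), and —
when the count is constrained — use exactly the observed number of
delta-delta junctions. Canonicalization merges reference-contiguous
segments, takes the lexicographic minimum of each molecule and its
reverse complement, and sorts molecules, so a model and its mirror are
one solution.

With the single-macrotene constraint set (disomy, one extra copy each of
the two overlapping amplicons, one expanded array with a strand-switch
junction, one delta-delta junction, one normal-sized molecule) exactly
four topologies survive: expanded locus proximal or distal to the
preserved one, times the two orientations of the inverted amplicon block.
The data genuinely cannot distinguish them — locus-edge junctions read
identically wherever the expanded array sits. When the constraint set is
derived automatically from pipeline calls (`constraints_from_calls()`),
the delta-junction count is left unconstrained, because delta-junction
copy estimates are repeat-ambiguous by nature; the solution list is then
a superset that still contains the generating topology. The shared
subtelomere's level is read from the unique marker rather than from the
raw segment (the designed confounder inflates it by the twin
chromosome's reads).

# The formation model

Three steps, executed as explicit transformations: (1) a delta-mediated
segmental duplication spanning the CUP locus and the selected marker,
concomitant with disomy, giving the M0 intermediate (two normal CUP loci,
three marker copies per cell); (2) an accidental quasi-palindromic
junction in the left or the right CUP locus triggers tandem amplification
— left terminates by a delta-delta interaction that inverts the
overlapping amplicon block and keeps the right chromosome end; right
deletes the distal arm and acquires a new telomere, by direct telomeric
repeats at the 123.2 kb boundary or by capturing the XVI-A subtelomere;
(3) the normal homolog is homogenized from the CUP locus rightward using
the macrotene as template. Step 3 follows the long-range
loss-of-heterozygosity reading rather than a literal whole-chromosome
copy: a literal copy cannot produce the observed shorter second macrotene
that lacks everything distal to the CUP locus. Amplification is a count
parameter, not a kinetic process, and the left/right choice is exposed
both explicitly and as a seeded equal-probability draw. The marker
trajectory is 1 -> 3 -> 4 (single-macrotene path) or 5 (two-macrotene
paths), and each scenario's product is topology-isomorphic to the
corresponding deduced structure.

# Problem sizes, defaults and limitations

The test suite and the acceptance script run the full pipeline at genome
scale 0.1, 50x coverage, 100 nt reads, 0.1% substitution errors, with
desk-scale expanded arrays of 28-34 units standing in for the
multi-hundred-copy arrays of the real mutants (the repeat-unit, flank,
loop and spacer arithmetic never scales, so every junction and fragment
quantity is identical to full scale). What passing shows: the estimators
recover planted truth under uniform sampling with substitution noise and
the designed repeat confounders. What it does not show: robustness to GC
waves, indels, chimeric library artifacts, or mixed populations — and
PFGE band sizes of real mutants and the published junction coverages
(0.96x, 0.63x) are full-scale measurements that a desk-scale synthetic
run does not reproduce. Whether each expanded locus replaces or sits
beside the normal one is undecidable from the data; the built-in models
adopt the drawn convention and the enumerator carries both. Exact
junction sequences of the original mutants are not in the main text, so
synthetic junctions are parameterized, not sequence-faithful.

```{r}
library(macrotene)
ref <- build_reference(scale = 0.1)
cell <- builtin_model(ref, "BYAT711")
reads <- simulate_reads(cell, ref, simulation_config(coverage = 50, seed = 11))
analysis <- analyze_readset(reads, ref)
analysis$junctions
constraints <- constraints_from_calls(analysis, ref, simulated_pfge(cell, ref))
solutions <- enumerate_structures(constraints)
topology_key(cell, ref) %in% vapply(solutions, function(s)
  topology_key(s$cell, ref), "")
```
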