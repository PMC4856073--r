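# macrotene

Reconstruction of massively amplified ("macrotene") yeast chromosomes
from short-read data: copy-number inference, quasi-palindromic junction
discovery, tandem-repeat quantification by two independent estimators,
and constraint-based enumeration of chromosome topologies.

## The problem

Under severe fitness stress, budding yeast can answer selection on a
single gene with wholesale chromosome remodeling: grossly enlarged
chromosomes carrying low-order segmental amplifications plus a massive
tandem expansion of the 2 kb *CUP1* repeat unit — hundreds of copies per
cell at a locus the selection never touched. Reconstructing these
structures from sequencing is a composite problem, and this package
implements each piece as a practitioner would run it:

* **Copies per cell from read depth.** Sequencing coverage at each
  position divided by the haploid median depth, smoothed, segmented into
  integer levels, and decomposed into a minimum multiset of amplicons:
  find the smallest set of intervals with integer multiplicities
  `e_i >= 1` whose pointwise sum matches `level(x) - baseline`, preferring
  right-aligned nesting.
* **Breakpoints from unmapped reads.** Novel junctions cannot be mapped,
  only assembled: a de Bruijn assembler (k = 21, 51, 71) over the read
  pool the mapper rejects, a 0.5 copies-per-genome contig support filter,
  and a classifier that aligns contig ends to both reference strands.
  Junction classes: strand-switch quasi-palindromes (two arms of one
  locus in inverted orientation around a short non-palindromic loop),
  inverted microhomologies (switch across two inverted near-identical
  motifs a fixed reference distance apart), telomere fusions, and
  delta-repeat-ambiguous junctions that defeat assembly by design.
* **Tandem-repeat counts, twice.** By coverage:
  `units = mean(copies over reference unit) x units_in_reference` (the
  reference carries two unit copies, so a 100-fold haploid excess is 200
  units per cell). By restriction fragments: the unit has no EcoRI/BamHI
  site, so a locus of *n* units travels as one fragment —
  `round((kb - 2.5)/2)` for the preserved normal locus,
  `floor(kb/2)` for expanded loci.
* **Topology enumeration.** Exhaustive, pruned search over orderings and
  orientations of breakpoint-delimited blocks and tandem arrays, with
  junction-compatible adjacencies only, matching the observed copy-number
  vector, band sizes and junction counts; solutions are canonical up to
  reverse complement.
* **A three-step formation model** (delta-mediated segmental duplication
  with disomy; quasi-palindromic template switch triggering the
  amplification cascade, ending in an internal inversion or a new
  telomere; homogenization of the normal homolog) that provably lands on
  the deduced structures.

A first-class synthetic-data module builds a scaled genome with the
confounders that shaped the original analysis — sequence-identical
dispersed delta elements, and a chromosome I subtelomere identical to
chromosome VIII's except for one unique marker gene — and simulates
uniform single-end reads with truth tracking.

## Worked example

Restriction arithmetic for a mutant whose gel shows a 34.5 kb normal-locus
fragment and a 220 kb expanded-locus fragment, with a coverage total of
200 units per cell:

```r
library(macrotene)
strain_estimate(c(34.5, 220), coverage_total = 200, strain = "BYAT711")
#> Strain: BYAT711
#> Fragments (kb): 34.5 + 220 -> repeats: 16 + 110 = 126
#> Coverage total: 200  ratio: 1.59
```

The chromosomal total (126) is the sum of the per-locus counts; the
1.59 ratio is the systematic excess of the coverage estimator over the
chromosomal one (episomal copies and mapping policy are the candidate
explanations, both exposed as knobs).

Full pipeline on a simulated mutant (0.1-scale genome, 50x coverage):

```r
ref   <- build_reference(scale = 0.1)
cell  <- builtin_model(ref, "BYAT711")
reads <- simulate_reads(cell, ref, simulation_config(coverage = 50, seed = 11))
analysis <- analyze_readset(reads, ref)

subset(analysis$segments, chrom == "chrVIII")
#>     chrom start   end level mean_raw non_integer
#> 1 chrVIII   420 11650     2 1.982422       FALSE
#> 2 chrVIII 11950 13380     3 3.014415       FALSE
#> 3 chrVIII 13680 20000     4 4.015358       FALSE
#> 4 chrVIII 28500 54878     2 2.008226       FALSE
#> 5 chrVIII 55178 55880     2 2.130367       FALSE
```

The staircase reads 2 / 3 / 4 with breakpoints at the scaled images of
116.5 kb and 133.8 kb: disomy plus one extra copy each of the two
overlapping amplicons, right-aligned on the CUP locus.

```r
analysis$junctions[, c("class", "pos1", "loop_length",
                       "mismatches_in_palindrome", "copy_number")]
#>                      class  pos1 loop_length mismatches_in_palindrome copy_number
#> 1 strand_switch_palindrome 22650          38                        0   1.0617284
#> 2         repeat_ambiguous 11650          NA                       NA   0.9629630
```

One strand-switch quasi-palindrome inside the expanded array (38 nt loop,
~1 occurrence per cell) and one delta-delta junction that is reported but
unresolvable. `analysis$repeat_total` returns 61 units per cell, within
5% of the 61.4 unit-equivalents the generator placed. Deriving a
constraint set from these calls and enumerating:

```r
sol <- enumerate_structures(constraints_from_calls(analysis, ref,
                                                   simulated_pfge(cell, ref)))
topology_key(cell, ref) %in% vapply(sol, function(s) topology_key(s$cell, ref), "")
#> [1] TRUE
```

With the delta-junction count pinned to the observed single junction
(`fx` constraint construction in the test suite), the solution list is
exactly the four logically equivalent topologies: expanded locus proximal
or distal to the preserved one, times the two orientations of the
inverted amplicon block.

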