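---
title: "Methods: detecting perfect inverted repeats and characterizing their genomic topography"
author: "irtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting perfect inverted repeats and characterizing their genomic topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtopo)
```

## The object of study

A perfect inverted repeat (IR) is a sequence of the form
*arm* + *spacer* + *revcomp(arm)*: two tracts that are exact reverse
complements of each other, separated by an unconstrained spacer. Such loci
can extrude into hairpins on single-stranded DNA and cruciforms on duplex
DNA, and they are implicated in replication fork stalling, genomic
instability, and — prominently in bacteria — rho-independent transcription
termination, where a hairpin just downstream of the stop codon dislodges
the polymerase.

`irtopo` implements a complete desk-scale pipeline around this motif
class: exhaustive detection, a dinucleotide-preserving shuffled null for
abundance, density across functional genomic compartments, positional
enrichment around transcription/translation start and end sites (TSS/TES)
and termination points (POT), and the intraspecific single-nucleotide
variant (SNV) burden inside IR arms versus spacers under two null models.

## Detection semantics

An IR is parameterized by its full span `[start, end]`, arm length `a`,
and spacer length `d`, with `end - start + 1 = 2a + d`. Detection keeps
every **maximal** IR with `a >= min_arm` (default 10 bp) and
`d <= max_spacer` (default 8 bp). The defaults follow the biophysical
observation that shorter arms and longer spacers are decreasingly likely
to form stable secondary structure; both are exposed in
`detection_params()`.

Maximality has two prongs:

* **outward** — the flanking base pair just outside the arms must not
  complement (or the sequence ends there);
* **inward** — for `d >= 2`, the two bases flanking the spacer's interior
  must not complement, because then the same center carries a
  longer-armed IR at spacer `d - 2`, which is the one reported.

One IR is reported per (center, spacer); overlapping IRs at different
centers or spacers are all reported, and double counting is resolved only
at the footprint level (interval union), which is what density is defined
on. `N` never base-pairs, so arms are always N-free; spacers may contain
anything. Sequences are treated as linear — the topology flag of
`genome_seq()` is recorded but origin-spanning IRs on circular replicons
are not searched for.

The detector itself is a small C++ routine that enumerates every
(innermost pair, spacer) combination and extends arms outward — linear
work per center in random sequence. Its correctness is not taken on
faith: the test suite contains two independently formulated enumerators
(a naive substring triple-loop and a vectorized anti-diagonal run-length
scan) and asserts exact set equality on hundreds of seeded random
sequences, as well as three-way agreement on small inputs.

### Densities

IR density is footprint base pairs per kilobase:
`1000 * ir_bp / region_bp`. "IR bp" uses the full span (arms plus spacer)
by default; because the literature is ambiguous on whether spacer bases
count, every footprint-consuming function takes a `what = "span" | "arms"`
switch. A zero-length region yields a flagged `NA`, never an exception.

## The shuffled null

Expected IR content is estimated from a control genome produced by a
dinucleotide-preserving shuffle applied independently to non-overlapping
1,000-bp chunks (`shuffle_params(chunk_bp = 1000)`); the final partial
chunk is shuffled as its own segment. The shuffle is the Euler-walk
construction: the chunk is an Eulerian path on the graph whose vertices
are symbols and whose edges are the overlapping doublets; a random "last
edge" per vertex is drawn and accepted only when the last edges form an
arborescence into the terminal symbol, remaining edges are ordered
uniformly, and the walk is read off. This guarantees — not approximates —
an identical doublet multiset per chunk, hence identical mononucleotide
counts, GC content, and fixed first/last residues. `N` is a fifth symbol
in the graph, so N-containing doublets are preserved rather than
stripped. Doublets straddling chunk boundaries are not preserved; that is
inherent to chunk-independent shuffling and accepted as such. One seeded
RNG stream is used per genome, so a (genome, seed) pair is fully
reproducible.

## Enrichment and effect sizes

For observed `O` and expected `E` (bp or densities) the enrichment is

\[ FE(O, E) = \frac{O - E}{O + E}, \qquad FE = 0 \text{ when } O = E, \]

bounded in \([-1, 1]\), antisymmetric, and scale invariant. Paired effect
sizes across genomes use the differences \(d_i = X_i - Y_i\) between each
real genome and its matched control:

* **Hedges' g**: \( g = J(N-1)\,\bar d / s_d \) with the small-sample
  correction \( J(n) = 1 - 3/(4n - 1) \). The standard deviation is the
  sample (n−1) form by default — the convention that the J correction
  presumes — with a `sd_type = "population"` option.
* **paired Cliff's δ**: \( 2\,P(X > Y) + P(X = Y) - 1 \) with empirical
  proportions, so ties contribute exactly the \(P(X=Y)\) term; the
  unpaired form averages the sign over all \(N \times M\) cross pairs.

Significance uses the two-sided Wilcoxon signed-rank test per taxonomic
group with Benjamini–Hochberg adjustment across groups
(`paired_test_with_bh()`); both are delegated to the standard `stats`
routines. Groups whose differences are all zero have an undefined test
and are flagged rather than dropped silently. Aggregation follows the
two-level mean: a species' density is the mean over its assemblies, a
rank's density `F(R)` the mean over its species.

## Topography

`derive_compartments()` turns gene models into mutually disjoint merged
interval sets: genic, intergenic (complement), exonic, intronic (genic
minus exonic), CDS, and strand-aware 5′/3′ UTRs (exonic bases outside the
CDS extent). Prokaryotic-style annotations lacking exon features are
filled in with a single gene-spanning exon at ingestion. Compartment
density intersects the IR footprint with each compartment, so an IR
straddling a boundary contributes proportionally to each side.

Positional profiles lay a symmetric window (default ±500 bp, 1001
positions; ±100 for POT) around each anchor and sum IR footprint bp per
offset over genes. Windows of minus-strand genes are reflected so that
negative offsets always mean upstream — the orientation the biology
requires even though annotation formats do not impose it. Genes whose
window overruns the replicon are dropped, not zero-padded: padding would
deflate the window mean and fabricate enrichment. Enrichment divides each
offset by the window mean, so `mean(enrichment) == 1` exactly for every
non-flagged profile; a window with no IR coverage at all is flagged
`NA` rather than silently zero. Each gene contributes its own window
independently; bases shared by overlapping windows are counted in each.

Domain-level profiles are per-offset means over genomes, and confidence
bands come from a two-stage bootstrap: families resampled with
replacement, then species within each drawn family, N = 1000 replicates,
2.5/97.5 percentiles per offset, deterministic under a fixed seed. With a
single family the outer layer is degenerate and the function falls back
to species-only resampling with a warning. A per-offset standard-error
band would be a cheaper alternative; the percentile bootstrap is the
default because it respects the strong phylogenetic clustering of
species-level profiles.

## SNV burden in arms versus spacers

Variants are ingested with inclusive quality filters (mapping quality
≥ 50, site QUAL ≥ 60); each passing position is a binary SNV site,
independent of allele frequency. Records without an MQ annotation are
excluded — the conservative reading of "high-quality variants only".
Multi-allelic records are split per alt before filtering, and a site with
at least one passing alt counts once.

Two expectations are computed per segment (arms, spacers):

* **length-based**: \( E(L, r) = L\,r \), with `L` the merged footprint bp
  of the segment and `r` the genome-wide SNV site density;
* **trinucleotide-adjusted**: \( E[X] = \sum_{j=1}^{32} c_j\,p_j \), where
  the 32 canonical trinucleotide classes are the lexicographic minima of
  each triplet and its reverse complement, \(p_j\) is the genome-wide
  per-class substitution frequency, and \(c_j\) counts segment positions
  in class `j`.

Positions lacking a full N-free context (sequence ends, N neighbors) are
excluded symmetrically from both the class occurrence totals and the
segment counts, which keeps \(p_j\) unbiased. A base covered by an arm of
one IR and the spacer of another is assigned to arms — arm pairing
constrains the base — with `arm_precedence = FALSE` available to study
the other convention.

Per-species enrichment of SNVs within IR loci uses a two-tailed Fisher's
exact test on the 2×2 table of observed versus expected sites inside/
outside the footprint; the fractional expectation is rounded half away
from zero to form counts, and the reported odds ratio is the sample
cross-product ratio of that table. Terminator-proximal stratification
partitions IRs at an inclusive 50-bp distance from the nearest terminator
interval, and near-versus-far SNV densities are compared across species
with the unpaired Cliff's δ, optionally per spacer-length stratum.

The regression-deviation ratio summarizes, across species, how far the
observed-versus-expected regression strays from the identity line:
through-origin least-squares slopes (the 45° comparison presumes a zero
intercept) for arms and spacers, and
\( R = |\arctan(b_\text{spacer}) - \pi/4| \,/\,
       |\arctan(b_\text{arm}) - \pi/4| \).
Which segment belongs in the numerator is interpretation sensitive, so
both orientations are returned; `R` is spacer-over-arm. An arm slope of
exactly 1 makes the ratio undefined and is flagged.

## The synthetic-data generator

Every stage is testable without downloads because `simulate_genome()`
produces genomes whose ground truth is exact:

* background residues i.i.d. or first-order Markov (a mild CpG-depleted
  transition matrix is provided so dinucleotide-sensitive tests are
  non-trivial); default GC 0.5;
* planted IRs with chosen arm/spacer lengths and arm GC, flanked by guard
  bases that cannot base-pair, so the planted arm **is** the maximal arm
  at that center; for spacers ≥ 2 the spacer ends are forced
  non-complementary so the planted (center, spacer) is itself maximal;
  uniform placements go largest-first into unfragmented space, anchored
  placements sit at a fixed strand-oriented offset from a gene's TSS/TES;
* single-exon gene models with configurable lengths, intergenic gaps,
  strand pattern and UTR margins; terminator intervals at a fixed offset
  after each TES;
* SNVs drawn per position with per-class trinucleotide rates, a spacer
  rate multiplier `m >= 1`, and an arm multiplier (below 1 emulates arm
  conservation, e.g. near terminators).

Accidental background IRs are not suppressed: the emitted truth table is
the detector's scan of the final genome, so recall is always measured
against complete truth. Everything is deterministic given the spec seed.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: repeat families and
transposable elements (which dominate real IR landscapes), GC skew and
replication-strand asymmetries, phylogenetic correlation between strains
(SNV sites are independent draws), indels, assembly errors, and
multi-isoform gene structure. The generator validates the machinery, not
the biology.

### Problem sizes

The shipped tests run at sizes chosen to exercise every code path while
keeping a full run in the low minutes: oracle equivalence on 200 random
2-kb sequences; planted-IR recovery with 50 IRs spanning arms 10 bp to
10 kb in a 120-kb genome; shuffle invariants over 1,000 independent 1-kb
chunks; burden-multiplier recovery (m = 1, 2, 4) over 10 replicates of a
50-kb genome carrying 80 IRs at per-class rates of 0.005; topography
recovery over 20 genomes of 8 genes each with IRs planted 50 bp upstream
of every TSS, and 1,000-replicate bootstrap bands. Statistical
recovery checks assert agreement within three binomial standard errors
under a fixed seed.

## Numerical and design choices

* **Coordinates** are 1-based closed everywhere inside the package — the
  IRanges convention — with BED (0-based half-open) and GFF3/VCF (1-based)
  converted only at the readers and writers. One convention, converted at
  the boundary, is the point; fighting the interval library's convention
  internally would manufacture off-by-one risk.
* **Determinism**: detector output is sorted by start then spacer; all
  randomized steps (shuffle, generator, bootstrap) take explicit seeds and
  restore the caller's RNG state.
* **Degenerate inputs** are flagged, not fatal: zero-length regions,
  zero-variance differences, all-N sequences, zero window means,
  zero-margin exact-test tables and unit regression slopes all return
  `NA` with a warning.
* **Ties and rounding**: Cliff's δ counts ties exactly as its formula
  prescribes; expected counts entering Fisher's table round half away
  from zero.
* Chunks shorter than 2 bp (and single-symbol chunks) are their own
  unique arrangement and are returned unchanged by the shuffle.

## Limitations

Only perfect IRs are considered; arm mismatches, mirror/direct repeats
and other non-B motif classes are out of scope. Circular replicons are
scanned as linear sequences. The pipeline ingests variant *sites*, not
genotypes, and applies no phylogenetic correction for strain
non-independence. Lineage information is consumed from a plain TSV;
taxonomy retrieval is a separate concern. At genome scales far beyond
desk scale (hundreds of Mb), the per-position trinucleotide
classification and the pure-R shuffle become the practical bottlenecks.
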