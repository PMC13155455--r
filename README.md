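# irtopo — perfect inverted repeats and their genomic topography

`irtopo` is an R package for scientists studying non-B DNA: it detects
**perfect inverted repeats** (IRs) — two arms that are exact reverse
complements separated by a short spacer, the sequence class that extrudes
hairpins and cruciforms and drives rho-independent transcription
termination in bacteria — and characterizes where they sit in a genome
and how they evolve.

Around the detector, the package implements a complete analysis pipeline:

* **Detection** of all *maximal* perfect IRs with arm length ≥ `min_arm`
  (default 10 bp) and spacer ≤ `max_spacer` (default 8 bp); an IR is
  maximal when its arms can be extended neither outward by one
  complementary pair nor inward at the spacer's expense.
* **Null model** for abundance: dinucleotide-preserving shuffled control
  genomes built by an exact Euler-walk shuffle in independent 1-kb
  chunks, and the enrichment statistic
  `FE(O, E) = (O − E) / (O + E) ∈ [−1, 1]` (0 when `O = E`).
* **Effect sizes and tests**: paired Hedges' `g = J(N−1)·mean(d)/sd(d)`
  with `J(n) = 1 − 3/(4n − 1)`, paired Cliff's
  `δ = 2P(X>Y) + P(X=Y) − 1`, its unpaired cross-pair form, two-sided
  Wilcoxon signed-rank tests with Benjamini–Hochberg adjustment, and
  two-level taxonomic aggregation `F(R) = mean of species densities`.
* **Topography**: IR density per kB in merged genic / intergenic /
  exonic / intronic / CDS / UTR compartments, and strand-oriented
  positional profiles in ±500 bp windows around TSS/TES (±100 bp around
  Term-seq POTs), normalized by the window mean, with two-stage
  (family, then species) bootstrap confidence bands.
* **SNV burden**: observed intraspecific SNV sites in IR arms versus
  spacers against a length-based null `E(L, r) = L·r` and a
  trinucleotide-adjusted null `E[X] = Σ c_j p_j` over the 32 canonical
  trinucleotide classes; Fisher's exact enrichment per species,
  terminator-proximal stratification (inclusive 50-bp rule), and the
  regression-deviation ratio `R = |atan(b_spacer) − π/4| /
  |atan(b_arm) − π/4|`.
* **Synthetic data**: a generator for genomes with guard-flanked planted
  IRs, gene models, terminators, lineages and trinucleotide-rate SNVs,
  with exact ground truth — every pipeline stage is testable offline.

Standard formats are read through the usual Bioconductor stack
(FASTA via Biostrings, GFF3 via rtracklayer, VCF via vcfR, intervals via
IRanges); gzip input is accepted everywhere.

## Worked example

Simulate a 50-kb genome with 25 planted IRs, detect, compare against the
shuffled control, and measure SNV burden with a 4× elevated spacer
mutation rate:

```r
library(irtopo)

spec <- simulation_spec(
  seed = 42, genome_length = 50000,
  planted_irs = data.frame(arm_length = c(12L, 20L), spacer_length = c(8L, 0L),
                           arm_gc = 0.5, count = c(20L, 5L),
                           placement = "uniform", offset = NA_integer_))
sim <- simulate_genome(spec)

irs <- detect_inverted_repeats(sim$genome)
head(irs[, 1:5], 3)
#>   seq_id start   end arm_length spacer_length
#> 1    syn  9382  9413         12             8
#> 2    syn 10813 10844         12             8
#> 3    syn 12871 12893         10             3

obs <- sum(IRanges::width(ir_footprint(irs)))
ir_density_per_kb(obs, genome_length(sim$genome))
#> [1] 17.26

ctrl <- shuffle_genome(sim$genome, shuffle_params(seed = 7))
exp_bp <- sum(IRanges::width(ir_footprint(detect_inverted_repeats(ctrl))))
enrichment_fe(obs, exp_bp)
#> [1] 1

snvs <- simulate_snvs(sim$genome, sim$truth_irs, p = 0.01,
                      spacer_multiplier = 4, seed = 9)
burden_tables(sim$truth_irs, snvs, sim$genome)[,
  c("segment", "L", "observed", "expected_length", "expected_trinuc")]
#>   segment   L observed expected_length expected_trinuc
#> 1    arms 700        4           6.902           6.816
#> 2 spacers 163        6           1.607           1.577
```

Reading the output: the detector found 26 IRs (the 25 planted plus one
background hit), a footprint of 863 bp, i.e. 17.3 IR bp/kB. The shuffled
control of this genome contains no IRs at the default thresholds, so the
enrichment statistic is at its maximum of 1. In the burden table the
spacers carry 6 observed SNV sites against ≈1.6 expected under the
trinucleotide-adjusted null — recovering the simulated 4× spacer rate —
while the arms sit at or below their expectation.

A full multi-assembly run (detect → shuffle → enrich → topography →
burden, with TSV/BED/JSON outputs) goes through `run_manifest()` +
`run_pipeline()`, or the thin CLI in `inst/scripts/irtopo.R`
(`detect`, `shuffle`, `run` subcommands).

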