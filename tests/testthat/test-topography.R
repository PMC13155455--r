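test_that("compartments partition the genome as defined", {
  g1 <- gene_record("g1", "c", 101, 200)
  comps <- derive_compartments(list(g1), 1000)
  bp <- compartment_bp(comps)
  expect_equal(unname(bp["genic"]), 100L)
  expect_equal(unname(bp["intergenic"]), 900L)
  expect_equal(unname(bp["genome"]), 1000L)
  expect_error(derive_compartments(list(gene_record("g", "c", 900, 1200)),
                                   1000),
               "beyond genome end")
})

test_that("UTRs are the strand-aware exonic flanks of the CDS", {
  mk <- function(strand) {
    gene_record("g", "c", 101, 200, strand = strand,
                exons = IRanges::IRanges(101, 200),
                cds = IRanges::IRanges(121, 180))
  }
  plus <- derive_compartments(list(mk("+")), 500)
  expect_equal(IRanges::start(plus$utr5), 101L)
  expect_equal(IRanges::end(plus$utr5), 120L)
  expect_equal(IRanges::start(plus$utr3), 181L)
  expect_equal(IRanges::end(plus$utr3), 200L)
  minus <- derive_compartments(list(mk("-")), 500)
  expect_equal(IRanges::start(minus$utr5), 181L)
  expect_equal(IRanges::end(minus$utr5), 200L)
  expect_equal(IRanges::start(minus$utr3), 101L)
  expect_equal(IRanges::end(minus$utr3), 120L)
})

test_that("compartment bp conservation holds on generated annotations", {
  set.seed(13)
  for (rep in 1:3) {
    spec <- simulation_spec(seed = 100 + rep, genome_length = 20000L,
                            planted_irs = NULL,
                            gene_model = list(n_genes = 8L, gene_length = 900L,
                                              intergenic_length = 400L,
                                              strand = "random",
                                              utr5_length = 50L,
                                              utr3_length = 70L))
    sim <- simulate_genome(spec)
    comps <- derive_compartments(sim$genes, genome_length(sim$genome))
    bp <- compartment_bp(comps)
    expect_equal(unname(bp["genic"] + bp["intergenic"]),
                 unname(bp["genome"]))
    expect_equal(unname(bp["exonic"] + bp["intronic"]), unname(bp["genic"]))
  }
})

test_that("compartment densities split straddling IRs proportionally", {
  g1 <- gene_record("g1", "c", 101, 200)
  comps <- derive_compartments(list(g1), 1000)
  # IR [91,110]: 10 bp intergenic + 10 bp genic
  fp <- IRanges::IRanges(91, 110)
  expect_warning(tab <- compartment_density(fp, comps), "zero-length")
  expect_equal(tab$ir_bp[tab$compartment == "genic"], 10L)
  expect_equal(tab$density[tab$compartment == "genic"], 1000 * 10 / 100)
  expect_equal(tab$ir_bp[tab$compartment == "intergenic"], 10L)
  expect_equal(tab$density[tab$compartment == "genome"], 1000 * 20 / 1000)
  # no IRs -> all zero
  tab0 <- suppressWarnings(compartment_density(IRanges::IRanges(), comps))
  expect_true(all(tab0$density[!is.na(tab0$density)] == 0))
})

test_that("a single covered stretch yields the hand-computed enrichment", {
  gene <- gene_record("g", "c", 1001, 1600, strand = "+")
  # IR footprint at genomic [941, 964] = strand offsets -60..-37 (24 bp)
  fp <- IRanges::IRanges(941, 964)
  pr <- positional_profile(fp, list(gene), "TSS", window = 500,
                           genome_length = 3000)
  expect_equal(sum(pr$raw), 24)
  covered <- pr$offsets >= -60 & pr$offsets <= -37
  expect_true(all(pr$raw[covered] == 1))
  expect_true(all(pr$raw[!covered] == 0))
  expect_equal(unique(pr$enrichment[covered]), 1001 / 24)
  expect_equal(mean(pr$enrichment), 1)
})

test_that("profiles are strand oriented and flag empty windows", {
  # minus-strand gene: TSS at the gene end; footprint downstream in genome
  # coordinates is upstream in strand coordinates
  gene <- gene_record("g", "c", 1001, 1600, strand = "-")
  fp <- IRanges::IRanges(1651, 1660)   # 50..60 bp beyond the 3' genomic end
  pr <- positional_profile(fp, list(gene), "TSS", window = 500,
                           genome_length = 3000)
  expect_true(all(which(pr$raw > 0) %in%
                    which(pr$offsets >= -60 & pr$offsets <= -51)))
  # uniform coverage normalizes to exactly 1
  pr2 <- positional_profile(IRanges::IRanges(1, 3000), list(gene), "TSS",
                            window = 500, genome_length = 3000)
  expect_true(all(pr2$enrichment == 1))
  # empty coverage -> flagged
  expect_warning(
    pr3 <- positional_profile(IRanges::IRanges(), list(gene), "TSS",
                              window = 500, genome_length = 3000),
    "window mean is zero")
  expect_true(pr3$flagged)
})

test_that("anchors with truncated windows are dropped not zero-padded", {
  genes <- list(gene_record("g1", "c", 50, 400),     # window overruns start
                gene_record("g2", "c", 1001, 1400))
  fp <- IRanges::IRanges(600, 640)
  expect_message(
    pr <- positional_profile(fp, genes, "TSS", window = 500,
                             genome_length = 2000),
    "dropped 1 anchor")
  expect_equal(pr$n_anchors, 1L)
  expect_error(positional_profile(fp, genes[1], "TSS", window = 500,
                                  genome_length = 520))
})

test_that("aggregation is a per-offset mean and permutation invariant", {
  gene <- gene_record("g", "c", 1001, 1600)
  p1 <- positional_profile(IRanges::IRanges(941, 964), list(gene), "TSS",
                           window = 500, genome_length = 3000)
  p2 <- positional_profile(IRanges::IRanges(1, 3000), list(gene), "TSS",
                           window = 500, genome_length = 3000)
  agg <- aggregate_profiles(list(p1, p2))
  expect_equal(agg$enrichment, (p1$enrichment + p2$enrichment) / 2)
  expect_equal(aggregate_profiles(list(p2, p1))$enrichment, agg$enrichment)
  same <- aggregate_profiles(list(p1, p1))
  expect_equal(same$enrichment, p1$enrichment)
  expect_equal(mean(agg$enrichment), 1)
})

test_that("two-stage bootstrap bands are reproducible and degenerate correctly", {
  gene <- gene_record("g", "c", 1001, 1600)
  mk <- function(fp_start) {
    positional_profile(IRanges::IRanges(fp_start, fp_start + 23), list(gene),
                       "TSS", window = 500, genome_length = 3000)
  }
  profiles <- list(s1 = mk(941), s2 = mk(901), s3 = mk(1101), s4 = mk(1301))
  lineage <- data.frame(species = c("s1", "s2", "s3", "s4"),
                        family = c("f1", "f1", "f2", "f2"))
  ci_a <- bootstrap_ci(profiles, lineage, n_boot = 100, seed = 5)
  ci_b <- bootstrap_ci(profiles, lineage, n_boot = 100, seed = 5)
  expect_identical(ci_a, ci_b)
  expect_true(all(ci_a$ci_low <= ci_a$ci_high))

  # all-identical profiles collapse the bands onto the profile
  same <- list(s1 = mk(941), s2 = mk(941), s3 = mk(941), s4 = mk(941))
  ci_s <- bootstrap_ci(same, lineage, n_boot = 20, seed = 1)
  expect_equal(ci_s$ci_low, same$s1$enrichment)
  expect_equal(ci_s$ci_high, same$s1$enrichment)

  # n_boot = 1: both bands equal that single replicate
  ci_1 <- bootstrap_ci(profiles, lineage, n_boot = 1, seed = 2)
  expect_equal(ci_1$ci_low, ci_1$ci_high)

  # single family falls back to species-only resampling with a warning
  lin1 <- data.frame(species = names(profiles), family = "f1")
  expect_warning(bootstrap_ci(profiles, lin1, n_boot = 10, seed = 3),
                 "single family")
})

test_that("POT profiles anchor at the termination point", {
  # IR ending 10 bp upstream of every POT
  pots <- data.frame(seq_id = "c", start = c(500L, 1500L), end = c(500L, 1500L))
  fp <- IRanges::reduce(IRanges::IRanges(c(466, 1466), c(489, 1489)))
  pr <- pot_profile(fp, pots, window = 100, genome_length = 3000)
  expect_equal(length(pr$offsets), 201L)
  expect_true(all(pr$offsets[pr$raw > 0] < 0))
  expect_equal(pr$anchor, "POT")
  expect_error(pot_profile(fp, pots[0, ], window = 100, genome_length = 3000),
               "empty POT")
})
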