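test_that("there are exactly 32 canonical trinucleotide classes", {
  canon <- canonical_trinucleotides()
  expect_length(canon, 32L)
  expect_true(all(canon == sort(canon)))
  # each class is its own canonical form
  expect_equal(pmin(canon, reverse_complement(canon)), canon)
  # the 64 trinucleotides collapse onto the 32 classes
  b <- c("A", "C", "G", "T")
  tri <- as.vector(outer(outer(b, b, paste0), b, paste0))
  expect_setequal(unique(pmin(tri, reverse_complement(tri))), canon)
})

test_that("the trinucleotide profile classifies contexts canonically", {
  g <- genome_seq("g", "AAAA")
  snvs <- data.frame(seq_id = "g", pos = 2L, ref = "A", alt = "G")
  pr <- suppressWarnings(trinucleotide_profile(g, snvs))
  expect_equal(unname(pr$genome_occ["AAA"]), 2L)
  expect_equal(unname(pr$p["AAA"]), 0.5)
  # a TTT context maps to the AAA class
  g2 <- genome_seq("g", "TTTT")
  pr2 <- suppressWarnings(trinucleotide_profile(g2, data.frame(pos = integer(0))))
  expect_equal(unname(pr2$genome_occ["AAA"]), 2L)
  # N voids the context
  g3 <- genome_seq("g", "ANAA")
  pr3 <- suppressWarnings(trinucleotide_profile(g3, data.frame(pos = integer(0))))
  expect_equal(sum(pr3$genome_occ), 0L)
})

test_that("genome SNV density collapses duplicate positions", {
  g <- genome_seq("g", strrep("ACGT", 2500))
  snvs <- data.frame(pos = c(rep(5L, 3), seq(100L, 900L, 100L)))
  expect_equal(genome_snv_density(snvs, g), 10 / 10000)
  expect_equal(genome_snv_density(data.frame(pos = integer(0)), g), 0)
})

test_that("expected trinucleotide burden equals the per-position oracle", {
  set.seed(41)
  for (rep in 1:3) {
    g <- genome_seq("g", random_dna(5000))
    n <- genome_length(g)
    snvs <- data.frame(seq_id = "g", pos = sample.int(n, 60),
                       ref = "A", alt = "G")
    pr <- suppressWarnings(trinucleotide_profile(g, snvs))
    rng <- IRanges::reduce(IRanges::IRanges(sort(sample.int(n - 60, 8)),
                                            width = sample(5:40, 8, TRUE)))
    got <- expected_burden_trinuc(rng, pr)
    # oracle: walk every position, take its centered context directly
    oracle <- 0
    for (p in unlist(lapply(seq_along(rng), function(i)
      IRanges::start(rng)[i]:IRanges::end(rng)[i]))) {
      if (p < 2 || p > n - 1) next
      ctx <- substring(g$residues, p - 1, p + 1)
      if (grepl("N", ctx)) next
      cls <- min(ctx, oracle_revcomp(ctx))
      oracle <- oracle + pr$p[[cls]]
    }
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # degenerate cases
  g <- genome_seq("g", random_dna(100))
  pr0 <- suppressWarnings(trinucleotide_profile(g, data.frame(pos = integer(0))))
  expect_equal(expected_burden_trinuc(IRanges::IRanges(10, 50), pr0), 0)
})

test_that("arm/spacer segments partition with arm precedence", {
  irs <- data.frame(seq_id = "g", start = 11L, end = 34L,
                    arm_length = 10L, spacer_length = 4L)
  segs <- ir_segments(irs)
  expect_equal(sum(IRanges::width(segs$arms)), 20L)
  expect_equal(sum(IRanges::width(segs$spacers)), 4L)
  expect_equal(IRanges::start(segs$spacers), 21L)
  expect_equal(IRanges::end(segs$spacers), 24L)
  # overlap: the arm of one IR covering another's spacer wins
  irs2 <- rbind(irs, data.frame(seq_id = "g", start = 19L, end = 46L,
                                arm_length = 12L, spacer_length = 4L))
  segs2 <- ir_segments(irs2)
  expect_equal(sum(IRanges::width(IRanges::intersect(segs2$arms,
                                                     segs2$spacers))), 0L)
  no_prec <- ir_segments(irs2, arm_precedence = FALSE)
  expect_gt(sum(IRanges::width(IRanges::intersect(no_prec$arms,
                                                  no_prec$spacers))), 0L)
})

test_that("burden tables count observed sites and both expectations", {
  set.seed(43)
  g <- genome_seq("g", random_dna(10000))
  irs <- data.frame(seq_id = "g", start = c(101L, 1001L),
                    end = c(124L, 1024L),
                    arm_length = 10L, spacer_length = 4L)
  # one SNV in a spacer, one in an arm, 98 elsewhere
  spacer_pos <- 111L; arm_pos <- 1005L
  other <- setdiff(seq(2000L, 9999L, by = 80L), c(spacer_pos, arm_pos))
  snvs <- data.frame(seq_id = "g", pos = c(spacer_pos, arm_pos, other),
                     ref = "A", alt = "G")
  bt <- burden_tables(irs, snvs, g)
  expect_equal(bt$observed[bt$segment == "spacers"], 1L)
  expect_equal(bt$observed[bt$segment == "arms"], 1L)
  expect_equal(bt$L, c(40L, 8L))
  r <- length(unique(snvs$pos)) / 10000
  expect_equal(bt$expected_length, bt$L * r)
  expect_true(all(bt$expected_trinuc >= 0))
  # hand arithmetic: L = 100, r = 0.01 -> 1.0
  expect_equal(100 * 0.01, 1.0)

  # no SNVs at all
  bt0 <- burden_tables(irs, snvs[0, ], g)
  expect_equal(bt0$observed, c(0L, 0L))
  expect_equal(bt0$expected_length, c(0, 0))
})

test_that("Fisher enrichment table uses the sample odds ratio", {
  res <- fisher_ir_enrichment(10, 5, 100)
  expect_equal(res$odds_ratio, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_false(res$flagged)
  expect_true(res$p >= 0 && res$p <= 1)
  # observed equals expected -> OR 1
  expect_equal(fisher_ir_enrichment(10, 10, 100)$odds_ratio, 1)
  # fractional expectation rounds half away from zero
  expect_equal(fisher_ir_enrichment(10, 4.5, 100)$table["expected", "in_ir"], 5)
  expect_warning(res0 <- fisher_ir_enrichment(0, 0, 100), "degenerate")
  expect_true(res0$flagged)
})

test_that("terminator proximity is inclusive at the distance threshold", {
  terms <- data.frame(seq_id = "g", start = 200L, end = 230L)
  mk_ir <- function(s, e) data.frame(seq_id = "g", start = s, end = e,
                                     arm_length = 10L,
                                     spacer_length = as.integer(e - s + 1 - 20))
  # IR ending exactly 50 bp before the terminator start: gap = 50 -> near
  at50 <- mk_ir(126L, 149L)
  tab <- terminator_partition_density(at50, data.frame(pos = integer(0)),
                                      terms)
  expect_equal(tab$n_irs[tab$group == "near"][1], 1L)
  # gap = 51 -> far
  at51 <- mk_ir(125L, 148L)
  tab2 <- terminator_partition_density(at51, data.frame(pos = integer(0)),
                                       terms)
  expect_equal(tab2$n_irs[tab2$group == "near"][1], 0L)
  # no terminators: everything is far
  tab3 <- terminator_partition_density(at50, data.frame(pos = integer(0)),
                                       NULL)
  expect_equal(tab3$n_irs[tab3$group == "far"][1], 1L)
  # spacer stratification
  tab4 <- terminator_partition_density(rbind(at50, at51),
                                       data.frame(pos = 136L), terms,
                                       by_spacer = TRUE)
  expect_true(all(tab4$stratum == "4"))
  near_sp <- tab4[tab4$group == "near" & tab4$segment == "spacers", ]
  expect_equal(near_sp$snv_sites, 1L)
})

test_that("regression deviation ratio handles the canonical slopes", {
  x <- c(1, 2, 3, 4)
  # spacer slope exactly 1, arm slope 2 -> R = 0
  res <- regression_deviation_ratio(2 * x, x, x, x)
  expect_equal(res$R, 0)
  # equal angular deviations on either side of 45 degrees -> R = 1
  res2 <- regression_deviation_ratio(tan(pi / 6) * x, x, tan(pi / 3) * x, x)
  expect_equal(res2$R, 1, tolerance = 1e-12)
  # arm slope exactly 1 -> flagged
  expect_warning(res3 <- regression_deviation_ratio(x, x, 2 * x, x),
                 "undefined")
  expect_true(res3$flagged)
  expect_true(is.na(res3$R))
})
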