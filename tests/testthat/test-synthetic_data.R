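test_that("generation is deterministic and planted IRs validate", {
  spec <- simulation_spec(seed = 7L, genome_length = 15000L,
                          planted_irs = data.frame(arm_length = 12L,
                                                   spacer_length = 4L,
                                                   arm_gc = 0.5, count = 5L,
                                                   placement = "uniform",
                                                   offset = NA_integer_),
                          gene_model = NULL, terminator = NULL)
  sim1 <- simulate_genome(spec)
  sim2 <- simulate_genome(spec)
  expect_identical(sim1$genome$residues, sim2$genome$residues)
  expect_identical(sim1$truth_irs, sim2$truth_irs)
  expect_equal(nrow(sim1$planted), 5L)
  for (i in 1:5) expect_true(validate_ir(sim1$planted[i, ], sim1$genome))
})

test_that("the truth table is the complete scan of the emitted genome", {
  spec <- simulation_spec(seed = 19L, genome_length = 20000L,
                          gene_model = NULL, terminator = NULL)
  sim <- simulate_genome(spec)
  # truth = detector output; spot-check against the diagonal enumerator on
  # a window containing a planted IR plus background
  ir1 <- sim$planted[1, ]
  lo <- max(1L, ir1$start - 300L); hi <- min(genome_length(sim$genome),
                                             ir1$end + 300L)
  windowed <- ir_oracle(substring(sim$genome$residues, lo, hi))
  windowed$start <- windowed$start + lo - 1L
  windowed$end <- windowed$end + lo - 1L
  truth_in <- sim$truth_irs[sim$truth_irs$start >= lo + 30 &
                              sim$truth_irs$end <= hi - 30, ]
  key <- function(df) paste(df$start, df$end, df$arm_length, df$spacer_length)
  expect_true(all(key(truth_in) %in% key(windowed)))
})

test_that("anchored planting puts the IR at the requested strand offset", {
  spec <- simulation_spec(seed = 3L, genome_length = 30000L,
                          planted_irs = NULL,
                          gene_model = list(n_genes = 6L, gene_length = 900L,
                                            intergenic_length = 600L,
                                            strand = "alternate",
                                            utr5_length = 60L,
                                            utr3_length = 60L),
                          terminator = NULL)
  sim <- simulate_genome(spec)
  g_plus <- sim$genes[[1]]; g_minus <- sim$genes[[2]]
  res <- plant_ir_at_offset(sim$genome, g_plus, "TSS", -50, 10, 4)
  expect_lte(res$ir$end, g_plus$start)        # fully upstream on + strand
  expect_equal(res$ir$end, g_plus$start - 50L)
  det <- detect_inverted_repeats(res$genome)
  expect_true(any(det$start == res$ir$start & det$end == res$ir$end &
                    det$arm_length == 10L))
  res2 <- plant_ir_at_offset(sim$genome, g_minus, "TSS", -50, 10, 4)
  expect_gte(res2$ir$start, g_minus$end)      # reflected for - strand
  expect_equal(res2$ir$start, g_minus$end + 50L)
})

test_that("infeasible packing errors with a required minimum length", {
  spec <- simulation_spec(seed = 1L, genome_length = 400L,
                          planted_irs = data.frame(arm_length = 40L,
                                                   spacer_length = 8L,
                                                   arm_gc = 0.5, count = 10L,
                                                   placement = "uniform",
                                                   offset = NA_integer_),
                          gene_model = NULL, terminator = NULL)
  expect_error(simulate_genome(spec), "required|place")
})

test_that("emitted files parse back through the package readers", {
  spec <- simulation_spec(seed = 23L, genome_length = 25000L,
                          gene_model = list(n_genes = 5L, gene_length = 900L,
                                            intergenic_length = 500L,
                                            strand = "alternate",
                                            utr5_length = 60L,
                                            utr3_length = 60L))
  sim <- simulate_genome(spec)
  dir <- tempfile(); dir.create(dir)
  write_fasta(sim$genome, file.path(dir, "g.fa"))
  write_gff3(sim$genes, file.path(dir, "g.gff3"))
  write_lineage_tsv(sim$lineage, file.path(dir, "lin.tsv"))
  expect_silent(gg <- read_fasta(file.path(dir, "g.fa")))
  expect_identical(gg[[1]]$residues, sim$genome$residues)
  expect_silent(genes <- read_gff3(file.path(dir, "g.gff3")))
  expect_equal(length(genes), 5L)
  expect_silent(li <- read_lineage_tsv(file.path(dir, "lin.tsv")))
  expect_equal(li$assembly_id, sim$lineage$assembly_id)
})

test_that("simulated SNVs respect rates and round-trip through VCF", {
  spec <- simulation_spec(seed = 31L, genome_length = 20000L,
                          gene_model = NULL, terminator = NULL,
                          planted_irs = data.frame(arm_length = 12L,
                                                   spacer_length = 8L,
                                                   arm_gc = 0.5, count = 30L,
                                                   placement = "uniform",
                                                   offset = NA_integer_))
  sim <- simulate_genome(spec)
  # zero rate -> no sites
  none <- simulate_snvs(sim$genome, sim$truth_irs, p = 0, seed = 1)
  expect_equal(nrow(none), 0L)

  snvs <- simulate_snvs(sim$genome, sim$truth_irs, p = 0.01, seed = 2)
  expect_gt(nrow(snvs), 50L)
  expect_true(all(snvs$ref != snvs$alt))
  f <- tempfile(fileext = ".vcf")
  write_snv_vcf(snvs, f)
  suppressMessages(back <- read_vcf_filtered(f))
  expect_equal(back$pos, snvs$pos)
  expect_equal(back$alt, snvs$alt)

  # with multiplier 1 the arm and spacer empirical rates agree within
  # 3 binomial SEs over replicates
  segs <- ir_segments(sim$truth_irs)
  arm_bp <- sum(IRanges::width(segs$arms))
  sp_bp <- sum(IRanges::width(segs$spacers))
  arm_hits <- 0; sp_hits <- 0
  for (r in 1:10) {
    sv <- simulate_snvs(sim$genome, sim$truth_irs, p = 0.01,
                        spacer_multiplier = 1, seed = 100 + r)
    arm_hits <- arm_hits + sum(irtopo:::.pos_in_ranges(sv$pos, segs$arms))
    sp_hits <- sp_hits + sum(irtopo:::.pos_in_ranges(sv$pos, segs$spacers))
  }
  rate_arm <- arm_hits / (10 * arm_bp)
  rate_sp <- sp_hits / (10 * sp_bp)
  se <- sqrt(0.01 * 0.99 * (1 / (10 * arm_bp) + 1 / (10 * sp_bp)))
  expect_lt(abs(rate_arm - rate_sp), 3 * se)
})
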