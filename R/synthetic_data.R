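# Synthetic-data generator: genomes with controlled composition, planted
# IRs (guard-flanked so the planted arm is the maximal arm), gene models,
# terminators, trinucleotide-rate variants and lineages. Every emitted
# object parses back through the package's own readers, and the truth IR
# table is the detector scan of the final genome, so accidental background
# IRs are part of the truth rather than silently ignored.

#' Random background genome sequence
#'
#' Draws residues i.i.d. from mononucleotide frequencies, or from a
#' first-order Markov chain when a 4x4 transition matrix is supplied
#' (rows = current base A,C,G,T; rows must sum to 1). A mild CpG-depleted
#' transition matrix is available via [cpg_depleted_transitions()] to make
#' dinucleotide-sensitive tests non-trivial.
#'
#' @param length Sequence length in bp.
#' @param freqs Named mononucleotide frequencies (default uniform,
#'   GC = 0.5).
#' @param transitions Optional 4x4 transition matrix (overrides `freqs`
#'   beyond the first base).
#' @param seq_id Identifier for the record.
#' @return A [genome_seq()].
#' @export
random_genome <- function(length, freqs = c(A = 0.25, C = 0.25, G = 0.25,
                                            T = 0.25),
                          transitions = NULL, seq_id = "synthetic") {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  b <- c("A", "C", "G", "T")
  freqs <- freqs[b] / sum(freqs[b])
  if (is.null(transitions)) {
    chars <- sample(b, length, replace = TRUE, prob = freqs)
  } else {
    stopifnot(all(dim(transitions) == c(4L, 4L)))
    rownames(transitions) <- colnames(transitions) <- b
    chars <- character(length)
    chars[1L] <- sample(b, 1L, prob = freqs)
    for (i in seq_len(length - 1L)) {
      chars[i + 1L] <- sample(b, 1L, prob = transitions[chars[i], ])
    }
  }
  genome_seq(seq_id, .c2s(chars))
}

#' CpG-depleted first-order transition matrix
#'
#' Uniform transitions with the C->G probability multiplied by
#' `depletion` and renormalized, emulating the CpG depletion seen in many
#' real genomes.
#'
#' @param depletion Multiplier on the C->G transition (default 0.25).
#' @return A 4x4 row-stochastic matrix over A,C,G,T.
#' @export
cpg_depleted_transitions <- function(depletion = 0.25) {
  b <- c("A", "C", "G", "T")
  m <- matrix(0.25, 4, 4, dimnames = list(b, b))
  m["C", "G"] <- 0.25 * depletion
  m / rowSums(m)
}

# Random arm with a given GC fraction (in expectation).
.random_arm <- function(arm, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .c2s(sample(names(probs), arm, replace = TRUE, prob = probs))
}

# Overwrite genome residues at [start, start+len-1] (1-based) with `insert`
# and place non-pairing guard bases immediately outside the span.
.splice_ir <- function(residues, start, insert) {
  len <- nchar(insert)
  end <- start + len - 1L
  out <- paste0(substring(residues, 1L, start - 1L), insert,
                substring(residues, end + 1L, nchar(residues)))
  # guards: an A on both flanks never base-pairs with itself, so the
  # planted arms cannot extend outward
  if (start > 1L) substring(out, start - 1L, start - 1L) <- "A"
  if (end < nchar(out)) substring(out, end + 1L, end + 1L) <- "A"
  out
}

# Build the arm + spacer + revcomp(arm) insert; for spacers >= 2 the spacer
# ends are forced non-complementary so the planted IR cannot extend inward.
.ir_insert <- function(arm, spacer, arm_gc) {
  left <- .random_arm(arm, arm_gc)
  sp <- if (spacer > 0L) .random_arm(spacer, 0.5) else ""
  if (spacer >= 2L) {
    first <- substring(sp, 1L, 1L)
    # force last spacer base equal to first: X...X never pairs with itself
    substring(sp, spacer, spacer) <- first
  }
  paste0(left, sp, reverse_complement(left))
}

#' Plant a perfect IR at a fixed offset from a gene anchor
#'
#' Overwrites the target span with `arm + spacer + revcomp(arm)`, flanked
#' by guard bases that break outward extension. `offset` is strand-aware:
#' the 3'-most base of the IR span sits at `anchor + offset` in the
#' strand-oriented coordinate system (so `offset = -50` at a TSS places
#' the whole IR upstream, ending 50 bp before the anchor).
#'
#' @param genome A [genome_seq()].
#' @param gene A [gene_record()] supplying the anchor and strand.
#' @param anchor `"TSS"` or `"TES"`.
#' @param offset Signed offset in strand-oriented coordinates.
#' @param arm Arm length in bp.
#' @param spacer Spacer length in bp.
#' @param arm_gc Arm GC fraction (default 0.5).
#' @return List with the modified `genome` and the planted `ir` record
#'   (a one-row data.frame with `start`, `end`, `arm_length`,
#'   `spacer_length`).
#' @export
plant_ir_at_offset <- function(genome, gene, anchor = c("TSS", "TES"),
                               offset, arm, spacer, arm_gc = 0.5) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(genome, "genome_seq"), inherits(gene, "gene_record"))
  len <- 2L * as.integer(arm) + as.integer(spacer)
  apos <- if (anchor == "TSS") {
    if (gene$strand == "+") gene$start else gene$end
  } else {
    if (gene$strand == "+") gene$end else gene$start
  }
  if (gene$strand == "+") {
    end <- apos + as.integer(offset)
    start <- end - len + 1L
  } else {
    start <- apos - as.integer(offset)
    end <- start + len - 1L
  }
  if (start < 2L || end > genome_length(genome) - 1L) {
    stop("plant_ir_at_offset: planted span (with guards) outside genome")
  }
  insert <- .ir_insert(as.integer(arm), as.integer(spacer), arm_gc)
  genome$residues <- .splice_ir(genome$residues, start, insert)
  list(genome = genome,
       ir = data.frame(seq_id = genome$seq_id, start = start, end = end,
                       arm_length = as.integer(arm),
                       spacer_length = as.integer(spacer),
                       stringsAsFactors = FALSE))
}

#' Specification for a synthetic dataset
#'
#' Collects every knob of the generator with defaults that emulate a small
#' bacterial-like replicon: uniform GC = 0.5 background, genes of 900 bp
#' separated by 300 bp intergenic gaps, planted IRs with the detector's
#' default thresholds, uniform per-trinucleotide SNV rates and a spacer
#' rate multiplier of 1.
#'
#' @param seed Integer seed; the whole generation is deterministic given
#'   it.
#' @param genome_length Replicon length in bp.
#' @param background List: `freqs` (mononucleotide) and optional
#'   `transitions` (first-order Markov).
#' @param planted_irs Data.frame with columns `arm_length`,
#'   `spacer_length`, `arm_gc`, `count`, `placement` (`"uniform"`,
#'   `"tss_offset"` or `"tes_offset"`), `offset` (used by the anchored
#'   placements).
#' @param gene_model List: `n_genes`, `gene_length`, `intergenic_length`,
#'   `strand` (`"alternate"`, `"random"`, `"plus"`), `utr5_length`,
#'   `utr3_length`.
#' @param snv_model List: `p` (scalar rate or named vector over the 32
#'   canonical trinucleotide classes), `spacer_multiplier`.
#' @param terminator List: `offset` after the TES and interval `width`;
#'   `NULL` disables terminator placement.
#' @param assembly_id,species,family,phylum,kingdom,domain Lineage fields
#'   for the emitted lineage table.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            genome_length = 50000L,
                            background = list(freqs = c(A = 0.25, C = 0.25,
                                                        G = 0.25, T = 0.25),
                                              transitions = NULL),
                            planted_irs = data.frame(arm_length = 12L,
                                                     spacer_length = 4L,
                                                     arm_gc = 0.5,
                                                     count = 10L,
                                                     placement = "uniform",
                                                     offset = NA_integer_),
                            gene_model = list(n_genes = 20L,
                                              gene_length = 900L,
                                              intergenic_length = 300L,
                                              strand = "alternate",
                                              utr5_length = 60L,
                                              utr3_length = 60L),
                            snv_model = list(p = 0.005,
                                             spacer_multiplier = 1),
                            terminator = list(offset = 20L, width = 30L),
                            assembly_id = "SYN_001", species = "Synthia prima",
                            family = "Synthiaceae", phylum = "Synthibacteria",
                            kingdom = "", domain = "Bacteria") {
  spec <- list(seed = as.integer(seed),
               genome_length = as.integer(genome_length),
               background = background, planted_irs = planted_irs,
               gene_model = gene_model, snv_model = snv_model,
               terminator = terminator, assembly_id = assembly_id,
               species = species, family = family, phylum = phylum,
               kingdom = kingdom, domain = domain)
  stopifnot(spec$genome_length >= 100L)
  if (!is.null(spec$snv_model$spacer_multiplier)) {
    stopifnot(spec$snv_model$spacer_multiplier >= 1)
  }
  class(spec) <- "simulation_spec"
  spec
}

# Lay genes along the replicon; errors if they do not fit.
.layout_genes <- function(spec) {
  gm <- spec$gene_model
  if (is.null(gm) || gm$n_genes == 0L) return(list())
  need <- gm$n_genes * (gm$gene_length + gm$intergenic_length) +
    gm$intergenic_length
  if (need > spec$genome_length) {
    stop("simulate_genome: gene model needs at least ", need,
         " bp but genome_length is ", spec$genome_length)
  }
  genes <- vector("list", gm$n_genes)
  cursor <- gm$intergenic_length
  for (i in seq_len(gm$n_genes)) {
    start <- cursor + 1L
    end <- start + gm$gene_length - 1L
    cursor <- end + gm$intergenic_length
    strand <- switch(gm$strand,
                     alternate = if (i %% 2L == 1L) "+" else "-",
                     random = sample(c("+", "-"), 1L),
                     plus = "+")
    u5 <- gm$utr5_length; u3 <- gm$utr3_length
    cds <- if (strand == "+") {
      IRanges::IRanges(start + u5, end - u3)
    } else {
      IRanges::IRanges(start + u3, end - u5)
    }
    genes[[i]] <- gene_record(sprintf("g%03d", i), "syn", start, end,
                              strand = strand, biotype = "protein_coding",
                              exons = IRanges::IRanges(start, end), cds = cds)
  }
  genes
}

#' Generate a synthetic genome with planted IRs, genes and terminators
#'
#' Deterministic given the spec's seed. Planted IRs are guard-flanked so
#' the planted arm equals the maximal arm at that (center, spacer); the
#' emitted truth table is the detector's scan of the final genome, so
#' accidental background IRs are included rather than suppressed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `genome` ([genome_seq()]), `genes` (list of
#'   [gene_record()]), `planted` (data.frame of planted IR spans),
#'   `truth_irs` (full detector table of the final genome),
#'   `terminators` (data.frame `seq_id`, `start`, `end`, `strand`), and
#'   `lineage` (one-row data.frame).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$seed, {
    genome <- random_genome(spec$genome_length,
                            freqs = spec$background$freqs,
                            transitions = spec$background$transitions,
                            seq_id = "syn")
    genes <- .layout_genes(spec)

    occupied <- .empty_iranges()
    planted <- list()
    pir <- spec$planted_irs
    if (!is.null(pir) && nrow(pir) > 0L) {
      # anchored placements first (fixed coordinates), then uniform ones
      # largest-first so big spans are placed into unfragmented space
      span <- 2L * pir$arm_length + pir$spacer_length
      ord <- order(pir$placement != "uniform", span, decreasing = TRUE)
      pir <- pir[ord, , drop = FALSE]
      for (i in seq_len(nrow(pir))) {
        arm <- as.integer(pir$arm_length[i])
        sp <- as.integer(pir$spacer_length[i])
        gc <- pir$arm_gc[i]
        len <- 2L * arm + sp
        placement <- pir$placement[i]
        if (placement == "uniform") {
          for (copy in seq_len(pir$count[i])) {
            placed <- FALSE
            for (try in seq_len(2000L)) {
              s <- sample.int(spec$genome_length - len - 2L, 1L) + 1L
              cand <- IRanges::IRanges(s - 1L, s + len)
              if (!IRanges::overlapsAny(cand, occupied)) {
                genome$residues <- .splice_ir(genome$residues, s,
                                              .ir_insert(arm, sp, gc))
                occupied <- c(occupied, cand)
                planted[[length(planted) + 1L]] <- data.frame(
                  seq_id = "syn", start = s, end = s + len - 1L,
                  arm_length = arm, spacer_length = sp,
                  stringsAsFactors = FALSE)
                placed <- TRUE
                break
              }
            }
            if (!placed) {
              stop("simulate_genome: could not place planted IRs; ",
                   "genome_length of at least ",
                   sum(2L * pir$arm_length + pir$spacer_length + 2L) * 2L,
                   " bp is required")
            }
          }
        } else {
          anchor <- if (placement == "tss_offset") "TSS" else "TES"
          n_use <- min(pir$count[i], length(genes))
          if (n_use < pir$count[i]) {
            stop("simulate_genome: anchored placement needs ", pir$count[i],
                 " genes but only ", length(genes), " are modeled")
          }
          for (gidx in seq_len(n_use)) {
            res <- plant_ir_at_offset(genome, genes[[gidx]], anchor,
                                      offset = as.integer(pir$offset[i]),
                                      arm = arm, spacer = sp, arm_gc = gc)
            cand <- IRanges::IRanges(res$ir$start - 1L, res$ir$end + 1L)
            if (IRanges::overlapsAny(cand, occupied)) {
              stop("simulate_genome: anchored planted IRs overlap")
            }
            genome <- res$genome
            occupied <- c(occupied, cand)
            planted[[length(planted) + 1L]] <- res$ir
          }
        }
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 arm_length = integer(0), spacer_length = integer(0))

    terminators <- data.frame(seq_id = character(0), start = integer(0),
                              end = integer(0), strand = character(0))
    if (!is.null(spec$terminator) && length(genes) > 0L) {
      toff <- spec$terminator$offset; tw <- spec$terminator$width
      rows <- lapply(genes, function(g) {
        if (g$strand == "+") {
          s <- g$end + toff; e <- s + tw - 1L
        } else {
          e <- g$start - toff; s <- e - tw + 1L
        }
        if (s < 1L || e > spec$genome_length) return(NULL)
        data.frame(seq_id = "syn", start = s, end = e, strand = g$strand,
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) terminators <- do.call(rbind, rows)
    }

    truth <- detect_inverted_repeats(genome)
    lineage <- data.frame(assembly_id = spec$assembly_id,
                          species = spec$species, family = spec$family,
                          phylum = spec$phylum, kingdom = spec$kingdom,
                          domain = spec$domain, stringsAsFactors = FALSE)
    list(genome = genome, genes = genes, planted = planted,
         truth_irs = truth, terminators = terminators, lineage = lineage)
  })
}

#' Simulate intraspecific SNV sites with trinucleotide-dependent rates
#'
#' Every interior, N-free position carries an SNV with probability
#' `p_class(pos)`, multiplied by `spacer_multiplier` inside IR spacer
#' footprints and by `arm_multiplier` inside arm footprints (capped at 1
#' with a warning; an `arm_multiplier` below 1 emulates arm conservation).
#' Sites are binary indicators; alt bases are drawn uniformly from the
#' three non-reference bases, and MQ/QUAL are populated above the default
#' filter thresholds.
#'
#' @param genome A [genome_seq()].
#' @param irs IR table used to derive the arm/spacer footprints (may have
#'   zero rows).
#' @param p Scalar per-position rate, or a named vector over the 32
#'   canonical trinucleotide classes.
#' @param spacer_multiplier Rate multiplier inside spacer footprints
#'   (>= 1).
#' @param arm_multiplier Rate multiplier inside arm footprints (> 0,
#'   default 1).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `seq_id`, `pos`, `ref`, `alt`, `mq`,
#'   `qual`.
#' @export
simulate_snvs <- function(genome, irs, p = 0.005, spacer_multiplier = 1,
                          arm_multiplier = 1, seed = NULL) {
  stopifnot(inherits(genome, "genome_seq"), spacer_multiplier >= 1,
            arm_multiplier > 0)
  canon <- canonical_trinucleotides()
  if (length(p) == 1L) {
    p <- setNames(rep(p, 32L), canon)
  } else {
    stopifnot(all(canon %in% names(p)))
    p <- p[canon]
  }
  cls <- .position_classes(genome)
  n <- genome_length(genome)
  prob <- rep(0, n)
  has_ctx <- cls > 0L
  prob[has_ctx] <- p[cls[has_ctx]]
  segs <- ir_segments(irs)
  if (length(segs$spacers) > 0L) {
    in_sp <- .pos_in_ranges(seq_len(n), segs$spacers)
    prob[in_sp] <- prob[in_sp] * spacer_multiplier
  }
  if (arm_multiplier != 1 && length(segs$arms) > 0L) {
    in_arm <- .pos_in_ranges(seq_len(n), segs$arms)
    prob[in_arm] <- prob[in_arm] * arm_multiplier
  }
  if (any(prob > 1)) {
    warning("simulate_snvs: multiplied rate exceeds 1 at ", sum(prob > 1),
            " position(s); capped")
    prob <- pmin(prob, 1)
  }
  .with_seed(seed, {
    hit <- which(runif(n) < prob)
    if (length(hit) == 0L) {
      return(data.frame(seq_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        mq = numeric(0), qual = numeric(0)))
    }
    ref <- substring(genome$residues, hit, hit)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "", USE.NAMES = FALSE)
    data.frame(seq_id = genome$seq_id, pos = hit, ref = ref, alt = alt,
               mq = 60, qual = 100, stringsAsFactors = FALSE)
  })
}
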