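# Intraspecific SNV burden within IR arms and spacers against length-based
# and trinucleotide-context-adjusted expectations.

#' The 32 canonical trinucleotide classes
#'
#' The canonical form of a trinucleotide is the lexicographic minimum of
#' the trinucleotide and its reverse complement; the 64 ACGT trinucleotides
#' collapse into 32 classes.
#'
#' @return Sorted character vector of the 32 class labels.
#' @export
canonical_trinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  tri <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(unique(pmin(tri, reverse_complement(tri))))
}

# Integer class id (1..32) per genome position; 0 where the centered
# trinucleotide context is incomplete (sequence ends) or contains N.
.position_classes <- function(genome) {
  n <- genome_length(genome)
  cls <- integer(n)
  if (n < 3L) return(cls)
  ctx <- substring(genome$residues, 1:(n - 2L), 3:n)
  canon <- canonical_trinucleotides()
  # classify via a lookup over the distinct contexts (<= 125) rather than
  # per-position reverse complements
  u <- unique(ctx)
  has_n <- grepl("N", u, fixed = TRUE)
  cls_u <- integer(length(u))
  cls_u[!has_n] <- match(pmin(u[!has_n], reverse_complement(u[!has_n])), canon)
  cls[seq.int(2L, n - 1L)] <- cls_u[match(ctx, u)]
  cls
}

#' Genome-wide SNV site density
#'
#' The baseline substitution density `r`: distinct SNV positions (each site
#' a binary indicator, independent of allele frequency) divided by genome
#' length.
#'
#' @param snvs SNV table from [read_vcf_filtered()] (column `pos`).
#' @param genome The [genome_seq()] the variants were called on.
#' @return The density `r` in sites per bp.
#' @export
genome_snv_density <- function(snvs, genome) {
  stopifnot(inherits(genome, "genome_seq"))
  length(unique(snvs$pos)) / genome_length(genome)
}

#' Genome-wide trinucleotide SNV profile
#'
#' Classifies every interior, N-free genome position by the canonical
#' class of its centered trinucleotide and computes, per class `j`, the
#' genome occurrence count and the substitution frequency
#' `p_j = (distinct SNV sites in class j) / (occurrences of class j)`.
#' Classes absent from the genome get `p_j = 0` with a warning.
#'
#' @param genome A [genome_seq()] of length >= 3.
#' @param snvs SNV table from [read_vcf_filtered()].
#' @return List of class `trinuc_profile` with `classes`, `genome_occ`,
#'   `snv_occ`, `p`, and the per-position class vector `pos_class`
#'   (0 = no full context).
#' @export
trinucleotide_profile <- function(genome, snvs) {
  stopifnot(inherits(genome, "genome_seq"), genome_length(genome) >= 3L)
  canon <- canonical_trinucleotides()
  cls <- .position_classes(genome)
  genome_occ <- tabulate(cls, nbins = 32L)
  pos <- unique(snvs$pos)
  pos <- pos[pos >= 1L & pos <= genome_length(genome)]
  snv_cls <- cls[pos]
  snv_occ <- tabulate(snv_cls, nbins = 32L)
  p <- rep(0, 32L)
  ok <- genome_occ > 0L
  p[ok] <- snv_occ[ok] / genome_occ[ok]
  if (any(!ok & snv_occ > 0L)) {
    warning("trinucleotide_profile: SNVs in classes absent from the genome")
  }
  if (any(!ok)) {
    warning("trinucleotide_profile: ", sum(!ok),
            " class(es) with zero genome occurrences; p set to 0")
  }
  structure(list(classes = canon,
                 genome_occ = setNames(genome_occ, canon),
                 snv_occ = setNames(snv_occ, canon),
                 p = setNames(p, canon),
                 pos_class = cls),
            class = "trinuc_profile")
}

#' Expected substitution burden under the trinucleotide-adjusted null
#'
#' `E[X] = sum_j c_j * p_j` where `c_j` counts segment positions whose
#' centered trinucleotide falls in canonical class `j`. Positions lacking
#' a full N-free context are excluded from the `c_j` (logged).
#'
#' @param segment_intervals Non-overlapping [IRanges::IRanges] of segment
#'   positions (pre-merged).
#' @param profile A `trinuc_profile` from [trinucleotide_profile()].
#' @return The expected SNV site count.
#' @export
expected_burden_trinuc <- function(segment_intervals, profile) {
  stopifnot(inherits(profile, "trinuc_profile"))
  pos <- .ranges_positions(segment_intervals)
  if (length(pos) == 0L) return(0)
  cls <- profile$pos_class[pos]
  n_excl <- sum(cls == 0L)
  if (n_excl > 0L) {
    .log_msg("expected_burden_trinuc: excluded ", n_excl,
             " position(s) without full trinucleotide context")
  }
  sum(profile$p[cls[cls > 0L]])
}

#' Arm and spacer footprints of an IR set
#'
#' Arm intervals are merged into one footprint; spacer intervals are merged
#' and then have the arm footprint removed, so a base covered by an arm of
#' one IR and the spacer of another is assigned to arms (arm pairing
#' constrains the base). Set `arm_precedence = FALSE` to keep the raw
#' spacer union instead.
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @param arm_precedence Resolve arm/spacer overlaps in favor of arms
#'   (default `TRUE`).
#' @return List with [IRanges::IRanges] `arms` and `spacers`.
#' @export
ir_segments <- function(irs, arm_precedence = TRUE) {
  if (nrow(irs) == 0L) {
    return(list(arms = .empty_iranges(), spacers = .empty_iranges()))
  }
  a <- irs$arm_length; d <- irs$spacer_length
  arms <- IRanges::reduce(BiocGenerics::sort(c(
    IRanges::IRanges(irs$start, irs$start + a - 1L),
    IRanges::IRanges(irs$end - a + 1L, irs$end))))
  has_sp <- d > 0L
  spacers <- if (any(has_sp)) {
    IRanges::reduce(BiocGenerics::sort(IRanges::IRanges(
      irs$start[has_sp] + a[has_sp],
      irs$start[has_sp] + a[has_sp] + d[has_sp] - 1L)))
  } else .empty_iranges()
  if (arm_precedence && length(spacers) > 0L) {
    spacers <- IRanges::setdiff(spacers, arms)
  }
  list(arms = arms, spacers = spacers)
}

#' Observed versus expected SNV burden in IR arms and spacers
#'
#' For each segment (arms, spacers): `L` = non-overlapping footprint bp,
#' `observed` = distinct SNV sites within the footprint,
#' `expected_length` = `L * r` with `r` the genome-wide SNV site density,
#' and `expected_trinuc` = the trinucleotide-context-adjusted expectation
#' `sum_j c_j p_j`.
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @param snvs SNV table from [read_vcf_filtered()].
#' @param genome The [genome_seq()] shared by both.
#' @param profile Optional precomputed `trinuc_profile` (recomputed when
#'   `NULL`).
#' @param arm_precedence Passed to [ir_segments()].
#' @return Data.frame with one row per segment: `segment`, `L`,
#'   `observed`, `expected_length`, `expected_trinuc`, `r`.
#' @export
burden_tables <- function(irs, snvs, genome, profile = NULL,
                          arm_precedence = TRUE) {
  stopifnot(inherits(genome, "genome_seq"))
  segs <- ir_segments(irs, arm_precedence = arm_precedence)
  if (is.null(profile)) profile <- trinucleotide_profile(genome, snvs)
  r <- genome_snv_density(snvs, genome)
  pos <- unique(snvs$pos)
  row_for <- function(label, rng) {
    L <- sum(IRanges::width(rng))
    data.frame(segment = label, L = L,
               observed = sum(.pos_in_ranges(pos, rng)),
               expected_length = L * r,
               expected_trinuc = expected_burden_trinuc(rng, profile),
               r = r, stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("arms", segs$arms), row_for("spacers", segs$spacers))
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for SNV enrichment within IR loci
#'
#' Builds the 2x2 table (observed SNVs inside/outside the IR footprint
#' versus trinucleotide-adjusted expected counts inside/outside, with the
#' expectation rounded half away from zero) and applies a two-tailed
#' Fisher's exact test. The reported odds ratio is the sample
#' (cross-product) odds ratio of the table.
#'
#' @param observed_in_ir Observed SNV sites within the IR footprint.
#' @param expected_in_ir Expected SNV sites within the footprint (may be
#'   fractional; rounded to a count).
#' @param total_snvs Total SNV sites in the genome.
#' @return List with `odds_ratio`, `p`, the 2x2 `table`, and `flagged`
#'   (`TRUE` for a zero-margin table, where the test is undefined).
#' @export
fisher_ir_enrichment <- function(observed_in_ir, expected_in_ir, total_snvs) {
  e_in <- .round_half_away(expected_in_ir)
  tab <- matrix(c(observed_in_ir, total_snvs - observed_in_ir,
                  e_in, total_snvs - e_in),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("in_ir", "out_ir")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || any(tab < 0)) {
    warning("fisher_ir_enrichment: degenerate 2x2 table; test undefined")
    return(list(odds_ratio = NA_real_, p = NA_real_, table = tab,
                flagged = TRUE))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = ft$p.value, table = tab, flagged = FALSE)
}

#' SNV density in terminator-proximal versus distal IRs
#'
#' Partitions IRs into those with any bp within `distance` bases of a
#' terminator interval (inclusive at the boundary) and the rest, then
#' reports, per segment (arms/spacers) and group (near/far), the footprint
#' bp, distinct SNV sites, and SNV density — optionally stratified by
#' spacer length. Cross-species effect sizes are computed downstream with
#' [cliffs_delta_unpaired()] on the per-species densities.
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @param snvs SNV table from [read_vcf_filtered()].
#' @param terminators Interval table (e.g. from [read_bed()]) with 1-based
#'   `start`, `end`; `NULL` or empty means every IR is "far".
#' @param distance Proximity threshold in bp (default 50, inclusive).
#' @param by_spacer Also stratify by spacer length (default `FALSE`).
#' @return Data.frame with columns `stratum`, `segment`, `group`, `n_irs`,
#'   `bp`, `snv_sites`, `density`.
#' @export
terminator_partition_density <- function(irs, snvs, terminators,
                                         distance = 50L, by_spacer = FALSE) {
  near <- rep(FALSE, nrow(irs))
  if (!is.null(terminators) && nrow(terminators) > 0L && nrow(irs) > 0L) {
    term_rng <- IRanges::IRanges(terminators$start, terminators$end)
    ir_rng <- IRanges::IRanges(irs$start, irs$end)
    hit <- IRanges::distanceToNearest(ir_rng, term_rng)
    d <- rep(NA_integer_, nrow(irs))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    near <- !is.na(d) & d <= distance
  }
  pos <- unique(snvs$pos)
  strata <- if (by_spacer) sort(unique(irs$spacer_length)) else "all"
  rows <- list()
  for (st in strata) {
    in_stratum <- if (identical(st, "all")) rep(TRUE, nrow(irs))
                  else irs$spacer_length == st
    for (grp in c("near", "far")) {
      sel <- irs[in_stratum & (near == (grp == "near")), , drop = FALSE]
      segs <- ir_segments(sel)
      for (seg in c("arms", "spacers")) {
        rng <- segs[[seg]]
        bp <- sum(IRanges::width(rng))
        obs <- sum(.pos_in_ranges(pos, rng))
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = as.character(st), segment = seg, group = grp,
          n_irs = nrow(sel), bp = bp, snv_sites = obs,
          density = if (bp > 0L) obs / bp else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deviation ratio of the arm and spacer regressions from the 45-degree line
#'
#' Across species, the observed burden is regressed on the expected burden
#' (least squares through the origin, as the 45-degree comparison
#' presumes) separately for arms and spacers, and the angular deviations
#' from the identity line are compared:
#' `R = |arctan(b_spacer) - pi/4| / |arctan(b_arm) - pi/4|`.
#' `R = 0` iff the spacer slope is exactly 1; when the arm slope is
#' exactly 1 the ratio is undefined and flagged. Both orientations of the
#' ratio are returned; the slope-label assignment is interpretation
#' sensitive, so `R` defaults to the spacer-over-arm orientation.
#'
#' @param obs_arm,exp_arm Observed and expected arm burdens across species.
#' @param obs_spacer,exp_spacer Observed and expected spacer burdens.
#' @return List with `slope_arm`, `slope_spacer`, `R`
#'   (spacer-over-arm), `R_arm_over_spacer`, `flagged`.
#' @export
regression_deviation_ratio <- function(obs_arm, exp_arm,
                                       obs_spacer, exp_spacer) {
  stopifnot(length(obs_arm) == length(exp_arm),
            length(obs_spacer) == length(exp_spacer))
  slope0 <- function(y, x) unname(coef(lm(y ~ 0 + x))[1])
  b_arm <- slope0(obs_arm, exp_arm)
  b_spacer <- slope0(obs_spacer, exp_spacer)
  dev_arm <- abs(atan(b_arm) - pi / 4)
  dev_spacer <- abs(atan(b_spacer) - pi / 4)
  flagged <- dev_arm == 0
  if (flagged) {
    warning("regression_deviation_ratio: arm slope exactly 1; ",
            "ratio undefined")
  }
  list(slope_arm = b_arm, slope_spacer = b_spacer,
       R = if (flagged) NA_real_ else dev_spacer / dev_arm,
       R_arm_over_spacer = if (dev_spacer == 0) NA_real_ else
         dev_arm / dev_spacer,
       flagged = flagged)
}
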