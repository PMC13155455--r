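# Detection of maximal perfect inverted repeats (IRs).
#
# An IR is two arms that are exact reverse complements of each other,
# separated by an unconstrained spacer. Only maximal IRs are reported: the
# arms can be extended neither outward by one complementary pair nor — for
# spacers >= 2 — inward (shrinking the spacer by two while growing each arm
# by one). N never base-pairs, so arms are N-free; spacers may contain N.

#' Detection parameters
#'
#' @param min_arm Minimum arm length in bp (default 10).
#' @param max_spacer Maximum spacer length in bp (default 8).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_arm = 10L, max_spacer = 8L) {
  min_arm <- as.integer(min_arm); max_spacer <- as.integer(max_spacer)
  stopifnot(min_arm >= 1L, max_spacer >= 0L)
  structure(list(min_arm = min_arm, max_spacer = max_spacer),
            class = "detection_params")
}

#' Reverse complement of a DNA sequence
#'
#' Alphabet `{A,C,G,T,N}`; N maps to N. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("reverse_complement: invalid characters in sequence")
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    .c2s(rev(.COMPLEMENT[.s2c(s)]))
  }, "", USE.NAMES = FALSE)
}

#' Detect all maximal perfect inverted repeats in a genome sequence
#'
#' Enumerates every center (innermost arm pair) and spacer length in
#' `[0, max_spacer]`, extends arms outward while bases complement, and keeps
#' maximal hits only. For each (center, spacer) at most one IR is reported.
#' Overlapping IRs at different centers or spacers are all reported;
#' double-counting is resolved at the footprint (union) level.
#'
#' @param genome A [genome_seq()] record (or a plain sequence string, in
#'   which case `seq_id` is `"seq"`).
#' @param params A [detection_params()] object.
#' @return A data.frame sorted by `start` then `spacer_length` with columns
#'   `seq_id`, `start`, `end` (1-based closed full span), `arm_length`,
#'   `spacer_length`, `left_arm`, `spacer`, `right_arm`.
#' @export
detect_inverted_repeats <- function(genome, params = detection_params()) {
  if (is.character(genome)) genome <- genome_seq("seq", genome)
  stopifnot(inherits(genome, "genome_seq"), inherits(params, "detection_params"))
  hits <- cpp_detect_ir(genome$residues, params$min_arm, params$max_spacer)
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), arm_length = integer(0),
                      spacer_length = integer(0), left_arm = character(0),
                      spacer = character(0), right_arm = character(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(hits$start, hits$spacer_length)
  hits <- hits[o, , drop = FALSE]
  n <- nrow(hits)
  res <- genome$residues
  a <- hits$arm_length; d <- hits$spacer_length
  out <- data.frame(
    seq_id = rep(genome$seq_id, n),
    start = hits$start, end = hits$end,
    arm_length = a, spacer_length = d,
    left_arm = substring(res, hits$start, hits$start + a - 1L),
    spacer = ifelse(d > 0L,
                    substring(res, hits$start + a, hits$start + a + d - 1L),
                    ""),
    right_arm = substring(res, hits$end - a + 1L, hits$end),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate a detected inverted repeat against its genome
#'
#' Re-extracts the arm and spacer subsequences from the genome and checks
#' every IR invariant: span arithmetic, exact reverse-complement arms,
#' N-free arms, and maximality (no outward extension; no inward extension
#' for spacers >= 2).
#'
#' @param ir A single IR (one-row data.frame or list with fields `start`,
#'   `end`, `arm_length`, `spacer_length`).
#' @param genome The [genome_seq()] the IR was detected on.
#' @return `TRUE` if all invariants hold, otherwise `FALSE`.
#' @export
validate_ir <- function(ir, genome) {
  stopifnot(inherits(genome, "genome_seq"))
  if (is.data.frame(ir)) {
    stopifnot(nrow(ir) == 1L)
    ir <- as.list(ir)
  }
  n <- genome_length(genome)
  s <- ir$start; e <- ir$end; a <- ir$arm_length; d <- ir$spacer_length
  if (s < 1L || e > n || s > e) stop("validate_ir: coordinates out of range")
  if (e - s + 1L != 2L * a + d) return(FALSE)
  res <- genome$residues
  left <- substring(res, s, s + a - 1L)
  right <- substring(res, e - a + 1L, e)
  if (grepl("N", left) || grepl("N", right)) return(FALSE)
  if (reverse_complement(left) != right) return(FALSE)
  # outward maximality
  if (s > 1L && e < n) {
    fl <- substring(res, s - 1L, s - 1L)
    fr <- substring(res, e + 1L, e + 1L)
    if (fl != "N" && .COMPLEMENT[[fl]] == fr) return(FALSE)
  }
  # inward maximality for spacer >= 2
  if (d >= 2L) {
    sl <- substring(res, s + a, s + a)
    sr <- substring(res, s + a + d - 1L, s + a + d - 1L)
    if (sl != "N" && .COMPLEMENT[[sl]] == sr) return(FALSE)
  }
  TRUE
}

#' Merged footprint of a set of inverted repeats
#'
#' Union of the IR spans (or of the arm intervals only) as sorted,
#' non-overlapping, merged intervals. Total footprint bp is
#' `sum(IRanges::width(.))` and is invariant to input ordering.
#'
#' @param irs IR table from [detect_inverted_repeats()]; all rows must share
#'   one `seq_id`.
#' @param what `"span"` (arms + spacer, the default) or `"arms"`.
#' @return An [IRanges::IRanges] of disjoint intervals.
#' @export
ir_footprint <- function(irs, what = c("span", "arms")) {
  what <- match.arg(what)
  if (nrow(irs) == 0L) return(.empty_iranges())
  if (length(unique(irs$seq_id)) > 1L) {
    stop("ir_footprint: mixed seq_ids; compute per replicon")
  }
  if (what == "span") {
    rng <- IRanges::IRanges(irs$start, irs$end)
  } else {
    a <- irs$arm_length
    rng <- c(IRanges::IRanges(irs$start, irs$start + a - 1L),
             IRanges::IRanges(irs$end - a + 1L, irs$end))
  }
  IRanges::reduce(BiocGenerics::sort(rng))
}

#' IR density per kilobase
#'
#' `1000 * ir_bp / region_bp`: IR footprint base pairs per kilobase of a
#' genome or genomic sub-compartment.
#'
#' @param ir_bp IR footprint base pairs.
#' @param region_bp Total base pairs of the region.
#' @return Density in IR bp per kB; `NA` with a warning when
#'   `region_bp == 0`.
#' @export
ir_density_per_kb <- function(ir_bp, region_bp) {
  stopifnot(ir_bp >= 0, region_bp >= 0)
  if (region_bp == 0) {
    warning("ir_density_per_kb: zero-length region; density undefined")
    return(NA_real_)
  }
  1000 * ir_bp / region_bp
}
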