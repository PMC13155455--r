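# Nucleotide-composition statistics of IR arms and spacers versus the
# genome background.

#' Count overlapping k-mers
#'
#' Sliding-window counts over one or more sequences. Windows containing N
#' are counted under their N-containing key (not dropped), so the counts
#' over all keys total `sum(len_i - k + 1)` for sequences of length >= k.
#'
#' @param seqs Character vector of sequences (or a [genome_seq()] / list of
#'   them).
#' @param k Word size (k >= 1). Sequences shorter than `k` contribute
#'   nothing.
#' @return List of class `kmer_counts` with `k`, `counts` (named integer
#'   vector, observed words only), and `total`.
#' @export
count_kmers <- function(seqs, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (inherits(seqs, "genome_seq")) seqs <- seqs$residues
  if (is.list(seqs)) seqs <- vapply(seqs, `[[`, "", "residues")
  stopifnot(is.character(seqs))
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  counts <- if (length(words)) table(words) else table(character(0))
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(k = k, counts = counts, total = sum(counts)),
            class = "kmer_counts")
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N is excluded from the denominator.
#'
#' @param seq A sequence string.
#' @return Fraction in `[0, 1]`; `NA` with a warning when no A/C/G/T
#'   residues are present.
#' @export
gc_content <- function(seq) {
  stopifnot(.is_string(seq), nchar(seq) > 0L)
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) {
    warning("gc_content: no A/C/G/T residues; undefined")
    return(NA_real_)
  }
  nchar(gsub("[^GC]", "", seq)) / acgt
}

#' GC enrichment of IR arms versus genome background
#'
#' @param arm_gc GC fraction of the IR arms.
#' @param genome_gc Genome-wide GC fraction (N-excluded, over all replicons
#'   of the assembly).
#' @return The ratio `arm_gc / genome_gc`; `NA` with a warning when
#'   `genome_gc == 0`.
#' @export
gc_enrichment_vs_background <- function(arm_gc, genome_gc) {
  if (any(genome_gc == 0)) {
    warning("gc_enrichment_vs_background: zero background GC; undefined")
    return(ifelse(genome_gc == 0, NA_real_, arm_gc / genome_gc))
  }
  arm_gc / genome_gc
}

#' Arm- and spacer-length spectra of an IR set
#'
#' Percentage of IRs per arm length, per spacer length, and the joint
#' (arm, spacer) count heatmap. Percentages within each one-dimensional
#' table sum to 100; heatmap counts sum to the total IR count, and its
#' marginals equal the one-dimensional counts.
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @return List with data.frames `arm` (`arm_length`, `count`, `pct`),
#'   `spacer` (`spacer_length`, `count`, `pct`) and `heatmap`
#'   (`arm_length`, `spacer_length`, `count`). Empty input gives empty
#'   tables.
#' @export
length_spectra <- function(irs) {
  if (nrow(irs) == 0L) {
    empty1 <- data.frame(length = integer(0), count = integer(0),
                         pct = numeric(0))
    return(list(arm = setNames(empty1, c("arm_length", "count", "pct")),
                spacer = setNames(empty1, c("spacer_length", "count", "pct")),
                heatmap = data.frame(arm_length = integer(0),
                                     spacer_length = integer(0),
                                     count = integer(0))))
  }
  n <- nrow(irs)
  one_d <- function(v, nm) {
    tab <- table(v)
    data.frame(setNames(list(as.integer(names(tab))), nm),
               count = as.integer(tab),
               pct = 100 * as.integer(tab) / n)
  }
  joint <- as.data.frame(table(arm_length = irs$arm_length,
                               spacer_length = irs$spacer_length),
                         stringsAsFactors = FALSE)
  joint$arm_length <- as.integer(joint$arm_length)
  joint$spacer_length <- as.integer(joint$spacer_length)
  names(joint)[3] <- "count"
  joint <- joint[joint$count > 0L, , drop = FALSE]
  rownames(joint) <- NULL
  list(arm = one_d(irs$arm_length, "arm_length"),
       spacer = one_d(irs$spacer_length, "spacer_length"),
       heatmap = joint)
}

#' IR density restricted to GC-rich arms
#'
#' Footprint density per kB using only IRs whose arm GC content is at
#' least `gc_threshold`. (Arm GC is computed on one arm; the two arms have
#' identical GC by reverse complementarity.) Monotonically non-increasing
#' in the threshold.
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @param genome The [genome_seq()] the IRs were detected on.
#' @param gc_threshold Minimum arm GC fraction (0 keeps everything).
#' @param what Footprint definition passed to [ir_footprint()].
#' @return Density in IR bp per kB.
#' @export
gc_stratified_density <- function(irs, genome, gc_threshold, what = "span") {
  stopifnot(inherits(genome, "genome_seq"), gc_threshold >= 0)
  if (nrow(irs) == 0L) return(0)
  arm_gc <- vapply(irs$left_arm, gc_content, 0, USE.NAMES = FALSE)
  keep <- irs[arm_gc >= gc_threshold, , drop = FALSE]
  if (nrow(keep) == 0L) return(0)
  ir_density_per_kb(sum(IRanges::width(ir_footprint(keep, what = what))),
                    genome_length(genome))
}
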