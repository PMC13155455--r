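# Enrichment statistic, paired effect sizes and rank-level aggregation for
# real-versus-shuffled IR density comparisons.

#' IR enrichment statistic
#'
#' `FE(O, E) = (O - E) / (O + E)` when `O != E`, and 0 when `O == E`
#' (which also covers `O == E == 0`). Takes values in `[-1, 1]`: -1 is
#' maximal depletion, 1 maximal enrichment relative to the matched
#' dinucleotide-preserving shuffled control.
#'
#' @param observed Observed IR bp (or density) in the real genome; >= 0.
#' @param expected Expected IR bp (or density) from the matched control
#'   (non-negative). Vectors are recycled elementwise.
#' @return Numeric vector of enrichment values in `[-1, 1]`.
#' @export
enrichment_fe <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    stop("enrichment_fe: inputs must be non-negative")
  }
  ifelse(observed == expected, 0, (observed - expected) / (observed + expected))
}

#' Paired Hedges' g with small-sample correction
#'
#' Standardized mean of the paired differences `d_i = x_i - y_i`,
#' `g = J(N - 1) * mean(d) / sd(d)` with the correction factor
#' `J(n) = 1 - 3 / (4n - 1)`.
#'
#' @param x Observed densities (real genomes).
#' @param y Expected densities (matched shuffled controls), same length.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return The signed effect size; `NA` with a warning when `sd(d) == 0`
#'   (all differences identical).
#' @export
hedges_g_paired <- function(x, y, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (s == 0) {
    warning("hedges_g_paired: zero variance of differences; g undefined")
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (n - 1) - 1)
  j * mean(d) / s
}

#' Paired Cliff's delta
#'
#' `delta = 2 * P(X > Y) + P(X = Y) - 1` with the probabilities taken as
#' empirical proportions over the pairs. Equals 1 iff every `x_i > y_i`,
#' -1 iff every `x_i < y_i`, and 0 when all pairs are tied.
#'
#' @param x,y Paired samples of equal length (N >= 1).
#' @return A number in `[-1, 1]`.
#' @export
cliffs_delta_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  2 * mean(x > y) + mean(x == y) - 1
}

#' Unpaired Cliff's delta
#'
#' Over all `N * M` cross pairs: `(#\{x > y\} - #\{x < y\}) / (N * M)`.
#'
#' @param x,y Two samples (not necessarily equal length).
#' @return A number in `[-1, 1]`.
#' @export
cliffs_delta_unpaired <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  cmp <- outer(x, y, "-")
  (sum(cmp > 0) - sum(cmp < 0)) / (length(x) * length(y))
}

#' Species-level IR density
#'
#' The IR density of a species is the arithmetic mean of the densities of
#' its assembly accessions.
#'
#' @param assembly_densities Non-empty numeric vector of per-assembly
#'   densities.
#' @return The mean density.
#' @export
species_density <- function(assembly_densities) {
  if (length(assembly_densities) == 0L) {
    stop("species_density: empty input")
  }
  mean(assembly_densities)
}

#' Rank-level IR density F(R)
#'
#' The density of a taxonomic rank is the arithmetic mean of the
#' species-level densities of its member species:
#' `F(R) = sum(f(S_j)) / m(R)`.
#'
#' @param species_densities Non-empty numeric vector of per-species
#'   densities.
#' @return The mean density.
#' @export
rank_density <- function(species_densities) {
  if (length(species_densities) == 0L) {
    stop("rank_density: empty input")
  }
  mean(species_densities)
}

#' Paired Wilcoxon signed-rank tests with BH correction across ranks
#'
#' For each taxonomic group, compares the paired observed and expected
#' densities with a two-sided Wilcoxon signed-rank test, then adjusts
#' p-values across groups with the Benjamini-Hochberg step-up procedure.
#' Effect sizes (paired Hedges' g and Cliff's delta) are reported per
#' group. Groups whose differences are all zero have an undefined test and
#' are flagged (`NA` p-value, excluded from the BH family).
#'
#' @param groups Named list; each element a list/data.frame with numeric
#'   components `x` (observed) and `y` (expected) of equal length >= 2.
#' @param alpha Significance level recorded in the output (default 0.05).
#' @return Data.frame with columns `rank`, `n`, `statistic`, `p`, `p_adj`,
#'   `g`, `delta`, `flagged`, `significant`.
#' @export
paired_test_with_bh <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) > 0L, !is.null(names(groups)))
  rows <- lapply(names(groups), function(nm) {
    gdat <- groups[[nm]]
    x <- gdat$x; y <- gdat$y
    stopifnot(length(x) == length(y), length(x) >= 2L)
    d <- x - y
    flagged <- all(d == 0)
    if (flagged) {
      stat <- NA_real_; p <- NA_real_; g <- NA_real_
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                         alternative = "two.sided",
                                         exact = FALSE, correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
      g <- suppressWarnings(hedges_g_paired(x, y))
    }
    data.frame(rank = nm, n = length(x), statistic = stat, p = p,
               g = g, delta = cliffs_delta_paired(x, y),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out[, c("rank", "n", "statistic", "p", "p_adj", "g", "delta",
          "flagged", "significant")]
}
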