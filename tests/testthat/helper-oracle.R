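# Independent enumerators of maximal perfect inverted repeats, used as
# oracles for the detector. Both are deliberately different formulations
# from the detector's center-extension algorithm.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  paste(rev(.ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive enumerator: tests every (left_start, arm, spacer) substring triple
# and keeps maximal hits. Cubic; tiny inputs only.
ir_naive <- function(seq, min_arm = 10L, max_spacer = 8L) {
  n <- nchar(seq)
  pair_ok <- function(a, b) a != "N" && .ORACLE_COMP[[a]] == b
  rows <- list()
  for (s in seq_len(n)) {
    max_a <- (n - s + 1L) %/% 2L
    if (max_a < min_arm) next
    for (a in min_arm:max_a) {
      for (d in 0:max_spacer) {
        e <- s + 2L * a + d - 1L
        if (e > n) next
        left <- substr(seq, s, s + a - 1L)
        right <- substr(seq, s + a + d, e)
        if (grepl("N", left)) next
        if (oracle_revcomp(left) != right) next
        # outward maximality
        if (s > 1L && e < n &&
            pair_ok(substr(seq, s - 1L, s - 1L), substr(seq, e + 1L, e + 1L)))
          next
        # inward maximality for spacer >= 2
        if (d >= 2L &&
            pair_ok(substr(seq, s + a, s + a),
                    substr(seq, s + a + d - 1L, s + a + d - 1L)))
          next
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = e, arm_length = a, spacer_length = d)
      }
    }
  }
  oracle_sort(if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               arm_length = integer(0), spacer_length = integer(0)))
}

# Anti-diagonal enumerator: for every constant position-sum C the
# complementarity matches along the diagonal are computed in one vector
# and arm lengths read off as run lengths; maximality comes from run ends.
# Quadratic overall; handles kb-scale sequences.
ir_oracle <- function(seq, min_arm = 10L, max_spacer = 8L) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
  n <- length(x)
  y <- c(4L, 3L, 2L, 1L, 0L)[x]   # complement codes; N (0) never matches
  rows <- list()
  for (C in 3:(2L * n - 1L)) {
    pmax_ <- (C - 1L) %/% 2L
    pmin_ <- max(1L, C - n)
    if (pmax_ < pmin_) next
    pp <- pmin_:pmax_
    m <- x[pp] == y[C - pp]
    idx <- seq_along(m)
    runlen <- idx - cummax(ifelse(m, 0L, idx))  # TRUE-run ending at idx
    for (d in 0:max_spacer) {
      if ((C - d - 1L) %% 2L != 0L) next
      p0 <- (C - d - 1L) %/% 2L
      if (p0 < pmin_ || p0 > pmax_) next
      i0 <- p0 - pmin_ + 1L
      a <- runlen[i0]
      if (a < min_arm) next
      if (d >= 2L && m[i0 + 1L]) next          # inward-extendable
      rows[[length(rows) + 1L]] <- c(p0 - a + 1L, (C - p0) + a - 1L, a, d)
    }
  }
  out <- if (length(rows)) {
    mat <- do.call(rbind, rows)
    data.frame(start = mat[, 1], end = mat[, 2],
               arm_length = mat[, 3], spacer_length = mat[, 4])
  } else {
    data.frame(start = integer(0), end = integer(0),
               arm_length = integer(0), spacer_length = integer(0))
  }
  oracle_sort(out)
}

oracle_sort <- function(df) {
  df <- df[order(df$start, df$spacer_length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Coordinate columns of a detector table, oracle-comparable.
ir_coords <- function(irs) {
  oracle_sort(irs[, c("start", "end", "arm_length", "spacer_length"),
                  drop = FALSE])
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Overlapping dinucleotide count vector over the 5-letter alphabet,
# as a named 25-cell vector (order fixed) for exact comparisons.
dinuc_vector <- function(seq) {
  b <- c("A", "C", "G", "T", "N")
  keys <- as.vector(outer(b, b, paste0))
  n <- nchar(seq)
  counts <- setNames(integer(25), keys)
  if (n >= 2L) {
    words <- substring(seq, 1:(n - 1L), 2:n)
    tab <- table(words)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
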