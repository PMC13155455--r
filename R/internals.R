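# Internal helpers shared across modules.

.IR_ALPHABET <- c("A", "C", "G", "T", "N")

# Complement lookup used everywhere; N maps to N but never base-pairs.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.log_msg <- function(...) message("[irtopo] ", ...)

# Round half away from zero (used when expected counts feed an exact test).
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Split a sequence string into single characters.
.s2c <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

.c2s <- function(chars) paste(chars, collapse = "")

# Run the expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the global stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Positions (1-based) covered by an IRanges as an integer vector.
.ranges_positions <- function(ir) {
  if (length(ir) == 0L) return(integer(0))
  unlist(lapply(seq_along(ir), function(i) {
    seq.int(IRanges::start(ir)[i], IRanges::end(ir)[i])
  }), use.names = FALSE)
}

# Membership of positions in an interval set.
.pos_in_ranges <- function(pos, ranges) {
  if (length(pos) == 0L) return(logical(0))
  if (length(ranges) == 0L) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(IRanges::IRanges(start = pos, width = 1L), ranges)
}

.empty_iranges <- function() IRanges::IRanges()
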