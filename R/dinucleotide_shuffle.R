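# Dinucleotide-preserving shuffling of genome sequences.
#
# The shuffle is the Euler-walk construction (Altschul–Erickson): the
# sequence is viewed as an Eulerian path on the graph whose vertices are
# symbols and whose edges are the overlapping dinucleotides. For every
# vertex except the terminal symbol a random "last" outgoing edge is drawn,
# and the draw is accepted only when the last edges form an arborescence
# into the terminal vertex; remaining edges are ordered uniformly at random.
# Walking the edges then yields a uniform sample from all sequences with
# exactly the same multiset of overlapping dinucleotides (hence identical
# mononucleotide counts and fixed first and last residue). N is treated as
# a fifth symbol, so N-containing doublets are preserved, not stripped.

# Shuffle one chunk given as a character vector; assumes length >= 2.
.euler_shuffle_chars <- function(x) {
  n <- length(x)
  syms <- unique(x)
  k <- length(syms)
  code <- match(x, syms)
  from <- code[-n]
  to <- code[-1L]
  out_edges <- split(to, factor(from, levels = seq_len(k)))
  terminal <- code[n]

  has_out <- lengths(out_edges) > 0L
  need_last <- which(has_out & seq_len(k) != terminal)

  if (length(need_last) > 0L) {
    for (try in seq_len(10000L)) {
      last <- vapply(need_last, function(u) {
        e <- out_edges[[u]]
        e[[sample.int(length(e), 1L)]]
      }, 0L)
      # accept iff every vertex with a last edge reaches the terminal by
      # following last edges (arborescence check; at most 5 vertices)
      reach <- rep(FALSE, k); reach[terminal] <- TRUE
      for (pass in seq_len(k)) {
        reach[need_last] <- reach[need_last] | reach[last]
      }
      if (all(reach[need_last])) break
      if (try == 10000L) stop("shuffle: arborescence sampling failed")
    }
  } else {
    last <- integer(0)
  }

  ordered <- vector("list", k)
  for (u in seq_len(k)) {
    e <- out_edges[[u]]
    if (length(e) == 0L) { ordered[[u]] <- integer(0); next }
    if (u %in% need_last) {
      lu <- last[match(u, need_last)]
      drop1 <- match(lu, e)
      rest <- e[-drop1]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[u]] <- c(rest, lu)
    } else {
      ordered[[u]] <- if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  }

  ptr <- rep(1L, k)
  res <- integer(n)
  cur <- code[1L]
  res[1L] <- cur
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  syms[res]
}

#' Dinucleotide-preserving shuffle of one sequence chunk
#'
#' Returns a permutation of `seq` with exactly the same multiset of
#' overlapping dinucleotides (and therefore the same mononucleotide counts,
#' first and last residue). Sequences shorter than 2 bp are returned
#' unchanged. Uses the current RNG stream; seed via [set.seed()] or
#' [shuffle_genome()].
#'
#' @param seq A sequence string over `{A,C,G,T,N}`.
#' @return The shuffled string.
#' @export
shuffle_chunk <- function(seq) {
  stopifnot(.is_string(seq))
  if (nchar(seq) < 2L) return(seq)
  .c2s(.euler_shuffle_chars(.s2c(seq)))
}

#' Shuffle parameters
#' @param chunk_bp Chunk length in bp (default 1000).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A list of class `shuffle_params`.
#' @export
shuffle_params <- function(chunk_bp = 1000L, seed = NULL) {
  chunk_bp <- as.integer(chunk_bp)
  stopifnot(chunk_bp >= 2L)
  structure(list(chunk_bp = chunk_bp, seed = seed), class = "shuffle_params")
}

#' Dinucleotide-preserving shuffled control genome
#'
#' The genome is processed in non-overlapping chunks of `chunk_bp` base
#' pairs, each chunk shuffled independently by the Euler-walk construction;
#' the final partial chunk is shuffled as its own segment. Per-chunk
#' dinucleotide counts (over the 5-symbol alphabet including N) are
#' preserved exactly; doublets straddling chunk boundaries are not.
#' One seeded RNG stream is used per genome.
#'
#' @param genome A [genome_seq()] record.
#' @param params A [shuffle_params()] object.
#' @return A [genome_seq()] with `seq_id` suffixed `"_shuffled"`.
#' @export
shuffle_genome <- function(genome, params = shuffle_params()) {
  stopifnot(inherits(genome, "genome_seq"), inherits(params, "shuffle_params"))
  n <- genome_length(genome)
  starts <- seq.int(1L, n, by = params$chunk_bp)
  ends <- pmin(starts + params$chunk_bp - 1L, n)
  shuffled <- .with_seed(params$seed, {
    vapply(seq_along(starts), function(i) {
      shuffle_chunk(substring(genome$residues, starts[i], ends[i]))
    }, "")
  })
  genome_seq(paste0(genome$seq_id, "_shuffled"), paste(shuffled, collapse = ""),
             topology = genome$topology)
}
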