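# IR density across functional genomic compartments and positional
# enrichment profiles around TSS/TES/POT anchors.

#' Derive merged functional compartments from gene models
#'
#' Builds mutually disjoint merged interval sets per functional class:
#' `genic` (union of gene spans), `intergenic` (its complement), `exonic`,
#' `intronic` (genic minus exonic), `cds`, `utr5` / `utr3` (strand-aware
#' exonic bases 5' of the CDS start / 3' of the CDS end), and `genome`.
#'
#' @param genes List of [gene_record()] objects on one replicon.
#' @param genome_length Replicon length in bp.
#' @return Named list of [IRanges::IRanges] (class `compartment_set`).
#' @export
derive_compartments <- function(genes, genome_length) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 1L)
  if (inherits(genes, "gene_record")) genes <- list(genes)
  for (g in genes) {
    if (g$end > genome_length) {
      stop("derive_compartments: gene ", g$gene_id, " beyond genome end")
    }
  }
  spans <- if (length(genes)) {
    IRanges::IRanges(vapply(genes, `[[`, 0L, "start"),
                     vapply(genes, `[[`, 0L, "end"))
  } else .empty_iranges()
  genic <- IRanges::reduce(BiocGenerics::sort(spans))
  whole <- IRanges::IRanges(1L, genome_length)
  intergenic <- IRanges::setdiff(whole, genic)

  exonic <- if (length(genes)) {
    IRanges::reduce(do.call(c, lapply(genes, `[[`, "exons")))
  } else .empty_iranges()
  cds_all <- lapply(genes, `[[`, "cds")
  cds_all <- cds_all[lengths(cds_all) > 0L]
  cds <- if (length(cds_all)) IRanges::reduce(do.call(c, cds_all)) else .empty_iranges()
  intronic <- IRanges::setdiff(genic, exonic)

  utr5_parts <- list(); utr3_parts <- list()
  for (g in genes) {
    if (length(g$cds) == 0L) next
    cs <- min(IRanges::start(g$cds)); ce <- max(IRanges::end(g$cds))
    up <- if (cs > g$start)
      IRanges::intersect(g$exons, IRanges::IRanges(g$start, cs - 1L)) else .empty_iranges()
    dn <- if (ce < g$end)
      IRanges::intersect(g$exons, IRanges::IRanges(ce + 1L, g$end)) else .empty_iranges()
    if (g$strand == "+") {
      utr5_parts <- c(utr5_parts, list(up)); utr3_parts <- c(utr3_parts, list(dn))
    } else {
      utr5_parts <- c(utr5_parts, list(dn)); utr3_parts <- c(utr3_parts, list(up))
    }
  }
  cat_reduce <- function(parts) {
    parts <- parts[lengths(parts) > 0L]
    if (length(parts) == 0L) return(.empty_iranges())
    IRanges::reduce(BiocGenerics::sort(do.call(c, parts)))
  }
  structure(list(genic = genic, intergenic = intergenic, exonic = exonic,
                 intronic = intronic, cds = cds,
                 utr5 = cat_reduce(utr5_parts), utr3 = cat_reduce(utr3_parts),
                 genome = whole),
            class = "compartment_set")
}

#' Total base pairs per compartment
#' @param compartments A `compartment_set` from [derive_compartments()].
#' @return Named integer vector of total bp per label.
#' @export
compartment_bp <- function(compartments) {
  vapply(compartments, function(r) sum(IRanges::width(r)), 0L)
}

#' IR density per kB within each functional compartment
#'
#' Density is `1000 * |footprint intersect compartment| / |compartment|`;
#' an IR straddling a compartment boundary contributes its bp to each side
#' proportionally to the overlap.
#'
#' @param irs IR table from [detect_inverted_repeats()] (or an
#'   [IRanges::IRanges] footprint).
#' @param compartments A `compartment_set`.
#' @param what Footprint definition passed to [ir_footprint()].
#' @return Data.frame with columns `compartment`, `compartment_bp`,
#'   `ir_bp`, `density` (`NA` with a warning for zero-length compartments).
#' @export
compartment_density <- function(irs, compartments, what = "span") {
  stopifnot(inherits(compartments, "compartment_set"))
  fp <- if (is(irs, "IRanges")) irs else ir_footprint(irs, what = what)
  labels <- names(compartments)
  comp_bp <- compartment_bp(compartments)
  ir_bp <- vapply(labels, function(l) {
    sum(IRanges::width(IRanges::intersect(fp, compartments[[l]])))
  }, 0L)
  dens <- rep(NA_real_, length(labels))
  ok <- comp_bp > 0L
  dens[ok] <- 1000 * ir_bp[ok] / comp_bp[ok]
  if (any(!ok)) {
    warning("compartment_density: zero-length compartment(s): ",
            paste(labels[!ok], collapse = ", "))
  }
  data.frame(compartment = labels, compartment_bp = unname(comp_bp),
             ir_bp = unname(ir_bp), density = dens,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Shared worker: per-offset IR bp counts over symmetric windows around
# anchors, strand-oriented so negative offsets are always upstream.
# Windows overrunning the replicon are dropped (zero-padding would bias the
# window mean).
.profile_at_anchors <- function(footprint, anchors, strands, window,
                                genome_length, anchor_label) {
  w <- as.integer(window)
  stopifnot(w >= 1L, length(anchors) == length(strands))
  keep <- anchors - w >= 1L & anchors + w <= genome_length
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    .log_msg("positional profile: dropped ", n_dropped,
             " anchor(s) with truncated windows")
  }
  anchors <- anchors[keep]; strands <- strands[keep]
  if (length(anchors) == 0L) {
    stop("positional profile: no anchor with a full window in the genome")
  }
  cov <- IRanges::coverage(footprint, width = genome_length)
  covv <- as.integer(cov)
  covv[covv > 1L] <- 1L   # footprint is already a union, but be safe
  raw <- numeric(2L * w + 1L)
  for (i in seq_along(anchors)) {
    slice <- covv[(anchors[i] - w):(anchors[i] + w)]
    if (strands[i] == "-") slice <- rev(slice)
    raw <- raw + slice
  }
  m <- mean(raw)
  flagged <- m == 0
  enrichment <- if (flagged) rep(NA_real_, length(raw)) else raw / m
  if (flagged) warning("positional profile: window mean is zero; ",
                       "enrichment undefined")
  structure(list(anchor = anchor_label, window = w, offsets = seq.int(-w, w),
                 raw = raw, enrichment = enrichment,
                 n_anchors = length(anchors), n_dropped = n_dropped,
                 flagged = flagged),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> anchor=%s window=+/-%d, %d anchor(s)%s\n",
              x$anchor, x$window, x$n_anchors,
              if (x$flagged) " [flagged: zero window mean]" else ""))
  invisible(x)
}

#' Positional IR enrichment profile around gene anchors
#'
#' For every gene, a symmetric window of `2 * window + 1` positions is laid
#' around the anchor (TSS = 5' gene end, TES = 3' gene end; for genes on
#' the minus strand the window is reflected so negative offsets are always
#' upstream), and IR footprint bp are summed per offset over genes.
#' Enrichment is the per-offset count divided by the window mean, so
#' `mean(enrichment) == 1` whenever the window mean is positive.
#'
#' @param irs IR table (or `IRanges` footprint) on the replicon.
#' @param genes List of [gene_record()] objects.
#' @param anchor `"TSS"` or `"TES"`.
#' @param window Half-window in bp (default 500, i.e. 1001 positions).
#' @param genome_length Replicon length in bp.
#' @param what Footprint definition passed to [ir_footprint()].
#' @return A `positional_profile` object.
#' @export
positional_profile <- function(irs, genes, anchor = c("TSS", "TES"),
                               window = 500L, genome_length,
                               what = "span") {
  anchor <- match.arg(anchor)
  if (inherits(genes, "gene_record")) genes <- list(genes)
  stopifnot(length(genes) >= 1L)
  fp <- if (is(irs, "IRanges")) irs else ir_footprint(irs, what = what)
  strands <- vapply(genes, `[[`, "", "strand")
  starts <- vapply(genes, `[[`, 0L, "start")
  ends <- vapply(genes, `[[`, 0L, "end")
  anchors <- if (anchor == "TSS") ifelse(strands == "+", starts, ends)
             else ifelse(strands == "+", ends, starts)
  .profile_at_anchors(fp, as.integer(anchors), strands, window,
                      as.integer(genome_length), anchor)
}

#' Positional IR profile around points of termination (POT)
#'
#' As [positional_profile()] with the anchor at the start coordinate of
#' each POT interval (strand-aware when a strand column is present) and a
#' default half-window of 100 bp (201 positions).
#'
#' @param irs IR table (or `IRanges` footprint).
#' @param pot POT coordinate table, e.g. from [read_bed()] (1-based
#'   `start`; optional `strand`).
#' @param window Half-window in bp (default 100).
#' @param genome_length Replicon length in bp.
#' @param what Footprint definition passed to [ir_footprint()].
#' @return A `positional_profile` object with `anchor == "POT"`.
#' @export
pot_profile <- function(irs, pot, window = 100L, genome_length,
                        what = "span") {
  if (is.null(pot) || nrow(pot) == 0L) stop("pot_profile: empty POT set")
  fp <- if (is(irs, "IRanges")) irs else ir_footprint(irs, what = what)
  strands <- if ("strand" %in% names(pot)) {
    ifelse(pot$strand == "-", "-", "+")
  } else rep("+", nrow(pot))
  .profile_at_anchors(fp, as.integer(pot$start), strands, window,
                      as.integer(genome_length), "POT")
}

#' Aggregate positional profiles across genomes
#'
#' Per-offset arithmetic mean of the enrichment vectors of the input
#' profiles; flagged profiles (zero window mean) are dropped with a logged
#' count.
#'
#' @param profiles List of `positional_profile` objects with identical
#'   anchor and window.
#' @return A `positional_profile` whose `enrichment` is the mean profile
#'   (`raw` holds the summed raw counts).
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ok <- !vapply(profiles, `[[`, TRUE, "flagged")
  if (any(!ok)) {
    .log_msg("aggregate_profiles: dropped ", sum(!ok), " flagged profile(s)")
  }
  profiles <- profiles[ok]
  if (length(profiles) == 0L) stop("aggregate_profiles: all profiles flagged")
  w <- profiles[[1]]$window
  anch <- profiles[[1]]$anchor
  stopifnot(all(vapply(profiles, `[[`, 0L, "window") == w),
            all(vapply(profiles, `[[`, "", "anchor") == anch))
  enr <- rowMeans(vapply(profiles, `[[`, numeric(2L * w + 1L), "enrichment"))
  raw <- rowSums(vapply(profiles, `[[`, numeric(2L * w + 1L), "raw"))
  structure(list(anchor = anch, window = w, offsets = seq.int(-w, w),
                 raw = raw, enrichment = enr,
                 n_anchors = sum(vapply(profiles, `[[`, 0L, "n_anchors")),
                 n_genomes = length(profiles), n_dropped = sum(!ok),
                 flagged = FALSE),
            class = "positional_profile")
}

#' Two-stage bootstrap confidence bands for an aggregate profile
#'
#' Monte-Carlo resampling with replacement on the family (outer layer) and
#' species (inner layer) taxonomic levels: each replicate draws families
#' with replacement, then, within every drawn family, species with
#' replacement; the aggregate (mean) profile of the drawn species is
#' recomputed and per-offset percentiles over replicates form the bands.
#' With a single family the outer layer is degenerate and species-only
#' resampling is used, with a warning.
#'
#' @param profiles Named list of per-species `positional_profile` objects
#'   (names are species).
#' @param lineage Data.frame with columns `species` and `family` covering
#'   the profile names.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param probs Lower/upper percentiles (default 2.5% and 97.5%).
#' @return List with per-offset `ci_low` and `ci_high`, plus `n_boot`.
#' @export
bootstrap_ci <- function(profiles, lineage, n_boot = 1000L, seed = NULL,
                         probs = c(0.025, 0.975)) {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  ok <- !vapply(profiles, `[[`, TRUE, "flagged")
  profiles <- profiles[ok]
  species <- names(profiles)
  fam <- lineage$family[match(species, lineage$species)]
  if (anyNA(fam)) stop("bootstrap_ci: species missing from lineage table")
  w <- profiles[[1]]$window
  mat <- vapply(profiles, `[[`, numeric(2L * w + 1L), "enrichment")
  by_family <- split(seq_along(species), fam)
  families <- names(by_family)
  single_family <- length(families) == 1L
  if (single_family) {
    warning("bootstrap_ci: single family; falling back to species-only ",
            "resampling")
  }
  reps <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      if (single_family) {
        idx <- sample.int(length(species), length(species), replace = TRUE)
      } else {
        fams <- sample(families, length(families), replace = TRUE)
        idx <- unlist(lapply(fams, function(f) {
          members <- by_family[[f]]
          members[sample.int(length(members), length(members), replace = TRUE)]
        }), use.names = FALSE)
      }
      rowMeans(mat[, idx, drop = FALSE])
    }, numeric(2L * w + 1L))
  })
  list(ci_low = apply(reps, 1L, quantile, probs = probs[1], names = FALSE),
       ci_high = apply(reps, 1L, quantile, probs = probs[2], names = FALSE),
       n_boot = n_boot)
}
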