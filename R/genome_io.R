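# Readers and writers for the standard formats the pipeline touches, and the
# constructors of the internal data model. Internal coordinates are 1-based
# closed (the IRanges convention); BED (0-based half-open) and GFF3/VCF
# (1-based) are converted at this boundary and nowhere else.

#' Construct a genome sequence record
#'
#' A `genome_seq` holds one replicon: an identifier, its residues over the
#' alphabet `{A,C,G,T,N}`, and a topology flag. Residues are uppercased and
#' any IUPAC ambiguity code other than A/C/G/T is mapped to N; the number of
#' substitutions is reported via a message when non-zero.
#'
#' @param seq_id Replicon identifier.
#' @param residues Sequence string.
#' @param topology `"linear"` or `"circular"`. The topology flag is recorded
#'   but detection always treats sequences as linear (no origin-spanning IRs).
#' @return An object of class `genome_seq` with elements `seq_id`,
#'   `residues`, `topology`.
#' @export
genome_seq <- function(seq_id, residues, topology = c("linear", "circular")) {
  stopifnot(.is_string(seq_id), .is_string(residues))
  topology <- match.arg(topology)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("genome_seq: residues must be non-empty")
  n_sub <- nchar(gsub("[ACGTN]", "", residues))
  if (n_sub > 0L) {
    residues <- gsub("[^ACGTN]", "N", residues)
    .log_msg(seq_id, ": mapped ", n_sub, " non-ACGTN residue(s) to N")
  }
  structure(list(seq_id = seq_id, residues = residues, topology = topology),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp (%s)\n",
              x$seq_id, nchar(x$residues), x$topology))
  invisible(x)
}

#' Sequence length of a genome record
#' @param genome A `genome_seq`.
#' @return Integer number of residues.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  nchar(genome$residues)
}

#' Read genome sequences from a FASTA file
#'
#' Records are returned in file order, residues uppercased and restricted to
#' `{A,C,G,T,N}` (other IUPAC codes become N, with a logged count).
#' Gzip-compressed input is accepted.
#'
#' @param path Path to a FASTA (optionally `.gz`) file.
#' @param topology Topology recorded on every returned record.
#' @return A list of [genome_seq()] records.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("read_fasta: malformed FASTA '",
                                           path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("read_fasta: empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_seq(ids[i], as.character(set[[i]]), topology = topology)
  })
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes A `genome_seq` or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "residues"))
  names(set) <- vapply(genomes, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a gene record
#'
#' Coordinates are 1-based closed. Exons must lie within the gene span;
#' for protein-coding genes the CDS must lie within the exon union (a CDS
#' outside the exons extends the exon union, with a warning).
#'
#' @param gene_id Identifier.
#' @param seq_id Replicon the gene lives on.
#' @param start,end 1-based closed gene span.
#' @param strand `"+"` or `"-"`.
#' @param biotype `"protein_coding"` or `"non_coding"`.
#' @param exons An [IRanges::IRanges] of exon intervals; if empty, a single
#'   exon spanning the gene is used (the prokaryotic-annotation fill-in).
#' @param cds An [IRanges::IRanges] of CDS intervals (may be empty).
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, seq_id, start, end, strand = "+",
                        biotype = c("protein_coding", "non_coding"),
                        exons = NULL, cds = NULL) {
  biotype <- match.arg(biotype)
  stopifnot(start >= 1, end >= start, strand %in% c("+", "-"))
  if (is.null(exons) || length(exons) == 0L) {
    exons <- IRanges::IRanges(start, end)
  }
  exons <- IRanges::reduce(BiocGenerics::sort(exons))
  if (is.null(cds)) cds <- .empty_iranges()
  cds <- IRanges::reduce(BiocGenerics::sort(cds))
  if (IRanges::start(exons)[1] < start ||
      IRanges::end(exons)[length(exons)] > end) {
    stop("gene_record: exons outside gene span for ", gene_id)
  }
  if (length(cds) > 0L) {
    uncovered <- IRanges::setdiff(cds, exons)
    if (sum(IRanges::width(uncovered)) > 0L) {
      warning("gene_record: CDS outside exons for ", gene_id,
              "; exon union extended")
      exons <- IRanges::reduce(IRanges::union(exons, cds))
    }
  }
  structure(list(gene_id = gene_id, seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end), strand = strand, biotype = biotype,
                 exons = exons, cds = cds),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s %s:%d-%d(%s) %s, %d exon(s), %d CDS part(s)\n",
              x$gene_id, x$seq_id, x$start, x$end, x$strand, x$biotype,
              length(x$exons), length(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Gene, mRNA/transcript, exon and CDS features are assembled into
#' [gene_record()] objects via their Parent links. GFF3 1-based closed
#' coordinates are kept 1-based closed internally. Genes lacking explicit
#' exons (prokaryotic-style annotations) are filled in with a single exon
#' spanning the gene. Child features whose Parent cannot be resolved are
#' skipped with a warning. A gene is `protein_coding` iff it has CDS.
#'
#' @param path Path to a GFF3 (optionally `.gz`) file.
#' @return List of [gene_record()] objects, in file order of the gene
#'   features.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("read_gff3: no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) md$Parent else
    S4Vectors::SimpleList(rep(list(character(0)), length(gr)))

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("read_gff3: no gene features in ", path)
  gene_idx <- which(is_gene)
  gene_ids <- ids[gene_idx]
  if (anyNA(gene_ids)) {
    gene_ids[is.na(gene_ids)] <- paste0("gene_", which(is.na(gene_ids)))
  }

  # Resolve each feature to its owning gene, following Parent one level
  # (transcript) deep.
  id2gene <- setNames(gene_ids, gene_ids)
  names(id2gene) <- ids[gene_idx]
  tx_idx <- which(type %in% c("mRNA", "transcript", "tRNA", "rRNA", "ncRNA"))
  tx2gene <- character(0)
  for (i in tx_idx) {
    p <- as.character(parents[[i]])
    p <- p[p %in% names(id2gene)]
    if (length(p) >= 1L && !is.na(ids[i])) tx2gene[ids[i]] <- id2gene[[p[1]]]
  }

  resolve_gene <- function(i) {
    p <- as.character(parents[[i]])
    for (pp in p) {
      if (pp %in% names(id2gene)) return(id2gene[[pp]])
      if (pp %in% names(tx2gene)) return(tx2gene[[pp]])
    }
    NA_character_
  }

  exon_map <- list(); cds_map <- list()
  n_orphans <- 0L
  for (i in which(type %in% c("exon", "CDS"))) {
    g <- resolve_gene(i)
    if (is.na(g)) { n_orphans <- n_orphans + 1L; next }
    rng <- IRanges::IRanges(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
    if (type[i] == "exon") exon_map[[g]] <- c(exon_map[[g]], list(rng))
    else cds_map[[g]] <- c(cds_map[[g]], list(rng))
  }
  if (n_orphans > 0L) {
    warning("read_gff3: skipped ", n_orphans,
            " exon/CDS feature(s) with unresolvable Parent")
  }

  genes <- vector("list", length(gene_idx))
  for (k in seq_along(gene_idx)) {
    i <- gene_idx[k]
    gid <- gene_ids[k]
    ex <- if (!is.null(exon_map[[gid]]))
      do.call(c, exon_map[[gid]]) else NULL
    cd <- if (!is.null(cds_map[[gid]]))
      do.call(c, cds_map[[gid]]) else NULL
    genes[[k]] <- gene_record(
      gene_id = gid,
      seq_id = as.character(GenomeInfoDb::seqnames(gr)[i]),
      start = BiocGenerics::start(gr)[i], end = BiocGenerics::end(gr)[i],
      strand = if (as.character(BiocGenerics::strand(gr)[i]) == "-") "-" else "+",
      biotype = if (!is.null(cd) && length(cd) > 0L) "protein_coding" else "non_coding",
      exons = ex, cds = cd)
  }
  genes
}

#' Write gene models to a normalized GFF3 file
#'
#' Emits gene, exon and CDS lines with Parent links, so that
#' [read_gff3()] on the output reproduces the input records (ingestion is
#' idempotent).
#'
#' @param genes List of [gene_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  if (inherits(genes, "gene_record")) genes <- list(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seqid, type, s, e, strand, attrs) {
    sprintf("%s\tirtopo\t%s\t%d\t%d\t.\t%s\t.\t%s", seqid, type, s, e, strand, attrs)
  }
  for (g in genes) {
    writeLines(fmt(g$seq_id, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)), con)
    for (i in seq_along(g$exons)) {
      writeLines(fmt(g$seq_id, "exon", IRanges::start(g$exons)[i],
                     IRanges::end(g$exons)[i], g$strand,
                     paste0("ID=", g$gene_id, ".exon", i, ";Parent=", g$gene_id)),
                 con)
    }
    for (i in seq_along(g$cds)) {
      writeLines(fmt(g$seq_id, "CDS", IRanges::start(g$cds)[i],
                     IRanges::end(g$cds)[i], g$strand,
                     paste0("ID=", g$gene_id, ".cds", i, ";Parent=", g$gene_id)),
                 con)
    }
  }
  invisible(path)
}

#' Read and filter SNV sites from a VCF file
#'
#' Retains only biallelic single-nucleotide substitutions passing the
#' mapping-quality and Phred-quality filters (both thresholds inclusive,
#' i.e. "at least"). Multi-allelic records are split into per-alt sites
#' before filtering; indel alts, records with missing MQ, and records
#' failing either threshold are dropped, with counts logged.
#'
#' @param path Path to a VCF (optionally `.gz`) file.
#' @param min_mq Minimum mapping quality (INFO/MQ), default 50.
#' @param min_qual Minimum Phred site quality (QUAL), default 60.
#' @return A data.frame with columns `seq_id`, `pos` (1-based), `ref`,
#'   `alt`, `mq`, `qual`.
#' @export
read_vcf_filtered <- function(path, min_mq = 50, min_qual = 60) {
  if (!file.exists(path)) stop("read_vcf_filtered: no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      mq = numeric(0), qual = numeric(0)))
  }
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])

  alt_split <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  idx <- rep.int(seq_along(ref), n_alt)
  out <- data.frame(seq_id = fix[idx, "CHROM"],
                    pos = as.integer(fix[idx, "POS"]),
                    ref = ref[idx],
                    alt = unlist(alt_split, use.names = FALSE),
                    mq = mq[idx], qual = qual[idx],
                    stringsAsFactors = FALSE)

  is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  no_mq <- is.na(out$mq)
  pass <- is_snv & !no_mq & out$mq >= min_mq & !is.na(out$qual) &
    out$qual >= min_qual
  .log_msg("read_vcf_filtered: ", sum(pass), "/", nrow(out),
           " alt record(s) retained (", sum(!is_snv), " non-SNV, ",
           sum(no_mq & is_snv), " missing MQ, ",
           sum(is_snv & !no_mq & !pass), " below quality thresholds)")
  out <- out[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SNV sites to a minimal VCF file
#'
#' Emits a VCF v4.2 site list with INFO/MQ populated, suitable for
#' round-tripping through [read_vcf_filtered()].
#'
#' @param snvs Data.frame with columns `seq_id`, `pos`, `ref`, `alt` and
#'   optionally `mq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snvs) > 0L) {
    mq <- if ("mq" %in% names(snvs)) snvs$mq else rep(60, nrow(snvs))
    qual <- if ("qual" %in% names(snvs)) snvs$qual else rep(100, nrow(snvs))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\tMQ=%g",
                       snvs$seq_id, as.integer(snvs$pos), snvs$ref, snvs$alt,
                       qual, mq), con)
  }
  invisible(path)
}

#' Write detected inverted repeats to a BED6 file
#'
#' One line per IR: `chrom  start0  end0  IR:arm=<a>;spacer=<s>  <arm>  .`
#' with 0-based half-open coordinates (the BED convention; internal
#' coordinates are 1-based closed).
#'
#' @param irs IR table from [detect_inverted_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ir_bed <- function(irs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(irs) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\tIR:arm=%d;spacer=%d\t%d\t.",
                       irs$seq_id, irs$start - 1L, irs$end,
                       irs$arm_length, irs$spacer_length, irs$arm_length),
               con)
  }
  invisible(path)
}

#' Read a BED file as an interval table
#'
#' Accepts BED3 to BED6; coordinates are converted from 0-based half-open
#' to the internal 1-based closed convention.
#'
#' @param path Path to a BED (optionally `.gz`) file.
#' @return Data.frame with columns `seq_id`, `start`, `end` (1-based
#'   closed), and `name`, `score`, `strand` where present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("read_bed: malformed line ", which(nf < 3L)[1], " in ", path)
  }
  get <- function(i) vapply(fields, function(f) f[i], "")
  out <- data.frame(seq_id = get(1),
                    start = as.integer(get(2)) + 1L,
                    end = as.integer(get(3)),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$end < out$start)) {
    stop("read_bed: malformed coordinates in ", path)
  }
  if (all(nf >= 4L)) out$name <- get(4)
  if (all(nf >= 5L)) out$score <- suppressWarnings(as.numeric(get(5)))
  if (all(nf >= 6L)) out$strand <- get(6)
  out
}

#' Read a taxonomic lineage table
#'
#' A TSV with a header row naming at least `assembly_id`; the lineage
#' columns `species`, `family`, `phylum`, `kingdom`, `domain` are kept
#' where present, missing values become empty strings. Duplicate
#' `assembly_id` rows are an error.
#'
#' @param path Path to a TSV (optionally `.gz`) file.
#' @return Data.frame with one row per assembly.
#' @export
read_lineage_tsv <- function(path) {
  if (!file.exists(path)) stop("read_lineage_tsv: no such file: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = NULL, colClasses = "character")
  if (!"assembly_id" %in% names(tab)) {
    stop("read_lineage_tsv: missing 'assembly_id' column in ", path)
  }
  if (anyDuplicated(tab$assembly_id)) {
    stop("read_lineage_tsv: duplicate assembly_id in ", path)
  }
  for (col in c("species", "family", "phylum", "kingdom", "domain")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab[, c("assembly_id", "species", "family", "phylum", "kingdom", "domain")]
}

#' Write a taxonomic lineage table
#' @param lineage Data.frame as returned by [read_lineage_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(lineage, path) {
  write.table(lineage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
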