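# End-to-end orchestration: detect -> shuffle -> detect-on-control ->
# enrichment -> compartments/profiles -> burden, over one or many
# assemblies described by a manifest.

#' Build a run manifest
#'
#' @param assemblies Named list; each element a list with paths `fasta`
#'   (required) and optionally `gff`, `vcf`, `terminators`.
#' @param lineage Path to a lineage TSV, or a lineage data.frame.
#' @param params Named list of parameter overrides: `min_arm`,
#'   `max_spacer`, `chunk_bp`, `window`, `n_boot`, `min_mq`, `min_qual`,
#'   `terminator_distance`, `group_by`.
#' @param seed Integer seed for the run.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(assemblies, lineage = NULL, params = list(),
                         seed = 1L) {
  stopifnot(is.list(assemblies), length(assemblies) > 0L,
            !is.null(names(assemblies)))
  defaults <- list(min_arm = 10L, max_spacer = 8L, chunk_bp = 1000L,
                   window = 500L, n_boot = 1000L, min_mq = 50, min_qual = 60,
                   terminator_distance = 50L, group_by = "phylum")
  params <- utils::modifyList(defaults, params)
  structure(list(assemblies = assemblies, lineage = lineage, params = params,
                 seed = as.integer(seed)),
            class = "run_manifest")
}

#' Read a run manifest from a YAML file
#' @param path Path to a YAML manifest with fields `assemblies`,
#'   `lineage`, `params`, `seed`.
#' @return A `run_manifest`.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  run_manifest(assemblies = y$assemblies, lineage = y$lineage,
               params = if (is.null(y$params)) list() else y$params,
               seed = if (is.null(y$seed)) 1L else y$seed)
}

# Per-assembly worker; returns the assembly's summary tables.
.run_assembly <- function(id, paths, params, seed) {
  dp <- detection_params(params$min_arm, params$max_spacer)
  genomes <- read_fasta(paths$fasta)
  irs <- lapply(genomes, detect_inverted_repeats, params = dp)
  genome_bp <- sum(vapply(genomes, genome_length, 0L))
  ir_bp <- sum(vapply(irs, function(x)
    sum(IRanges::width(ir_footprint(x))), 0L))

  controls <- lapply(seq_along(genomes), function(i) {
    shuffle_genome(genomes[[i]],
                   shuffle_params(params$chunk_bp, seed = seed + i))
  })
  ctrl_irs <- lapply(controls, detect_inverted_repeats, params = dp)
  ctrl_bp <- sum(vapply(ctrl_irs, function(x)
    sum(IRanges::width(ir_footprint(x))), 0L))

  density <- ir_density_per_kb(ir_bp, genome_bp)
  ctrl_density <- ir_density_per_kb(ctrl_bp, genome_bp)

  genes <- NULL
  compartments <- NULL
  profile_tss <- NULL; profile_tes <- NULL
  if (!is.null(paths$gff) && file.exists(paths$gff)) {
    genes <- read_gff3(paths$gff)
    comp_rows <- list(); tss_raw <- NULL; tes_raw <- NULL
    for (i in seq_along(genomes)) {
      g <- genomes[[i]]
      gg <- Filter(function(x) x$seq_id == g$seq_id, genes)
      if (length(gg) == 0L) next
      comps <- derive_compartments(gg, genome_length(g))
      comp_rows[[length(comp_rows) + 1L]] <-
        compartment_density(irs[[i]], comps)
      fp <- ir_footprint(irs[[i]])
      ptss <- tryCatch(positional_profile(fp, gg, "TSS", params$window,
                                          genome_length(g)),
                       error = function(e) NULL)
      ptes <- tryCatch(positional_profile(fp, gg, "TES", params$window,
                                          genome_length(g)),
                       error = function(e) NULL)
      if (!is.null(ptss)) tss_raw <- if (is.null(tss_raw)) ptss$raw
                          else tss_raw + ptss$raw
      if (!is.null(ptes)) tes_raw <- if (is.null(tes_raw)) ptes$raw
                          else tes_raw + ptes$raw
    }
    if (length(comp_rows) > 0L) {
      comp <- do.call(rbind, comp_rows)
      compartments <- do.call(rbind, lapply(split(comp, comp$compartment),
        function(df) data.frame(compartment = df$compartment[1],
                                compartment_bp = sum(df$compartment_bp),
                                ir_bp = sum(df$ir_bp),
                                density = if (sum(df$compartment_bp) > 0)
                                  1000 * sum(df$ir_bp) / sum(df$compartment_bp)
                                else NA_real_)))
      rownames(compartments) <- NULL
    }
    mk_profile <- function(raw, anchor) {
      if (is.null(raw) || mean(raw) == 0) return(NULL)
      w <- params$window
      structure(list(anchor = anchor, window = w, offsets = seq.int(-w, w),
                     raw = raw, enrichment = raw / mean(raw),
                     n_anchors = NA_integer_, n_dropped = NA_integer_,
                     flagged = FALSE),
                class = "positional_profile")
    }
    profile_tss <- mk_profile(tss_raw, "TSS")
    profile_tes <- mk_profile(tes_raw, "TES")
  }

  burden <- NULL
  if (!is.null(paths$vcf) && file.exists(paths$vcf)) {
    snvs <- read_vcf_filtered(paths$vcf, params$min_mq, params$min_qual)
    terms <- if (!is.null(paths$terminators) &&
                 file.exists(paths$terminators)) read_bed(paths$terminators)
             else NULL
    brows <- list()
    for (i in seq_along(genomes)) {
      g <- genomes[[i]]
      sv <- snvs[snvs$seq_id == g$seq_id, , drop = FALSE]
      bt <- burden_tables(irs[[i]], sv, g)
      bt$seq_id <- g$seq_id
      brows[[length(brows) + 1L]] <- bt
      if (!is.null(terms)) {
        tt <- terms[terms$seq_id == g$seq_id, , drop = FALSE]
        tp <- terminator_partition_density(irs[[i]], sv, tt,
                                           params$terminator_distance)
        tp$seq_id <- g$seq_id
        brows[[length(brows)]] <- bt   # keep burden; partition separate
        attr(brows[[length(brows)]], "terminator_partition") <- tp
      }
    }
    burden <- do.call(rbind, brows)
  }

  list(assembly_id = id, genome_bp = genome_bp, ir_bp = ir_bp,
       density = density, control_ir_bp = ctrl_bp,
       control_density = ctrl_density,
       fe = enrichment_fe(ir_bp, ctrl_bp),
       irs = do.call(rbind, irs), compartments = compartments,
       profile_tss = profile_tss, profile_tes = profile_tes,
       burden = burden)
}

#' Run the full IR analysis pipeline over a manifest
#'
#' For every assembly: detect IRs, build the dinucleotide-preserving
#' shuffled control and detect on it, compute genome and compartment
#' densities, TSS/TES profiles and (when variants are supplied) SNV burden
#' tables; then aggregate densities to species and rank level with paired
#' enrichment statistics. Re-running with the same manifest and seed
#' reproduces all tables. A failing assembly is reported with a warning
#' and skipped; its outputs are absent.
#'
#' @param manifest A [run_manifest()] (or a path to a YAML manifest).
#' @param outdir Output directory for TSV/BED/JSON artifacts, or `NULL`
#'   for no files.
#' @return List with `densities`, `rank_stats`, `compartments`, `burden`
#'   tables and the per-assembly `details`.
#' @export
run_pipeline <- function(manifest, outdir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  params <- manifest$params
  lineage <- manifest$lineage
  if (is.character(lineage)) lineage <- read_lineage_tsv(lineage)

  details <- list()
  for (i in seq_along(manifest$assemblies)) {
    id <- names(manifest$assemblies)[i]
    .log_msg("assembly ", id)
    res <- tryCatch(
      .run_assembly(id, manifest$assemblies[[i]], params,
                    manifest$seed + 1000L * i),
      error = function(e) {
        warning("run_pipeline: assembly ", id, " failed: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res)) details[[id]] <- res
  }
  if (length(details) == 0L) stop("run_pipeline: every assembly failed")

  densities <- do.call(rbind, lapply(details, function(d) {
    data.frame(assembly_id = d$assembly_id, genome_bp = d$genome_bp,
               ir_bp = d$ir_bp, density = d$density,
               control_ir_bp = d$control_ir_bp,
               control_density = d$control_density, fe = d$fe,
               stringsAsFactors = FALSE)
  }))
  rownames(densities) <- NULL

  rank_stats <- NULL
  if (!is.null(lineage)) {
    li <- lineage[match(densities$assembly_id, lineage$assembly_id), ]
    sp_obs <- tapply(densities$density, li$species, species_density)
    sp_exp <- tapply(densities$control_density, li$species, species_density)
    sp2rank <- li[[params$group_by]][match(names(sp_obs), li$species)]
    groups <- list()
    for (rk in unique(sp2rank)) {
      sel <- sp2rank == rk
      if (sum(sel) >= 2L) {
        groups[[rk]] <- list(x = unname(sp_obs[sel]), y = unname(sp_exp[sel]))
      }
    }
    tests <- if (length(groups) > 0L) paired_test_with_bh(groups) else NULL
    frs <- data.frame(rank = unique(sp2rank),
                      n_species = as.integer(table(sp2rank)[unique(sp2rank)]),
                      F_R = vapply(unique(sp2rank), function(rk)
                        rank_density(sp_obs[sp2rank == rk]), 0),
                      F_R_control = vapply(unique(sp2rank), function(rk)
                        rank_density(sp_exp[sp2rank == rk]), 0),
                      stringsAsFactors = FALSE)
    frs$fe <- enrichment_fe(frs$F_R, frs$F_R_control)
    rank_stats <- if (!is.null(tests)) merge(frs, tests, by = "rank",
                                             all.x = TRUE) else frs
  }

  compartments <- do.call(rbind, lapply(names(details), function(id) {
    cc <- details[[id]]$compartments
    if (is.null(cc)) return(NULL)
    cc$assembly_id <- id
    cc
  }))
  burden <- do.call(rbind, lapply(names(details), function(id) {
    bb <- details[[id]]$burden
    if (is.null(bb)) return(NULL)
    bb$assembly_id <- id
    bb
  }))

  out <- list(densities = densities, rank_stats = rank_stats,
              compartments = compartments, burden = burden,
              details = details)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      if (!is.null(df)) {
        write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
    wt(densities, "densities.tsv")
    wt(rank_stats, "rank_stats.tsv")
    wt(compartments, "compartments.tsv")
    wt(burden, "burden.tsv")
    for (id in names(details)) {
      write_ir_bed(details[[id]]$irs, file.path(outdir, paste0(id, ".irs.bed")))
      for (anch in c("tss", "tes")) {
        pr <- details[[id]][[paste0("profile_", anch)]]
        if (!is.null(pr)) {
          wt(data.frame(offset = pr$offsets, raw_bp = pr$raw,
                        enrichment = pr$enrichment),
             paste0(id, ".profile_", anch, ".tsv"))
        }
      }
    }
    jsonlite::write_json(
      list(seed = manifest$seed, params = params,
           assemblies = names(manifest$assemblies),
           completed = names(details),
           package_version = as.character(utils::packageVersion("irtopo"))),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
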