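# End-to-end orchestration: repeats, SSRs, shared loci, divergence ranking
# and exports for a set of annotated genomes, with deterministic outputs
# for a fixed input set and seed.

#' Pipeline configuration
#'
#' Defaults follow the classic screen: minimum repeat length 30 bp with a
#' Hamming distance of 3; SSR unit thresholds 10/6/5/5/5/5 for motif
#' lengths 1-6; top 20 loci; amplicon screen 150-1000 bp.
#'
#' @param genomes Character vector of GenBank file paths, or a list of
#'   [plastome_record()]s.
#' @param sim Optional [sim_config()]; when given, genomes are simulated
#'   instead of read.
#' @param out_dir Optional output directory for TSV/FASTA/Newick exports.
#' @param seed Integer seed (used by the simulator stage).
#' @param min_repeat_len,max_mm Repeat-finder parameters.
#' @param ssr_thresholds SSR unit thresholds, see [scan_ssrs()].
#' @param flank_bp,min_flank_identity Homologous-SSR grouping parameters.
#' @param top_n,amplicon_min,amplicon_max Ranking parameters.
#' @param align Alignment scoring, see [alignment_params()].
#' @param min_ir_len Minimum IR arm length for [infer_region_map()].
#' @return A `run_config` list.
#' @export
run_config <- function(genomes = NULL, sim = NULL, out_dir = NULL,
                       seed = 1L, min_repeat_len = 30L, max_mm = 3L,
                       ssr_thresholds = ssr_default_thresholds,
                       flank_bp = 100L, min_flank_identity = 0.8,
                       top_n = 20L, amplicon_min = 150, amplicon_max = 1000,
                       align = alignment_params(), min_ir_len = 1000L) {
  if (is.null(genomes) && is.null(sim)) {
    abort("run_config needs input genomes or a simulation config")
  }
  structure(list(
    genomes = genomes, sim = sim, out_dir = out_dir, seed = as.integer(seed),
    min_repeat_len = as.integer(min_repeat_len), max_mm = as.integer(max_mm),
    ssr_thresholds = ssr_thresholds, flank_bp = as.integer(flank_bp),
    min_flank_identity = min_flank_identity, top_n = as.integer(top_n),
    amplicon_min = amplicon_min, amplicon_max = amplicon_max,
    align = align, min_ir_len = as.integer(min_ir_len)
  ), class = "run_config")
}

#' Run the comparative screen end to end
#'
#' Stages: load (or simulate) genomes; infer structural partitions; find
#' repeats and SSRs per genome; group homologous SSRs; derive and
#' intersect the locus catalogues; score pairwise divergence per shared
#' locus; rank candidate markers with the amplicon screen; export a
#' supermatrix of the top-ranked amplicon-sized loci plus a
#' neighbor-joining sanity tree. Outputs are deterministic for fixed
#' inputs and seed.
#'
#' @param cfg A [run_config()].
#' @return A report bundle: list with `records`, `region_maps`, `repeats`,
#'   `repeat_summaries`, `ssrs`, `ssr_groups`, `shared_loci`, `divergence`,
#'   `ranking`, `supermatrix`, `nj_tree`, and `summary` (per-stage counts).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  records <- load_pipeline_genomes(cfg)
  if (length(records) < 2L) {
    abort("the comparative screen needs at least 2 genomes (got 1)")
  }
  ids <- vapply(records, function(r) r$species_id, character(1))
  if (anyDuplicated(ids)) abort("species ids must be unique")
  names(records) <- ids

  region_maps <- lapply(records, infer_region_map,
                        min_ir_len = cfg$min_ir_len)
  repeats <- purrr::map2(records, region_maps, function(r, rm) {
    find_repeats(r$sequence, min_len = cfg$min_repeat_len,
                 max_mm = cfg$max_mm, region_map = rm)
  })
  repeat_summaries <- lapply(repeats, summarize_repeats)
  ssrs <- purrr::map2(records, region_maps, function(r, rm) {
    scan_ssrs(r, thresholds = cfg$ssr_thresholds, region_map = rm)
  })
  ssr_groups <- group_homologous_ssrs(
    records, hits_by_species = ssrs, flank_bp = cfg$flank_bp,
    min_flank_identity = cfg$min_flank_identity
  )
  catalogues <- purrr::map2(records, region_maps, derive_loci)
  shared <- intersect_across_species(catalogues)
  divergence <- pairwise_divergence(shared, params = cfg$align)
  ranking <- rank_loci(summarize_loci(divergence, shared),
                       top_n = cfg$top_n, amplicon_min = cfg$amplicon_min,
                       amplicon_max = cfg$amplicon_max)
  top_amplicon <- ranking %>%
    filter(.data$top, .data$amplicon_ok) %>%
    pull(.data$locus_name)
  supermatrix <- if (length(top_amplicon) >= 1L) {
    export_supermatrix(shared, loci = top_amplicon, params = cfg$align)
  } else {
    NULL
  }
  nj_tree <- nj_sanity_tree(divergence)

  summary <- list(
    n_species = length(records),
    genome_bp = setNames(vapply(records, function(r) r$length_bp,
                                integer(1)), ids),
    n_repeats = setNames(vapply(repeats, nrow, integer(1)), ids),
    n_ssrs = setNames(vapply(ssrs, nrow, integer(1)), ids),
    n_ssr_groups = if (nrow(ssr_groups)) {
      length(unique(ssr_groups$group_id))
    } else 0L,
    n_ssr_groups_shared_by_all = if (nrow(ssr_groups)) {
      length(unique(ssr_groups$group_id[ssr_groups$shared_by_all]))
    } else 0L,
    n_shared_loci = length(unique(shared$locus_name)),
    n_coding = sum(!duplicated(shared$locus_name) & shared$coding),
    n_noncoding = sum(!duplicated(shared$locus_name) & !shared$coding),
    n_pairs_per_locus = choose(length(records), 2L),
    top_loci = utils::head(ranking$locus_name, cfg$top_n)
  )

  bundle <- list(records = records, region_maps = region_maps,
                 repeats = repeats, repeat_summaries = repeat_summaries,
                 ssrs = ssrs, ssr_groups = ssr_groups,
                 shared_loci = shared, divergence = divergence,
                 ranking = ranking, supermatrix = supermatrix,
                 nj_tree = nj_tree, summary = summary)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(bundle, cfg)
  bundle
}

#' Save / load a resolved pipeline configuration
#'
#' The resolved configuration (all parameters, including any simulation
#' settings) is written as JSON; loading it and re-running gives
#' identical outputs for the same inputs.
#'
#' @param cfg A [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a `run_config` for the reader.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  # named atomic vectors must become objects, not nameless arrays
  out$ssr_thresholds <- as.list(out$ssr_thresholds)
  if (!is.null(out$sim)) {
    out$sim <- unclass(out$sim)
    out$sim$intron_genes <- as.list(out$sim$intron_genes)
  }
  if (is.list(out$genomes) && length(out$genomes) &&
        inherits(out$genomes[[1]], "plastome_record")) {
    abort("in-memory genome records cannot be serialized; pass file paths")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_fields <- raw$sim
    # planted element lists deserialize as data frames; rebuild lists
    fix_planted <- function(x, cols) {
      if (is.null(x) || length(x) == 0L) return(list())
      if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
      lapply(x, function(row) {
        row <- as.list(row)
        row[cols] <- lapply(row[cols], unlist)
        row
      })
    }
    sim_fields$planted_ssrs <- fix_planted(sim_fields$planted_ssrs,
                                           c("motif", "units"))
    sim_fields$planted_repeats <- fix_planted(
      sim_fields$planted_repeats, c("rtype", "length", "mismatches")
    )
    sim_fields$intron_genes <- unlist(sim_fields$intron_genes)
    sim <- do.call(sim_config, sim_fields)
  }
  run_config(
    genomes = raw$genomes, sim = sim, out_dir = raw$out_dir,
    seed = raw$seed, min_repeat_len = raw$min_repeat_len,
    max_mm = raw$max_mm, ssr_thresholds = unlist(raw$ssr_thresholds),
    flank_bp = raw$flank_bp, min_flank_identity = raw$min_flank_identity,
    top_n = raw$top_n, amplicon_min = raw$amplicon_min,
    amplicon_max = raw$amplicon_max,
    align = do.call(alignment_params, raw$align),
    min_ir_len = raw$min_ir_len
  )
}

load_pipeline_genomes <- function(cfg) {
  if (!is.null(cfg$sim)) {
    sim <- simulate_plastomes(cfg$sim)
    return(sim$records)
  }
  g <- cfg$genomes
  if (is.list(g) && length(g) && inherits(g[[1]], "plastome_record")) {
    return(g)
  }
  lapply(g, read_genbank)
}

write_pipeline_outputs <- function(bundle, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tsv(bind_rows(lapply(names(bundle$repeats), function(s) {
    mutate(bundle$repeats[[s]], species_id = s)
  })), "repeats.tsv")
  tsv(bind_rows(bundle$ssrs), "ssrs.tsv")
  tsv(bundle$ssr_groups, "ssr_groups.tsv")
  tsv(ssr_class_table(bind_rows(bundle$ssrs)), "ssr_classes.tsv")
  tsv(select(bundle$shared_loci, -"seq"), "shared_loci.tsv")
  tsv(bundle$divergence, "divergence_pairs.tsv")
  tsv(tidy(bundle$ranking), "locus_ranking.tsv")
  for (s in names(bundle$region_maps)) {
    write_region_bed(bundle$region_maps[[s]],
                     file.path(cfg$out_dir, paste0(s, "_regions.bed")),
                     chrom = s)
  }
  if (!is.null(bundle$supermatrix)) {
    write_supermatrix(bundle$supermatrix, cfg$out_dir)
  }
  ape::write.tree(bundle$nj_tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  jsonlite::write_json(bundle$summary,
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (is.null(cfg$genomes) || is.character(cfg$genomes)) {
    save_run_config(cfg, file.path(cfg$out_dir, "run_config.json"))
  }
  invisible(cfg$out_dir)
}
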