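# Locus catalogue per genome: one locus per annotated gene (exon union),
# one per intron (gap between consecutive exons of a gene), one intergenic
# spacer (IGS) per nonempty gap between consecutive distinct features
# around the circle (named A-B in genome order), and pseudogene loci.
# Cross-species intersection by name gives the shared homologous loci.

#' Derive the locus catalogue of one annotated genome
#'
#' tRNA anticodon suffixes (e.g. `trnL-UAA`) are stripped to the bare gene
#' symbol for naming and matching. Genes duplicated by the inverted repeat
#' keep one row per copy; their matching key is disambiguated with the
#' structural arm (`IRa`/`IRb`). Overlapping features produce no IGS (a
#' warning is logged); abutting features (end == start) likewise yield
#' none.
#'
#' @param rec A [plastome_record()] with at least 2 features.
#' @param region_map Optional `region_map` (inferred when the genome is
#'   large enough).
#' @return Tibble with `locus_name`, `match_key`, `ltype` (gene, intron,
#'   IGS, pseudogene), `coding`, `start`, `end` (0-based half-open, `end`
#'   may exceed the genome length for the wrapping IGS), `strand`,
#'   `region`, `seq`, `species_id`.
#' @export
derive_loci <- function(rec, region_map = NULL) {
  ft <- rec$features
  if (nrow(ft) < 2L) abort("need at least 2 annotated features")
  n <- rec$length_bp
  if (is.null(region_map) && n >= 2000L) {
    region_map <- infer_region_map(rec)
  }
  # prefer gene/tRNA/rRNA/pseudogene rows; keep CDS only when it is the
  # sole annotation of its symbol
  primary <- ft[ft$kind != "CDS", , drop = FALSE]
  cds_only <- ft[ft$kind == "CDS" & !(strip_symbol(ft$name) %in%
                                        strip_symbol(primary$name)), ,
                 drop = FALSE]
  ft <- bind_rows(primary, cds_only)
  ft$symbol <- strip_symbol(ft$name)
  ft <- arrange(ft, .data$start, .data$end)

  loci <- list()
  add <- function(locus_name, ltype, start, end, strand) {
    coding <- ltype == "gene"
    loci[[length(loci) + 1L]] <<- tibble(
      locus_name = locus_name, ltype = ltype, coding = coding,
      start = as.integer(start), end = as.integer(end), strand = strand
    )
  }

  for (i in seq_len(nrow(ft))) {
    ltype <- if (ft$kind[i] == "pseudogene") "pseudogene" else "gene"
    nm <- if (ltype == "pseudogene") paste0(ft$symbol[i], "psi") else ft$symbol[i]
    add(nm, ltype, ft$start[i], ft$end[i], ft$strand[i])
    parts <- ft$parts[[i]]
    if (nrow(parts) > 1L) {
      parts <- arrange(parts, .data$start)
      for (j in seq_len(nrow(parts) - 1L)) {
        if (parts$start[j + 1L] > parts$end[j]) {
          add(sprintf("%s.intron%d", ft$symbol[i], j), "intron",
              parts$end[j], parts$start[j + 1L], ft$strand[i])
        }
      }
    }
  }

  # IGS between consecutive distinct features around the circle
  for (i in seq_len(nrow(ft))) {
    j <- if (i < nrow(ft)) i + 1L else 1L
    gap_start <- ft$end[i]
    gap_end <- if (i < nrow(ft)) ft$start[j] else ft$start[j] + n
    if (gap_end > gap_start) {
      add(paste0(ft$symbol[i], "-", ft$symbol[j]), "IGS",
          gap_start, gap_end, "+")
    } else if (gap_end < gap_start) {
      warn(sprintf("features %s and %s overlap; no IGS derived",
                   ft$name[i], ft$name[j]))
    }
  }

  out <- bind_rows(loci)
  out$species_id <- rec$species_id
  out$region <- if (!is.null(region_map)) {
    locate_region(region_map, out$start, out$end)
  } else {
    rep(NA_character_, nrow(out))
  }
  arm <- if (!is.null(region_map) && !attr(region_map, "degenerate")) {
    locate_arm(region_map, out$start, out$end)
  } else {
    out$region
  }
  # exact-name duplicates (IR-duplicated genes and spacers) are keyed by
  # their structural arm; unique names match on the name alone
  out <- out %>%
    mutate(base_key = canonical_locus_key(.data$locus_name, .data$ltype)) %>%
    group_by(.data$base_key) %>%
    mutate(match_key = if (dplyr::n() > 1L) {
      paste0(.data$base_key, "@", arm[dplyr::cur_group_rows()])
    } else {
      .data$base_key
    }) %>%
    ungroup() %>%
    select(-"base_key")
  # extract sequences (exon union for multi-part genes)
  out$seq <- vapply(seq_len(nrow(out)), function(i) {
    row <- out[i, ]
    if (row$ltype %in% c("gene", "pseudogene")) {
      fi <- which(ft$start == row$start & ft$end == row$end &
                    strip_symbol(ft$name) == sub("psi$", "", row$locus_name))
      if (length(fi) >= 1L) return(feature_sequence(rec, ft[fi[1], ]))
    }
    extract_span(rec, row$start, row$end, row$strand)
  }, character(1))
  select(out, "locus_name", "match_key", "ltype", "coding", "start", "end",
         "strand", "region", "seq", "species_id")
}

strip_symbol <- function(name) {
  sub("-[ACGTU]{3}$", "", name)
}

# IGS names match their reversed form (A-B == B-A) to absorb strand and
# rotation differences between genomes
canonical_locus_key <- function(name, ltype) {
  vapply(seq_along(name), function(i) {
    if (ltype[i] != "IGS") return(name[i])
    ab <- strsplit(name[i], "-", fixed = TRUE)[[1]]
    if (length(ab) != 2L) return(name[i])
    paste(sort(ab), collapse = "-")
  }, character(1))
}

# arm-level label (LSC/SSC/IRa/IRb) for duplicate disambiguation
locate_arm <- function(rm, start, end) {
  n <- attr(rm, "length_bp")
  mid <- ((start + end) %/% 2L) %% n
  vapply(mid, function(m) {
    for (i in seq_len(nrow(rm))) {
      if (circ_contains(rm$start[i], rm$end[i] - rm$start[i], m, n)) {
        return(rm$region[i])
      }
    }
    "LSC"
  }, character(1))
}

#' Intersect locus catalogues across species
#'
#' Keeps the loci whose (canonicalized) names occur in every species, with
#' per-species sequences and structural regions attached. IGS names also
#' match their reversed form (`A-B` == `B-A`). A per-species tibble of
#' unmatched loci is attached as the `"unmatched"` attribute.
#'
#' @param catalogues Named list of per-species tibbles from
#'   [derive_loci()], or a list of [plastome_record()]s (catalogues are
#'   derived).
#' @return Long tibble of shared loci: `locus_name`, `ltype`, `coding`,
#'   `species_id`, `region`, `seq`, one row per locus x species.
#' @export
intersect_across_species <- function(catalogues) {
  if (length(catalogues) < 2L) abort("need at least 2 species")
  if (inherits(catalogues[[1]], "plastome_record")) {
    catalogues <- lapply(catalogues, derive_loci)
  }
  all_loci <- bind_rows(catalogues)
  species <- unique(all_loci$species_id)
  # one row per (species, key): duplicates beyond arm disambiguation keep
  # the first occurrence in genome order
  dedup <- all_loci %>%
    group_by(.data$species_id, .data$match_key) %>%
    slice(1) %>%
    ungroup()
  shared_keys <- dedup %>%
    dplyr::count(.data$match_key) %>%
    filter(.data$n == length(species)) %>%
    pull(.data$match_key)
  shared <- dedup %>%
    filter(.data$match_key %in% shared_keys) %>%
    group_by(.data$match_key) %>%
    mutate(locus_name = .data$locus_name[1]) %>%  # one display name
    ungroup() %>%
    select("locus_name", "match_key", "ltype", "coding", "species_id",
           "region", "start", "end", "seq") %>%
    arrange(.data$match_key, .data$species_id)
  unmatched <- dedup %>%
    filter(!.data$match_key %in% shared_keys) %>%
    select("species_id", "locus_name", "match_key", "ltype")
  attr(shared, "unmatched") <- unmatched
  shared
}

#' Write the shared-locus catalogue and per-locus FASTA files
#'
#' @param shared Tibble from [intersect_across_species()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus_catalogue <- function(shared, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- shared %>%
    mutate(len = nchar(.data$seq)) %>%
    select("locus_name", "ltype", "coding", "species_id", "len",
           "region") %>%
    tidyr::pivot_wider(names_from = "species_id",
                       values_from = c("len", "region"))
  write.table(wide, file.path(dir, "shared_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fasta_dir <- file.path(dir, "loci_fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  for (locus in unique(shared$locus_name)) {
    sub <- shared[shared$locus_name == locus, ]
    ss <- Biostrings::DNAStringSet(setNames(sub$seq, sub$species_id))
    safe <- gsub("[^A-Za-z0-9._-]", "_", locus)
    Biostrings::writeXStringSet(ss, file.path(fasta_dir,
                                              paste0(safe, ".fasta")))
  }
  invisible(dir)
}
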