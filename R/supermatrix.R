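# Concatenated supermatrix export: per-locus multiple alignments built by
# progressive merging of pairwise alignments against the first species
# (adequate for near-identical plastome loci; externally produced
# alignments can be supplied instead), plus partition table, relaxed
# PHYLIP / FASTA writers, and an optional neighbor-joining sanity tree.

#' Multiple alignment of one locus across species
#'
#' Progressive star merge: every species is aligned pairwise to the first
#' species (guide order = input order) and the pairwise alignments are
#' merged on the shared reference row.
#'
#' @param seqs Named character vector of per-species sequences.
#' @param params Alignment scoring, see [alignment_params()].
#' @return Named character vector of equal-length aligned rows.
#' @export
align_locus_msa <- function(seqs, params = alignment_params()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  ref <- seqs[[1]]
  l0 <- nchar(ref)
  pairs <- lapply(seqs[-1], function(s) align_pair(ref, s, params))
  # insertion slots: gaps in the reference row before base p+1 (slot p in
  # 0..l0)
  slot_counts <- lapply(pairs, function(aln) {
    rref <- strsplit(aln[1], "", fixed = TRUE)[[1]]
    slots <- integer(l0 + 1L)
    p <- 0L
    for (ch in rref) {
      if (ch == "-") slots[p + 1L] <- slots[p + 1L] + 1L else p <- p + 1L
    }
    slots
  })
  ins <- Reduce(pmax, slot_counts, integer(l0 + 1L))
  build_row <- function(aln_ref, aln_row, slots) {
    rref <- strsplit(aln_ref, "", fixed = TRUE)[[1]]
    rrow <- strsplit(aln_row, "", fixed = TRUE)[[1]]
    out <- character(0)
    p <- 0L
    i <- 1L
    for (slot in 0:l0) {
      # emit this slot's insertion characters, padded to ins[slot + 1]
      k <- slots[slot + 1L]
      if (k > 0L) {
        out <- c(out, rrow[i:(i + k - 1L)])
        i <- i + k
      }
      if (ins[slot + 1L] > k) out <- c(out, rep("-", ins[slot + 1L] - k))
      if (slot < l0) {  # the aligned column of ref base slot + 1
        out <- c(out, rrow[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }
  ref_slots <- integer(l0 + 1L)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  ref_row <- build_row(paste(ref_chars, collapse = ""), ref, ref_slots)
  rows <- c(setNames(ref_row, names(seqs)[1]),
            setNames(vapply(seq_along(pairs), function(j) {
              build_row(pairs[[j]][1], pairs[[j]][2], slot_counts[[j]])
            }, character(1)), names(seqs)[-1]))
  rows
}

#' Export a concatenated supermatrix with a partition table
#'
#' @param shared Shared-locus tibble from [intersect_across_species()],
#'   restricted to the selected loci.
#' @param loci Optional character vector of locus names to concatenate
#'   (default: all, in order of appearance).
#' @param params Alignment scoring for the per-locus alignments.
#' @param msa Optional named list (by locus name) of pre-aligned named
#'   row vectors, e.g. imported external alignments.
#' @return List with `matrix` (named character vector, one row per
#'   species) and `partitions` (tibble `locus_name`, `start`, `end`,
#'   1-based inclusive column intervals).
#' @export
export_supermatrix <- function(shared, loci = unique(shared$locus_name),
                               params = alignment_params(), msa = NULL) {
  species <- sort(unique(shared$species_id))
  rows <- setNames(rep("", length(species)), species)
  parts <- list()
  col <- 0L
  for (locus in loci) {
    sub <- shared[shared$locus_name == locus, ]
    missing <- setdiff(species, sub$species_id)
    if (length(missing)) {
      abort(sprintf("species %s missing from locus %s", missing[1], locus))
    }
    aln <- if (!is.null(msa) && locus %in% names(msa)) {
      msa[[locus]]
    } else {
      align_locus_msa(setNames(sub$seq, sub$species_id), params)
    }
    w <- nchar(aln[[1]])
    rows[species] <- paste0(rows[species], unlist(aln)[species])
    parts[[length(parts) + 1L]] <- tibble(
      locus_name = locus, start = col + 1L, end = col + w
    )
    col <- col + w
  }
  list(matrix = rows, partitions = bind_rows(parts))
}

#' Write a supermatrix to FASTA, relaxed PHYLIP and a partition file
#'
#' The partition file uses the RAxML plain-text style
#' (`DNA, locus = start-end`).
#'
#' @param sm List from [export_supermatrix()].
#' @param dir Output directory.
#' @param basename File basename (default `"supermatrix"`).
#' @return `dir`, invisibly.
#' @export
write_supermatrix <- function(sm, dir, basename = "supermatrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::BStringSet(sm$matrix)
  Biostrings::writeXStringSet(ss, file.path(dir, paste0(basename, ".fasta")))
  write_relaxed_phylip(sm$matrix, file.path(dir, paste0(basename, ".phy")))
  part_lines <- sprintf("DNA, %s = %d-%d",
                        gsub("[^A-Za-z0-9._-]", "_", sm$partitions$locus_name),
                        sm$partitions$start, sm$partitions$end)
  writeLines(part_lines, file.path(dir, paste0(basename, ".partitions")))
  invisible(dir)
}

#' Write / read relaxed PHYLIP
#'
#' Relaxed PHYLIP: header `ntaxa ncols`, then `name<space>sequence` per
#' line with unrestricted name lengths.
#'
#' @param rows Named character vector of equal-length aligned rows.
#' @param path File path.
#' @return `path` invisibly for the writer; a named character vector for
#'   the reader.
#' @export
write_relaxed_phylip <- function(rows, path) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  lines <- c(sprintf(" %d %d", length(rows), nchar(rows[[1]])),
             sprintf("%s  %s", names(rows), unname(rows)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_relaxed_phylip
#' @export
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  setNames(vapply(parts, `[[`, character(1), 2L),
           vapply(parts, `[[`, character(1), 1L))
}

#' Neighbor-joining sanity tree from mean pairwise divergence
#'
#' Builds a distance matrix from the mean percent variation across loci for
#' each species pair and runs `ape::nj()`. This is a quick sanity check,
#' not a substitute for model-based phylogenetics.
#'
#' @param divs Pairwise tibble from [pairwise_divergence()].
#' @return An `ape::phylo` tree.
#' @export
nj_sanity_tree <- function(divs) {
  species <- sort(unique(c(divs$species_a, divs$species_b)))
  d <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  means <- divs %>%
    group_by(.data$species_a, .data$species_b) %>%
    summarise(m = mean(.data$pct) / 100, .groups = "drop")
  for (i in seq_len(nrow(means))) {
    d[means$species_a[i], means$species_b[i]] <- means$m[i]
    d[means$species_b[i], means$species_a[i]] <- means$m[i]
  }
  ape::nj(stats::as.dist(d))
}
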