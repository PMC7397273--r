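# Perfect microsatellite (SSR) scanning with per-motif-length unit
# thresholds, canonical motif classes, genomic-region assignment, and
# cross-species homologous-SSR grouping.
#
# Only perfect, simple SSRs are reported (no compound SSRs). A run meeting
# the threshold at two motif lengths (12xA is also 6xAA) is reported only
# at its primitive motif; runs are reported at their leftmost phase.

#' Default SSR unit thresholds
#'
#' Minimum repeat-unit counts per motif length: 10 for homopolymers, 6 for
#' dinucleotides, 5 for tri- through hexanucleotides.
#'
#' @export
ssr_default_thresholds <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                            `5` = 5L, `6` = 5L)

#' Scan a genome for perfect SSRs
#'
#' Finds all maximal perfect tandem runs of primitive 1-6 bp motifs meeting
#' the per-motif-length unit thresholds. Runs containing `N` are split at
#' the `N`; rotated re-reports of one run are collapsed to the leftmost
#' phase. The reported span covers whole units only.
#'
#' @param rec A [plastome_record()] or DNA string.
#' @param thresholds Named vector mapping motif length (`"1"`..`"6"`) to the
#'   minimum number of repeat units.
#' @param region_map Optional `region_map` used to label each hit with its
#'   structural region; computed from `rec` when possible.
#' @return Tibble with `species_id`, `motif`, `canonical_class`, `start`,
#'   `end` (0-based half-open), `n_repeats`, `region`.
#' @export
scan_ssrs <- function(rec, thresholds = ssr_default_thresholds,
                      region_map = NULL) {
  species_id <- NA_character_
  if (inherits(rec, "plastome_record")) {
    species_id <- rec$species_id
    if (is.null(region_map) && rec$length_bp >= 2000L) {
      region_map <- infer_region_map(rec)
    }
    seq <- rec$sequence
  } else {
    seq <- normalize_dna(rec)
  }
  check_dna(seq)
  if (!all(as.character(1:6) %in% names(thresholds))) {
    abort("thresholds must cover motif lengths 1..6")
  }
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (m in 1:6) {
    thr <- as.integer(thresholds[[as.character(m)]])
    if (n < m * thr) next
    # period-m agreement indicator: ch[i] == ch[i + m], N matches nothing
    a <- ch[seq_len(n - m)]
    b <- ch[(m + 1L):n]
    eq <- a == b & a != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= m * (thr - 1L))) {
      run_start <- starts[j]          # 1-based index into eq
      span_len <- r$lengths[j] + m    # periodic stretch length in bp
      pos0 <- run_start - 1L          # 0-based genome offset of stretch
      # slide right while the leading motif is non-primitive
      while (span_len >= m * thr) {
        motif <- substr(seq, pos0 + 1L, pos0 + m)
        if (!grepl("N", motif, fixed = TRUE) && is_primitive_motif(motif)) {
          units <- span_len %/% m
          hits[[length(hits) + 1L]] <- tibble(
            motif = motif,
            start = pos0,
            end = pos0 + units * m,
            n_repeats = units
          )
          break
        }
        pos0 <- pos0 + 1L
        span_len <- span_len - 1L
      }
    }
  }
  out <- if (length(hits)) bind_rows(hits) else {
    tibble(motif = character(), start = integer(), end = integer(),
           n_repeats = integer())
  }
  out <- out %>%
    mutate(species_id = species_id,
           canonical_class = vapply(.data$motif, canonical_class,
                                    character(1), USE.NAMES = FALSE)) %>%
    select("species_id", "motif", "canonical_class", "start", "end",
           "n_repeats") %>%
    arrange(.data$start, nchar(.data$motif))
  out$region <- if (!is.null(region_map) && nrow(out) > 0L) {
    locate_region(region_map, out$start, out$end)
  } else {
    rep(NA_character_, nrow(out))
  }
  out
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        strrep(substr(motif, 1L, d), m %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical class of an SSR motif
#'
#' Among all rotations of the motif and all rotations of its reverse
#' complement, the lexicographically smallest string is the class
#' representative; the class is rendered `"REP/REVCOMP(REP)"` (e.g. `TTC`
#' belongs to class `"AAG/CTT"`). The class is invariant under rotation,
#' strand flip, and phase.
#'
#' @param motif A primitive DNA motif of length 1-6.
#' @return Class label string.
#' @export
canonical_class <- function(motif) {
  motif <- normalize_dna(motif)
  m <- nchar(motif)
  if (m < 1L || m > 6L) abort("motif length must be 1..6")
  if (!is_primitive_motif(motif)) {
    abort(sprintf("motif %s is not primitive", motif))
  }
  rots <- function(x) {
    k <- nchar(x)
    vapply(seq_len(k) - 1L, function(i) {
      paste0(substr(x, i + 1L, k), substr(x, 1L, i))
    }, character(1))
  }
  variants <- c(rots(motif), rots(revcomp(motif)))
  rep_motif <- min(variants)
  paste0(rep_motif, "/", revcomp(rep_motif))
}

#' Tabulate SSR counts per canonical class
#'
#' Per-species counts of SSR hits by canonical motif class, the classic
#' SSR-type table of comparative plastome studies.
#'
#' @param hits SSR hit tibble(s) from [scan_ssrs()], bound together.
#' @return Tibble `canonical_class` x `species_id` counts (wide).
#' @export
ssr_class_table <- function(hits) {
  hits %>%
    mutate(motif_len = nchar(sub("/.*$", "", .data$canonical_class))) %>%
    dplyr::count(.data$motif_len, .data$canonical_class, .data$species_id) %>%
    tidyr::pivot_wider(names_from = "species_id", values_from = "n",
                       values_fill = 0L) %>%
    arrange(.data$motif_len, .data$canonical_class)
}

#' Group homologous SSRs across species
#'
#' Two SSR hits from different genomes are homologous when they share a
#' canonical class and both flanking windows align with at least
#' `min_flank_identity` identity under the package's pairwise aligner.
#' Groups are connected components of that relation.
#'
#' @param records Named list of [plastome_record()]s (names = species ids).
#' @param hits_by_species Optional named list of SSR hit tibbles; scanned
#'   from `records` when omitted.
#' @param flank_bp Flanking window length on each side (bp).
#' @param min_flank_identity Minimum alignment identity (fraction) required
#'   of both flanks.
#' @param thresholds Passed to [scan_ssrs()] when hits are scanned here.
#' @return Tibble with one row per SSR hit: `group_id`, `species_id`,
#'   `canonical_class`, `start`, `end`, `n_repeats`, `shared_by_all`,
#'   `length_variable`.
#' @export
group_homologous_ssrs <- function(records, hits_by_species = NULL,
                                  flank_bp = 100L,
                                  min_flank_identity = 0.8,
                                  thresholds = ssr_default_thresholds) {
  if (length(records) < 2L) abort("need at least 2 species")
  ids <- vapply(records, function(r) r$species_id, character(1))
  names(records) <- ids
  if (is.null(hits_by_species)) {
    hits_by_species <- lapply(records, scan_ssrs, thresholds = thresholds)
  }
  all_hits <- bind_rows(hits_by_species)
  if (nrow(all_hits) == 0L) {
    return(tibble(group_id = integer(), species_id = character(),
                  canonical_class = character(), start = integer(),
                  end = integer(), n_repeats = integer(),
                  shared_by_all = logical(), length_variable = logical()))
  }
  all_hits$hit_id <- seq_len(nrow(all_hits))
  # flanks (circular genomes: wrap around the origin)
  flanks <- purrr::map(seq_len(nrow(all_hits)), function(i) {
    rec <- records[[all_hits$species_id[i]]]
    n <- rec$length_bp
    s <- all_hits$start[i]; e <- all_hits$end[i]
    if (rec$is_circular) {
      left <- extract_span(rec, (s - flank_bp) %% n,
                           (s - flank_bp) %% n + flank_bp)
      right <- extract_span(rec, e %% n, e %% n + flank_bp)
      list(left = left, right = right, ok = TRUE)
    } else {
      ok <- s - flank_bp >= 0L && e + flank_bp <= n
      if (!ok) {
        warn(sprintf("hit %d at sequence end excluded from grouping", i))
        return(list(left = "", right = "", ok = FALSE))
      }
      list(left = substr(rec$sequence, s - flank_bp + 1L, s),
           right = substr(rec$sequence, e + 1L, e + flank_bp), ok = TRUE)
    }
  })
  usable <- which(vapply(flanks, function(f) f$ok, logical(1)))
  parent <- seq_len(nrow(all_hits))
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ci in unique(all_hits$canonical_class)) {
    members <- intersect(which(all_hits$canonical_class == ci), usable)
    if (length(members) < 2L) next
    for (a in seq_along(members)) {
      for (b in seq_len(a - 1L)) {
        i <- members[a]; j <- members[b]
        if (all_hits$species_id[i] == all_hits$species_id[j]) next
        if (find_root(i) == find_root(j)) next
        ok_l <- flank_identity(flanks[[i]]$left, flanks[[j]]$left) >=
          min_flank_identity
        if (!ok_l) next
        ok_r <- flank_identity(flanks[[i]]$right, flanks[[j]]$right) >=
          min_flank_identity
        if (ok_r) parent[find_root(i)] <- find_root(j)
      }
    }
  }
  roots <- vapply(seq_len(nrow(all_hits)), find_root, integer(1))
  all_hits$group_id <- as.integer(factor(roots, levels = unique(roots)))
  n_species <- length(records)
  all_hits %>%
    group_by(.data$group_id) %>%
    mutate(
      shared_by_all = dplyr::n_distinct(.data$species_id) == n_species,
      length_variable = dplyr::n_distinct(.data$end - .data$start) > 1L
    ) %>%
    ungroup() %>%
    select("group_id", "species_id", "canonical_class", "start", "end",
           "n_repeats", "shared_by_all", "length_variable") %>%
    arrange(.data$group_id, .data$species_id)
}

flank_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  aln <- align_pair(a, b)
  v1 <- strsplit(aln[1], "", fixed = TRUE)[[1]]
  v2 <- strsplit(aln[2], "", fixed = TRUE)[[1]]
  sum(v1 == v2 & v1 != "-") / length(v1)
}

#' Bar-chart of SSR counts per structural region
#'
#' @param hits Bound SSR hit tibbles from [scan_ssrs()] with `region` set.
#' @return A ggplot object.
#' @export
plot_ssr_regions <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$species_id,
                                     fill = .data$region)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "SSR count", fill = "region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
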