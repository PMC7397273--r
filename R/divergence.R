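# Per-locus molecular variation: global pairwise alignment, the
# percent-variation statistic 100 * (NS + ID) / L with indel-run
# collapsing (one maximal run of contiguous gap columns = one event,
# whatever its length), averaging over all species pairs, and marker
# ranking with an amplicon-length screen.

#' Default pairwise alignment scoring
#'
#' Global (Needleman-Wunsch) alignment with affine gaps: match +1,
#' mismatch -1, gap open -2, gap extend -0.5 per base.
#'
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = 2,
                             gap_extend = 0.5) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

align_submat <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- 0  # N is scored neutrally against everything
  m[, "N"] <- 0
  m
}

#' Globally align a pair of sequences
#'
#' Optimal global affine-gap alignment (via `Biostrings::pairwiseAlignment`)
#' under [alignment_params()]. Every input base appears exactly once in the
#' output and no column is gap/gap. The pair is canonically ordered before
#' aligning so that `align_pair(a, b)` and `align_pair(b, a)` give the same
#' alignment with rows swapped.
#'
#' @param seq_a,seq_b Non-empty DNA strings.
#' @param params Scoring scheme from [alignment_params()].
#' @return Character vector of two equal-length gapped strings.
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- normalize_dna(seq_a); seq_b <- normalize_dna(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    abort("sequences must be non-empty")
  }
  if (identical(seq_a, seq_b)) return(c(seq_a, seq_b))
  swapped <- seq_a > seq_b
  p <- if (swapped) seq_b else seq_a
  s <- if (swapped) seq_a else seq_b
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "global",
    substitutionMatrix = align_submat(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  row_p <- as.character(Biostrings::alignedPattern(aln))
  row_s <- as.character(Biostrings::alignedSubject(aln))
  if (swapped) c(row_s, row_p) else c(row_p, row_s)
}

#' Count divergence in an aligned pair
#'
#' Applies the percent-variation statistic: `NS` is the number of columns
#' with two different bases (columns pairing `N` with a base are not
#' counted), `ID` is the number of indel events, where one maximal run of
#' contiguous gap columns in one row counts as a single event regardless of
#' its length, and `L` is the alignment length in columns. The statistic is
#' `pct = 100 * (NS + ID) / L`.
#'
#' @param aln Character vector of two equal-length gapped rows (no gap/gap
#'   column), as returned by [align_pair()].
#' @return One-row tibble with `NS`, `ID`, `L`, `pct`.
#' @export
count_divergence <- function(aln) {
  stopifnot(length(aln) == 2L)
  v1 <- strsplit(aln[1], "", fixed = TRUE)[[1]]
  v2 <- strsplit(aln[2], "", fixed = TRUE)[[1]]
  if (length(v1) != length(v2)) abort("alignment rows differ in length")
  g1 <- v1 == "-"
  g2 <- v2 == "-"
  if (any(g1 & g2)) abort("alignment contains a gap/gap column")
  NS <- sum(!g1 & !g2 & v1 != v2 & v1 != "N" & v2 != "N")
  # one maximal run of gap columns in one row = one event; a run ends where
  # the gapped row switches
  state <- integer(length(v1))
  state[g1] <- 1L
  state[g2] <- 2L
  r <- rle(state)
  ID <- sum(r$values != 0L)
  L <- length(v1)
  tibble(NS = as.integer(NS), ID = as.integer(ID), L = as.integer(L),
         pct = 100 * (NS + ID) / L)
}

#' Pairwise divergence for every shared locus and species pair
#'
#' Aligns each homologous locus for every unordered species pair and applies
#' [count_divergence()]. With 7 species this is the classic 21 paired
#' comparisons per locus.
#'
#' @param loci Homologous-locus tibble from [intersect_across_species()]
#'   (columns `locus_name`, `ltype`, `species_id`, `seq`).
#' @param params Alignment scoring, see [alignment_params()].
#' @param alignments Optional named list of pre-computed pairwise
#'   alignments (names `"locus|sp_a|sp_b"`, each a 2-row gapped character
#'   vector, e.g. imported from an external aligner); used instead of the
#'   internal aligner where present.
#' @return Tibble with `locus_name`, `species_a`, `species_b`, `NS`, `ID`,
#'   `L`, `pct`.
#' @export
pairwise_divergence <- function(loci, params = alignment_params(),
                                alignments = NULL) {
  species <- sort(unique(loci$species_id))
  if (length(species) < 2L) abort("need at least 2 species")
  pairs <- combn(species, 2L)
  out <- vector("list", 0L)
  for (locus in unique(loci$locus_name)) {
    sub <- loci[loci$locus_name == locus, ]
    seqs <- setNames(sub$seq, sub$species_id)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      if (!a %in% names(seqs) || !b %in% names(seqs)) next
      key <- paste(locus, a, b, sep = "|")
      aln <- if (!is.null(alignments) && key %in% names(alignments)) {
        alignments[[key]]
      } else {
        align_pair(seqs[[a]], seqs[[b]], params)
      }
      d <- count_divergence(aln)
      out[[length(out) + 1L]] <- tibble(
        locus_name = locus, species_a = a, species_b = b,
        NS = d$NS, ID = d$ID, L = d$L, pct = d$pct
      )
    }
  }
  bind_rows(out)
}

#' Summarize per-locus variation over all species pairs
#'
#' @param divs Tibble from [pairwise_divergence()].
#' @param loci The homologous-locus tibble the divergences came from (for
#'   locus types and unaligned lengths).
#' @return A `locus_variation` tibble: `locus_name`, `ltype`, `coding`,
#'   `mean_pct` (arithmetic mean of `pct` over all pairs), `avg_length_bp`
#'   (mean unaligned length over species), `n_pairs`.
#' @export
summarize_loci <- function(divs, loci) {
  n_species <- length(unique(loci$species_id))
  expected_pairs <- choose(n_species, 2L)
  per_locus <- divs %>%
    group_by(.data$locus_name) %>%
    summarise(mean_pct = mean(.data$pct), n_pairs = dplyr::n(),
              .groups = "drop")
  bad <- per_locus$locus_name[per_locus$n_pairs != expected_pairs]
  if (length(bad)) {
    abort(sprintf("locus %s has %s of the %d expected species pairs",
                  bad[1],
                  per_locus$n_pairs[per_locus$locus_name == bad[1]],
                  expected_pairs))
  }
  meta <- loci %>%
    group_by(.data$locus_name) %>%
    summarise(ltype = .data$ltype[1], coding = .data$coding[1],
              avg_length_bp = mean(nchar(.data$seq)), .groups = "drop")
  out <- per_locus %>%
    left_join(meta, by = "locus_name") %>%
    select("locus_name", "ltype", "coding", "mean_pct", "avg_length_bp",
           "n_pairs")
  class(out) <- c("locus_variation", class(out))
  out
}

#' Check a single locus' pairwise results for completeness
#'
#' One entry per unordered species pair is required; the offending pair is
#' named otherwise.
#'
#' @param divs Pairwise tibble for one locus.
#' @param species Character vector of all species ids.
#' @return The mean `pct` and `n_pairs`, invisibly a one-row tibble.
#' @export
summarize_locus <- function(divs, species = sort(unique(c(divs$species_a,
                                                          divs$species_b)))) {
  pairs <- combn(sort(species), 2L)
  have <- paste(divs$species_a, divs$species_b, sep = "|")
  have <- c(have, paste(divs$species_b, divs$species_a, sep = "|"))
  want <- paste(pairs[1, ], pairs[2, ], sep = "|")
  missing <- setdiff(want, have)
  if (length(missing)) {
    abort(sprintf("missing species pair: %s",
                  gsub("|", " vs ", missing[1], fixed = TRUE)))
  }
  tibble(mean_pct = mean(divs$pct), n_pairs = ncol(pairs))
}

#' Rank loci as candidate markers
#'
#' Sorts by mean percent variation (descending), breaking ties by longer
#' average length then name, and applies the amplicon-length screen
#' (default 150-1000 bp average unaligned length, the range convenient for
#' Sanger sequencing).
#'
#' @param summaries `locus_variation` tibble from [summarize_loci()].
#' @param top_n Number of top loci to flag (default 20).
#' @param amplicon_min,amplicon_max Amplicon screen bounds in bp.
#' @return The summaries with `rank`, `top` and `amplicon_ok` columns,
#'   ordered by rank.
#' @export
rank_loci <- function(summaries, top_n = 20L, amplicon_min = 150,
                      amplicon_max = 1000) {
  if (nrow(summaries) == 0L) abort("no locus summaries to rank")
  out <- summaries %>%
    arrange(desc(.data$mean_pct), desc(.data$avg_length_bp),
            .data$locus_name) %>%
    mutate(rank = row_number(),
           top = .data$rank <= top_n,
           amplicon_ok = .data$avg_length_bp >= amplicon_min &
             .data$avg_length_bp <= amplicon_max)
  class(out) <- unique(c("locus_variation", class(out)))
  out
}

#' @export
tidy.locus_variation <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.locus_variation <- function(x, ...) {
  tibble(
    n_loci = nrow(x),
    n_coding = sum(x$coding),
    n_noncoding = sum(!x$coding),
    mean_pct_overall = mean(x$mean_pct),
    max_pct = max(x$mean_pct),
    n_pairs = if (nrow(x)) x$n_pairs[1] else NA_integer_
  )
}

#' Dot plot of per-locus variation, split by coding status
#'
#' @param summaries `locus_variation` tibble (ranked or not).
#' @param top_n Highlight the `top_n` most variable loci.
#' @return A ggplot object.
#' @export
plot_locus_variation <- function(summaries, top_n = 20L) {
  df <- summaries %>%
    arrange(desc(.data$mean_pct)) %>%
    mutate(highlight = row_number() <= top_n,
           coding_lab = ifelse(.data$coding, "coding", "non-coding"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_length_bp,
                                   y = .data$mean_pct,
                                   colour = .data$highlight)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~coding_lab) +
    ggplot2::labs(x = "average locus length (bp)",
                  y = "mean % variation over species pairs",
                  colour = "top ranked") +
    ggplot2::theme_minimal()
}
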