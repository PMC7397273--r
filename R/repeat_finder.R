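# Long repeated sequences of four orientation types under a Hamming
# mismatch budget, in the style of classic plastome repeat screens:
# forward (s1 ~ s2), reverse (s1 ~ reverse(s2)), palindromic
# (s1 ~ revcomp(s2)) and complement (s1 ~ complement(s2)).

REPEAT_TYPES <- c("forward", "reverse", "palindromic", "complement")
REPEAT_BIN_EDGES <- c(30, 45, 60, 75, 90, Inf)
REPEAT_BIN_LABELS <- c("[30,45)", "[45,60)", "[60,75)", "[75,90)", "[90,Inf)")

#' Find maximal repeated sequence pairs
#'
#' Enumerates every maximal pair of repeated segments of the requested
#' orientation types with at most `max_mm` mismatching aligned positions
#' and length at least `min_len`. A pair is maximal when extending both
#' endpoints jointly by one base in either direction would exceed the
#' mismatch budget or leave the sequence. Positions holding `N` always
#' count as mismatches. The scan is over the linearized sequence; repeats
#' spanning the origin of a circular molecule are not searched.
#'
#' @param seq A DNA string, or a [plastome_record()].
#' @param min_len Minimum repeat length in bp (default 30).
#' @param max_mm Maximum Hamming mismatches allowed (default 3).
#' @param types Subset of `c("forward", "reverse", "palindromic",
#'   "complement")`.
#' @param region_map Optional `region_map`; when supplied, hits whose two
#'   segments reciprocally overlap the IR arm pair by at least
#'   `ir_overlap` are flagged `ir_artifact` (the structural IR pair itself
#'   is one giant palindromic hit).
#' @param ir_overlap Reciprocal-overlap fraction for the IR-artifact flag.
#' @return Tibble with columns `rtype`, `pos1`, `pos2` (0-based starts,
#'   `pos1 <= pos2`), `length`, `mismatches`, `ir_artifact`.
#' @export
find_repeats <- function(seq, min_len = 30L, max_mm = 3L,
                         types = REPEAT_TYPES, region_map = NULL,
                         ir_overlap = 0.9) {
  if (inherits(seq, "plastome_record")) {
    if (is.null(region_map)) region_map <- infer_region_map(seq)
    seq <- seq$sequence
  }
  seq <- normalize_dna(seq)
  check_dna(seq)
  if (min_len < 8L) abort("min_len must be at least 8")
  if (max_mm < 0L) abort("max_mm must be non-negative")
  types <- match.arg(types, REPEAT_TYPES, several.ok = TRUE)
  empty <- tibble(rtype = character(), pos1 = integer(), pos2 = integer(),
                  length = integer(), mismatches = integer(),
                  ir_artifact = logical())
  if (nchar(seq) < min_len) return(empty)
  raw <- find_repeats_cpp(encode_dna(seq), as.integer(min_len),
                          as.integer(max_mm), REPEAT_TYPES %in% types)
  if (nrow(raw) == 0L) return(empty)
  hits <- as_tibble(raw) %>%
    mutate(rtype = REPEAT_TYPES[.data$rtype_code]) %>%
    select("rtype", "pos1", "pos2", "length", "mismatches") %>%
    arrange(.data$rtype, .data$pos1, .data$pos2)
  hits$ir_artifact <- flag_ir_artifact(hits, region_map, ir_overlap)
  hits
}

flag_ir_artifact <- function(hits, rm, ir_overlap) {
  if (is.null(rm) || isTRUE(attr(rm, "degenerate"))) {
    return(rep(FALSE, nrow(hits)))
  }
  ira <- rm[rm$region == "IRa", ]
  irb <- rm[rm$region == "IRb", ]
  n <- attr(rm, "length_bp")
  recip <- function(s, l, rs, re) {
    # linear hit segment vs (possibly wrapping) region interval
    ov <- max(0L, min(s + l, re) - max(s, rs))
    if (re > n) ov <- max(ov, max(0L, min(s + l, re - n) - max(s, 0L)))
    min(ov / l, ov / (re - rs))
  }
  vapply(seq_len(nrow(hits)), function(i) {
    if (hits$rtype[i] != "palindromic") return(FALSE)
    s1 <- hits$pos1[i]; s2 <- hits$pos2[i]; l <- hits$length[i]
    o1 <- max(recip(s1, l, ira$start, ira$end), recip(s1, l, irb$start, irb$end))
    o2 <- max(recip(s2, l, ira$start, ira$end), recip(s2, l, irb$start, irb$end))
    o1 >= ir_overlap && o2 >= ir_overlap
  }, logical(1))
}

#' Summarize repeat hits by type and length bin
#'
#' @param hits Tibble from [find_repeats()] (a single genome).
#' @param drop_ir_artifact Exclude hits flagged as the structural-IR
#'   self-hit from the counts?
#' @return List with tibbles `counts_by_type` and `counts_by_bin`; both
#'   total to the number of hits counted.
#' @export
summarize_repeats <- function(hits, drop_ir_artifact = FALSE) {
  if (drop_ir_artifact && nrow(hits) > 0L) {
    hits <- filter(hits, !.data$ir_artifact)
  }
  by_type <- tibble(rtype = REPEAT_TYPES) %>%
    left_join(dplyr::count(hits, .data$rtype), by = "rtype") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  bin <- cut(hits$length, breaks = REPEAT_BIN_EDGES, right = FALSE,
             labels = REPEAT_BIN_LABELS)
  by_bin <- tibble(length_bin = REPEAT_BIN_LABELS) %>%
    left_join(tibble(length_bin = as.character(bin)) %>%
                dplyr::count(.data$length_bin),
              by = "length_bin") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  list(counts_by_type = by_type, counts_by_bin = by_bin)
}

#' Bar-chart of repeat counts by type and length bin
#'
#' Data view analogous to the classic per-species repeat figures.
#'
#' @param hits Tibble from [find_repeats()].
#' @inheritParams summarize_repeats
#' @return A ggplot object.
#' @export
plot_repeat_summary <- function(hits, drop_ir_artifact = FALSE) {
  if (drop_ir_artifact && nrow(hits) > 0L) {
    hits <- filter(hits, !.data$ir_artifact)
  }
  hits <- mutate(hits, length_bin = cut(.data$length,
                                        breaks = REPEAT_BIN_EDGES,
                                        right = FALSE,
                                        labels = REPEAT_BIN_LABELS))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$rtype,
                                     fill = .data$length_bin)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "repeat type", y = "count", fill = "length (bp)") +
    ggplot2::theme_minimal()
}
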