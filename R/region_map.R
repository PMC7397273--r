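# Quadripartite structural partition: LSC / IRa / SSC / IRb.
#
# The two inverted repeats are found as the longest pair of disjoint,
# exactly reverse-complementary segments on the circle (N never matches);
# the two remaining arcs become LSC (longer) and SSC (shorter). The
# mismatch-tolerant repeat finder is deliberately not used here: the
# structural partition that downstream region assignment relies on must be
# stable, so IR detection is exact.

#' Infer the LSC/SSC/IR partition of a circular plastome
#'
#' @param rec A [plastome_record()].
#' @param min_ir_len Minimum length (bp) of an inverted-repeat arm.
#' @return A `region_map` object: a tibble of `region`, `start`, `end`
#'   (0-based half-open on the circle; `end` may exceed the genome length
#'   for a wrapping interval) plus `length_bp` and `degenerate` attributes.
#'   With no inverted duplication of at least `min_ir_len`, a degenerate
#'   map with the whole genome as LSC is returned and flagged.
#' @export
infer_region_map <- function(rec, min_ir_len = 1000L) {
  n <- rec$length_bp
  degenerate <- function() {
    new_region_map(tibble(region = "LSC", start = 0L, end = n), n, TRUE)
  }
  if (n < 2L * min_ir_len) return(degenerate())
  doubled <- paste0(rec$sequence, rec$sequence)
  hits <- find_repeats_cpp(encode_dna(doubled), as.integer(min_ir_len), 0L,
                           c(FALSE, FALSE, TRUE, FALSE))
  if (nrow(hits) == 0L) return(degenerate())
  # normalize to the circle and keep disjoint arm pairs
  cand <- tibble(
    s1 = hits$pos1 %% n, s2 = hits$pos2 %% n, len = hits$length
  ) %>%
    filter(.data$len <= n) %>%
    distinct()
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    circular_disjoint(cand$s1[i], cand$s2[i], cand$len[i], n)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(degenerate())
  best <- cand %>% arrange(desc(.data$len), .data$s1, .data$s2) %>% slice(1)
  s1 <- best$s1; s2 <- best$s2; len <- best$len
  e1 <- (s1 + len) %% n
  e2 <- (s2 + len) %% n
  arc1 <- circ_len(e1, s2, n)  # arm1 -> arm2
  arc2 <- circ_len(e2, s1, n)  # arm2 -> arm1
  if (arc1 >= arc2) {
    lsc <- c(e1, arc1); ssc <- c(e2, arc2)
    ira <- c(s2, len); irb <- c(s1, len)
  } else {
    lsc <- c(e2, arc2); ssc <- c(e1, arc1)
    ira <- c(s1, len); irb <- c(s2, len)
  }
  regions <- tibble(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = as.integer(c(lsc[1], ira[1], ssc[1], irb[1])),
    end = as.integer(c(lsc[1] + lsc[2], ira[1] + ira[2],
                       ssc[1] + ssc[2], irb[1] + irb[2]))
  )
  new_region_map(regions, n, FALSE)
}

circular_disjoint <- function(s1, s2, len, n) {
  if (2L * len > n) return(FALSE)
  !circ_contains(s1, len, s2, n) && !circ_contains(s2, len, s1, n) &&
    !circ_contains(s1, len, (s2 + len - 1L) %% n, n) &&
    !circ_contains(s2, len, (s1 + len - 1L) %% n, n)
}

new_region_map <- function(regions, n, degenerate) {
  structure(regions, length_bp = n, degenerate = degenerate,
            class = c("region_map", class(regions)))
}

#' @export
print.region_map <- function(x, ...) {
  n <- attr(x, "length_bp")
  cat(sprintf("<region_map> genome %s bp%s\n", format(n, big.mark = ","),
              if (attr(x, "degenerate")) " (degenerate: no IR found)" else ""))
  NextMethod()
}

#' Region lengths of a region map
#'
#' @param rm A `region_map`.
#' @return Named integer vector of region lengths (bp).
#' @export
region_lengths <- function(rm) {
  setNames(as.integer(rm$end - rm$start), rm$region)
}

#' Locate spans on the structural partition
#'
#' Assigns each span to the region containing its midpoint on the circle.
#' Both IR copies map to the single label `IR`.
#'
#' @param rm A `region_map`.
#' @param start,end Integer vectors of 0-based half-open spans; `end` may
#'   exceed the genome length for wrapping spans.
#' @return Character vector of labels in `{LSC, SSC, IR}`.
#' @export
locate_region <- function(rm, start, end) {
  if (any(end <= start)) abort("empty span")
  n <- attr(rm, "length_bp")
  mid <- ((start + end) %/% 2L) %% n
  vapply(mid, function(m) {
    for (i in seq_len(nrow(rm))) {
      if (circ_contains(rm$start[i], rm$end[i] - rm$start[i], m, n)) {
        lab <- rm$region[i]
        return(if (lab %in% c("IRa", "IRb")) "IR" else lab)
      }
    }
    "LSC"  # unreachable for a covering map
  }, character(1))
}

#' Write a region map as BED
#'
#' 0-based half-open BED with names LSC/IRa/SSC/IRb; wrapping intervals are
#' split at the origin.
#'
#' @param rm A `region_map`.
#' @param path Output path.
#' @param chrom Chromosome/sequence name for the first BED column.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(rm, path, chrom = "plastome") {
  n <- attr(rm, "length_bp")
  rows <- purrr::map_dfr(seq_len(nrow(rm)), function(i) {
    s <- rm$start[i]; e <- rm$end[i]
    if (e <= n) {
      tibble(chrom = chrom, start = s, end = e, name = rm$region[i])
    } else {
      tibble(chrom = chrom, start = c(s, 0L), end = c(n, e - n),
             name = rm$region[i])
    }
  })
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
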