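# DNA string helpers. Sequences are plain uppercase character scalars over
# {A,C,G,T,N}; Biostrings is used where it is the established route, but the
# hot paths below work on raw strings to avoid repeated XString boxing.

DNA_BASES <- c("A", "C", "G", "T")

dna_complement_chr <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-string reverse complement over the `A`, `C`, `G`, `T`, `N`
#' alphabet. `N` complements to `N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(dna_complement_chr[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_dna <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(dna_complement_chr[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

reverse_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Draw a random DNA string
#'
#' Uniform i.i.d. bases; used by the simulator and in tests. Respects the
#' current RNG state.
#'
#' @param n Length in bp.
#' @param bases Alphabet to draw from.
#' @return A single DNA string of length `n`.
#' @export
random_dna <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# encode to integer codes A=0 C=1 G=2 T=3 N=4 for the C++ kernels
encode_dna <- function(s) {
  codes <- utf8ToInt(s)
  out <- integer(length(codes))
  out[codes == 65L] <- 0L  # A
  out[codes == 67L] <- 1L  # C
  out[codes == 71L] <- 2L  # G
  out[codes == 84L] <- 3L  # T
  other <- !(codes %in% c(65L, 67L, 71L, 84L))
  out[other] <- 4L
  out
}

check_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L) {
    abort(sprintf("%s must be a single character string", what))
  }
  if (grepl("[^ACGTN]", s)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  }
  invisible(s)
}

normalize_dna <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

# circular substring [start, end) with 0-based half-open coordinates;
# end may exceed the sequence length to denote an origin-wrapping span
substr_circular <- function(seq, start, end, n = nchar(seq)) {
  if (end <= n) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, n), substr_circular(seq, 0L, end - n, n))
  }
}

# length of a circular interval [start, end) mod n
circ_len <- function(start, end, n) {
  if (end >= start) end - start else end - start + n
}

# is circular position p inside circular interval [start, len)?
circ_contains <- function(start, len, p, n) {
  ((p - start) %% n) < len
}

pick_other_base <- function(b) {
  cand <- setdiff(DNA_BASES, b)
  cand[sample.int(length(cand), 1L)]
}
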