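# Annotated plastome records and GenBank / FASTA I/O.
#
# Coordinates are 0-based half-open internally; GenBank's 1-based inclusive
# spans are converted at the boundary. A feature crossing the origin of the
# circular molecule is stored once, with `end > length_bp` and
# `wraps_origin = TRUE`; it is materialized as two physical segments only
# when its sequence is extracted.

FEATURE_KINDS <- c("gene", "tRNA", "rRNA", "CDS", "pseudogene")

#' Construct an annotated plastome record
#'
#' A `plastome_record` holds one species' circular chloroplast genome: the
#' uppercase DNA sequence, its length, and a feature table.
#'
#' @param species_id Unique species identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (lowercase and `U` are
#'   normalized).
#' @param features Data frame with columns `name`, `kind` (one of gene,
#'   tRNA, rRNA, CDS, pseudogene), `start`, `end` (0-based half-open;
#'   `end` may exceed the genome length for origin-wrapping features),
#'   `strand` (`"+"`/`"-"`), and optionally `wraps_origin` and a `parts`
#'   list-column of per-exon `start`/`end` data frames.
#' @param is_circular Is the molecule circular? Default `TRUE`.
#' @return A `plastome_record` object.
#' @export
plastome_record <- function(species_id, sequence, features = NULL,
                            is_circular = TRUE) {
  sequence <- normalize_dna(sequence)
  check_dna(sequence)
  n <- nchar(sequence)
  if (n == 0L) abort("sequence must be non-empty")
  features <- normalize_features(features, n)
  structure(
    list(
      species_id = as.character(species_id),
      sequence = sequence,
      length_bp = n,
      is_circular = isTRUE(is_circular),
      features = features
    ),
    class = "plastome_record"
  )
}

normalize_features <- function(features, n) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0L) {
    return(tibble(
      name = character(), kind = character(), start = integer(),
      end = integer(), strand = character(), wraps_origin = logical(),
      parts = list()
    ))
  }
  ft <- as_tibble(features)
  stopifnot(all(c("name", "kind", "start", "end") %in% names(ft)))
  if (!"strand" %in% names(ft)) ft$strand <- "+"
  if (!"wraps_origin" %in% names(ft)) ft$wraps_origin <- ft$end > n
  if (!"parts" %in% names(ft)) {
    ft$parts <- purrr::map2(ft$start, ft$end,
                            ~tibble(start = .x, end = .y))
  }
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  if (any(ft$name == "" | is.na(ft$name))) abort("feature names must be non-empty")
  if (!all(ft$kind %in% FEATURE_KINDS)) {
    abort(sprintf("feature kind must be one of %s",
                  paste(FEATURE_KINDS, collapse = ", ")))
  }
  if (any(ft$start < 0L | ft$start >= n)) {
    abort("feature start must lie in [0, length_bp)")
  }
  if (any(ft$end > n & !ft$wraps_origin)) {
    abort("feature end beyond genome length requires wraps_origin")
  }
  ft
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features\n",
              x$species_id, format(x$length_bp, big.mark = ","),
              if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Extract a (possibly wrapping) span of a plastome
#'
#' @param rec A `plastome_record`.
#' @param start,end 0-based half-open span; `end` may exceed the genome
#'   length, in which case the span wraps the origin.
#' @param strand `"+"` for the genome strand, `"-"` for its reverse
#'   complement.
#' @return A DNA string.
#' @export
extract_span <- function(rec, start, end, strand = "+") {
  if (end <= start) abort("empty span")
  s <- substr_circular(rec$sequence, start, end, rec$length_bp)
  if (identical(strand, "-")) revcomp(s) else s
}

# strand-corrected sequence of one feature row (exon union for multi-part)
feature_sequence <- function(rec, frow) {
  parts <- frow$parts[[1]]
  segs <- vapply(seq_len(nrow(parts)), function(i) {
    substr_circular(rec$sequence, parts$start[i], parts$end[i], rec$length_bp)
  }, character(1))
  s <- paste(segs, collapse = "")
  if (identical(frow$strand, "-")) revcomp(s) else s
}

#' Rotate a circular plastome
#'
#' Shifts the origin of the circular molecule by `offset` bases; feature
#' coordinates are remapped. Useful for testing rotation invariance of
#' downstream inference.
#'
#' @param rec A `plastome_record`.
#' @param offset Number of bases to rotate by (new origin at `offset`).
#' @return A rotated `plastome_record`.
#' @export
rotate_plastome <- function(rec, offset) {
  n <- rec$length_bp
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(rec)
  seq2 <- paste0(substr(rec$sequence, offset + 1L, n),
                 substr(rec$sequence, 1L, offset))
  ft <- rec$features
  if (nrow(ft) > 0L) {
    shift <- function(pos) (pos - offset) %% n
    ft2 <- ft
    for (i in seq_len(nrow(ft))) {
      parts <- ft$parts[[i]]
      len <- ft$end[i] - ft$start[i]
      ns <- shift(ft$start[i])
      ft2$start[i] <- ns
      ft2$end[i] <- ns + len
      ft2$wraps_origin[i] <- ns + len > n
      d <- ns - ft$start[i]
      parts$start <- parts$start + d
      parts$end <- parts$end + d
      # keep part starts within [0, n)
      under <- parts$start < 0L
      parts$start[under] <- parts$start[under] + n
      parts$end[under] <- parts$end[under] + n
      ft2$parts[[i]] <- parts
    }
    ft <- ft2
  }
  plastome_record(rec$species_id, seq2, ft, rec$is_circular)
}

# ---------------------------------------------------------------------------
# GenBank flat-file I/O

#' Read an annotated genome from a GenBank flat file
#'
#' Minimal offline parser for GenBank flat files: LOCUS line, FEATURES table
#' (gene, tRNA, rRNA, CDS; a gene flagged `/pseudo` becomes a pseudogene)
#' and the ORIGIN sequence block. `join(...)` locations are kept as exon
#' parts; a join running past the end of a circular molecule and resuming at
#' base 1 is stored as a single origin-wrapping feature.
#'
#' @param path Path to a GenBank flat file.
#' @param species_id Identifier for the record; defaults to the LOCUS name.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) abort("not a GenBank flat file: no LOCUS line")
  locus_fields <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  locus_name <- locus_fields[2]
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) abort("GenBank record has no ORIGIN sequence block")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- normalize_dna(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i) > 0L) {
    body <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    # feature entries start with a key in column 6; continuation lines are
    # indented by 21 spaces
    starts <- grep("^ {5}\\S", body)
    for (si in seq_along(starts)) {
      from <- starts[si]
      to <- if (si < length(starts)) starts[si + 1L] - 1L else length(body)
      entry <- body[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", entry[1])
      if (!key %in% c("gene", "tRNA", "rRNA", "CDS")) next
      loc <- sub("^ {5}\\S+\\s+", "", entry[1])
      quals <- entry[-1]
      # location may continue onto lines that are not qualifiers
      extra <- quals[!grepl("^\\s*/", quals)]
      if (length(extra)) loc <- paste0(loc, paste(trimws(extra), collapse = ""))
      quals <- trimws(quals[grepl("^\\s*/", quals)])
      parsed <- parse_genbank_location(loc, n)
      nm <- genbank_qualifier(quals, "gene") %||%
        genbank_qualifier(quals, "standard_name") %||%
        genbank_qualifier(quals, "locus_tag") %||%
        sprintf("%s_%d", key, si)
      kind <- if (any(grepl("^/pseudo\\b", quals)) && key == "gene") {
        "pseudogene"
      } else {
        key
      }
      feats[[length(feats) + 1L]] <- tibble(
        name = nm, kind = kind,
        start = parsed$start, end = parsed$end,
        strand = parsed$strand, wraps_origin = parsed$end > n,
        parts = list(parsed$parts)
      )
    }
  }
  features <- if (length(feats)) bind_rows(feats) else NULL
  if (is.null(features)) {
    warn(sprintf("GenBank record %s has no captured features", locus_name))
  }
  plastome_record(species_id %||% locus_name, sequence, features,
                  is_circular = circular || TRUE)
}

genbank_qualifier <- function(quals, what) {
  hit <- grep(sprintf("^/%s=", what), quals, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  gsub('^/[^=]+="?|"$', "", hit[1])
}

# "complement(join(290..300,1..10))" -> strand, ordered 0-based parts;
# parts that re-start at the origin are shifted by +n so the feature is a
# single span with end > n
parse_genbank_location <- function(loc, n) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  loc <- gsub("[<>]", "", loc)
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1]]
  starts <- integer(0); ends <- integer(0)
  for (p in pieces) {
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      ab <- c(as.integer(p), as.integer(p))
    }
    starts <- c(starts, ab[1] - 1L)  # to 0-based half-open
    ends <- c(ends, ab[2])
  }
  shift <- 0L
  for (i in seq_along(starts)) {
    starts[i] <- starts[i] + shift
    ends[i] <- ends[i] + shift
    if (i < length(starts) && starts[i + 1L] + shift < ends[i]) {
      shift <- shift + n  # resumes before previous end: wraps the origin
    }
  }
  list(start = min(starts), end = max(ends), strand = strand,
       parts = tibble(start = starts, end = ends))
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits LOCUS, FEATURES (with `join`/`complement` locations) and ORIGIN
#' blocks. `read_genbank()` round-trips sequence and feature coordinates
#' exactly.
#'
#' @param rec A [plastome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  n <- rec$length_bp
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                   rec$species_id, n,
                   if (rec$is_circular) "circular" else "linear"),
           sprintf("DEFINITION  %s chloroplast genome.", rec$species_id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  ft <- rec$features
  for (i in seq_len(nrow(ft))) {
    parts <- ft$parts[[i]]
    spans <- vapply(seq_len(nrow(parts)), function(j) {
      s <- parts$start[j] %% n
      e <- parts$end[j]
      e <- if (e > n && parts$start[j] >= n) e - n else e
      sprintf("%d..%d", s + 1L, e)
    }, character(1))
    # origin-wrapping single part is materialized as its two segments
    if (nrow(parts) == 1L && parts$end[1] > n) {
      spans <- c(sprintf("%d..%d", parts$start[1] + 1L, n),
                 sprintf("1..%d", parts$end[1] - n))
    }
    loc <- if (length(spans) > 1L) {
      sprintf("join(%s)", paste(spans, collapse = ","))
    } else {
      spans
    }
    if (identical(ft$strand[i], "-")) loc <- sprintf("complement(%s)", loc)
    key <- if (ft$kind[i] == "pseudogene") "gene" else ft$kind[i]
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", ft$name[i]))
    if (ft$kind[i] == "pseudogene") {
      out <- c(out, "                     /pseudo")
    }
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(rec$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a genome from FASTA plus a feature table
#'
#' Alternative input route to [read_genbank()]: a single-record FASTA and a
#' tab-separated feature table with columns `name`, `kind`, `start`, `end`
#' (0-based half-open), `strand`.
#'
#' @param fasta_path Path to a FASTA file with one record.
#' @param features_path Optional path to the feature TSV.
#' @param species_id Identifier; defaults to the FASTA header word.
#' @return A [plastome_record()].
#' @export
read_plastome_fasta <- function(fasta_path, features_path = NULL,
                                species_id = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) < 1L) abort("FASTA file contains no record")
  sequence <- as.character(ss[[1]])
  id <- species_id %||% strsplit(names(ss)[1], "\\s+")[[1]][1]
  features <- NULL
  if (!is.null(features_path)) {
    features <- read.delim(features_path, stringsAsFactors = FALSE)
  }
  plastome_record(id, sequence, features)
}
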