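# Independent oracles used to verify the package's scanners and aligner.
# These deliberately take different algorithmic routes from the
# implementation: the repeat oracle walks every diagonal with a two-pointer
# and checks maximality by definition on raw substrings; the SSR oracle
# verifies regex/stretch candidates definitionally with a leftmost-phase
# back-walk; the alignment oracle is a quadratic Gotoh DP.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# all maximal repeat pairs by exhaustive diagonal scan + definitional checks
oracle_repeats <- function(seq, min_len, max_mm,
                           types = c("forward", "reverse", "palindromic",
                                     "complement")) {
  A <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(A)
  out <- list()
  for (type in types) {
    B <- switch(type,
                forward = A,
                complement = unname(oracle_comp[A]),
                reverse = rev(A),
                palindromic = unname(oracle_comp[rev(A)]))
    for (d in (-(n - 1)):(n - 1)) {
      lo <- max(0L, -d)
      hi <- min(n - 1L, n - 1L - d)
      if (hi - lo + 1L < min_len) next
      if (type %in% c("forward", "complement") && d == 0L) next
      i0 <- lo:hi  # 0-based A positions on this diagonal
      mm_vec <- A[i0 + 1L] != B[i0 + d + 1L] | A[i0 + 1L] == "N" |
        B[i0 + d + 1L] == "N"
      cum <- cumsum(mm_vec)
      mism_at <- function(s, e) {
        # mismatches in 0-based window [s, e]
        cum[e - lo + 1L] - if (s > lo) cum[s - lo] else 0L
      }
      # two-pointer: for each start the maximal end within budget
      e <- lo - 1L
      for (s in lo:hi) {
        if (e < s - 1L) e <- s - 1L
        while (e + 1L <= hi && mism_at(s, e + 1L) <= max_mm) e <- e + 1L
        len <- e - s + 1L
        if (len < min_len) next
        # left-maximality by definition
        if (s > lo && mism_at(s - 1L, e) <= max_mm) next
        out[[length(out) + 1L]] <- c(type = type, i = s, d = d, len = len,
                                     mm = mism_at(s, e))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(rtype = character(), pos1 = integer(),
                          pos2 = integer(), length = integer(),
                          mismatches = integer()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df$i <- as.integer(df$i); df$d <- as.integer(df$d)
  df$len <- as.integer(df$len); df$mm <- as.integer(df$mm)
  p1 <- df$i
  p2 <- ifelse(df$type %in% c("forward", "complement"),
               df$i + df$d, n - (df$i + df$d) - df$len)
  lo_p <- pmin(p1, p2); hi_p <- pmax(p1, p2)
  keep <- !(df$type %in% c("forward", "complement") & lo_p == hi_p)
  res <- tibble::tibble(rtype = df$type, pos1 = as.integer(lo_p),
                        pos2 = as.integer(hi_p), length = df$len,
                        mismatches = df$mm)[keep, ]
  dplyr::arrange(dplyr::distinct(res), rtype, pos1, pos2)
}

# independent SSR enumeration: stretch + regex candidates, then a
# definitional leftmost-phase/primitivity/unit-count verification
oracle_ssrs <- function(seq, thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                            `4` = 5L, `5` = 5L, `6` = 5L)) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  periodic_at <- function(q, m) {
    q >= 0L && q + m < n && ch[q + 1L] == ch[q + m + 1L] && ch[q + 1L] != "N"
  }
  is_prim <- function(motif) {
    m <- nchar(motif)
    if (grepl("N", motif, fixed = TRUE)) return(FALSE)
    for (dd in seq_len(max(m - 1L, 0L))) {
      if (m %% dd == 0L && strrep(substr(motif, 1L, dd), m %/% dd) == motif)
        return(FALSE)
    }
    TRUE
  }
  units_at <- function(p, m) {
    motif <- substr(seq, p + 1L, p + m)
    u <- 1L
    while (p + (u + 1L) * m <= n &&
           substr(seq, p + u * m + 1L, p + (u + 1L) * m) == motif) {
      u <- u + 1L
    }
    u
  }
  hits <- list()
  seen <- character(0)
  consider <- function(p0, m) {
    thr <- thresholds[[as.character(m)]]
    # back-walk to the start of the maximal period-m stretch, then forward
    # to its first primitive phase
    q <- p0
    while (periodic_at(q - 1L, m)) q <- q - 1L
    k <- q
    while (periodic_at(k, m)) k <- k + 1L
    span_end <- min(k + m, n)
    p <- q
    found <- FALSE
    while (span_end - p >= m * thr) {
      if (is_prim(substr(seq, p + 1L, p + m))) { found <- TRUE; break }
      p <- p + 1L
    }
    if (!found) return(invisible())
    u <- units_at(p, m)
    if (u < thr) return(invisible())
    key <- paste(m, p, sep = ":")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    hits[[length(hits) + 1L]] <<- tibble::tibble(
      motif = substr(seq, p + 1L, p + m), start = p,
      end = p + u * m, n_repeats = u
    )
  }
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    # candidates from regex scan
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", m, thr - 1L)
    mt <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (mt[1] != -1L) {
      for (p1 in as.integer(mt)) consider(p1 - 1L, m)
    }
    # candidates from periodicity stretches (catches runs the regex
    # consumption might shadow)
    if (n > m) {
      eq <- ch[seq_len(n - m)] == ch[(m + 1L):n] & ch[seq_len(n - m)] != "N"
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values & r$lengths >= m * (thr - 1L))) {
        consider(starts[j] - 1L, m)
      }
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(motif = character(), start = integer(),
                          end = integer(), n_repeats = integer()))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(hits)), start, motif)
}

# quadratic Gotoh DP: optimal global affine-gap alignment score
# (gap of length k costs open + k * extend)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, extend = 0.5) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  sub <- function(p, q) {
    if (x[p] == "N" || y[q] == "N") 0
    else if (x[p] == y[q]) match else mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (x aligned to -)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x
  M[1, 1] <- 0
  for (p in seq_len(n)) X[p + 1, 1] <- -open - extend * p
  for (q in seq_len(m)) Y[1, q + 1] <- -open - extend * q
  for (p in seq_len(n)) {
    for (q in seq_len(m)) {
      s <- sub(p, q)
      M[p + 1, q + 1] <- max(M[p, q], X[p, q], Y[p, q]) + s
      X[p + 1, q + 1] <- max(M[p, q + 1] - open - extend,
                             X[p, q + 1] - extend)
      Y[p + 1, q + 1] <- max(M[p + 1, q] - open - extend,
                             Y[p + 1, q] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an aligned pair under the same scheme
score_alignment <- function(aln, match = 1, mismatch = -1, open = 2,
                            extend = 0.5) {
  v1 <- strsplit(aln[1], "", fixed = TRUE)[[1]]
  v2 <- strsplit(aln[2], "", fixed = TRUE)[[1]]
  s <- 0
  in_gap <- FALSE
  for (i in seq_along(v1)) {
    if (v1[i] == "-" || v2[i] == "-") {
      s <- s - extend - if (!in_gap) open else 0
      in_gap <- TRUE
    } else {
      in_gap <- FALSE
      s <- s + if (v1[i] == "N" || v2[i] == "N") 0
      else if (v1[i] == v2[i]) match else mismatch
    }
  }
  s
}

# independent recount of the divergence statistic: regex-based gap-run
# count, elementwise substitution count
oracle_divergence <- function(aln) {
  v1 <- strsplit(aln[1], "", fixed = TRUE)[[1]]
  v2 <- strsplit(aln[2], "", fixed = TRUE)[[1]]
  ns <- sum(mapply(function(c1, c2) {
    c1 != "-" && c2 != "-" && c1 != c2 && c1 != "N" && c2 != "N"
  }, v1, v2))
  gap_runs <- function(row) {
    g <- gregexpr("-+", row)[[1]]
    if (g[1] == -1L) 0L else length(g)
  }
  id <- gap_runs(aln[1]) + gap_runs(aln[2])
  L <- length(v1)
  list(NS = ns, ID = id, L = L, pct = 100 * (ns + id) / L)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
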