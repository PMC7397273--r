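# Pairwise alignment and the percent-variation statistic

test_that("identical sequences align gap-free with zero divergence", {
  s <- "ACGTACGTACGT"
  aln <- align_pair(s, s)
  expect_equal(aln, c(s, s))
  d <- count_divergence(aln)
  expect_equal(c(d$NS, d$ID, d$pct), c(0, 0, 0))
})

test_that("the short deletion example aligns as one two-column gap run", {
  aln <- align_pair("ACGT", "AT")
  expect_equal(nchar(aln[1]), 4L)
  expect_equal(stringr::str_count(aln[2], "-"), 2L)
  # one contiguous gap run
  expect_equal(length(gregexpr("-+", aln[2])[[1]]), 1L)
  d <- count_divergence(aln)
  expect_equal(d$ID, 1L)
})

test_that("alignment scores are optimal against the Gotoh oracle", {
  set.seed(61)
  for (i in 1:15) {
    a <- random_dna_str(sample(30:180, 1))
    b <- random_dna_str(sample(30:180, 1))
    aln <- align_pair(a, b)
    # every base appears once, no gap/gap columns
    expect_equal(gsub("-", "", aln[1]), a)
    expect_equal(gsub("-", "", aln[2]), b)
    both_gap <- mapply(function(x, y) x == "-" && y == "-",
                       strsplit(aln[1], "")[[1]], strsplit(aln[2], "")[[1]])
    expect_false(any(both_gap))
    expect_equal(score_alignment(aln), oracle_align_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("divergence counts match hand-counted worked alignments", {
  d1 <- count_divergence(c("ACGTACGT", "ACCTA-GT"))
  expect_equal(c(d1$NS, d1$ID, d1$L), c(1L, 1L, 8L))
  expect_equal(d1$pct, 25.0)
  d2 <- count_divergence(c("AAAA----TT", "AAAACCCCTT"))
  expect_equal(c(d2$NS, d2$ID, d2$L), c(0L, 1L, 10L))
  expect_equal(d2$pct, 10.0)
  expect_error(count_divergence(c("A-G", "A-G")), "gap/gap")
})

test_that("count_divergence equals an independent column recount", {
  set.seed(62)
  for (i in 1:20) {
    a <- random_dna_str(sample(40:150, 1))
    b <- random_dna_str(sample(40:150, 1))
    aln <- align_pair(a, b)
    d <- count_divergence(aln)
    o <- oracle_divergence(aln)
    expect_equal(d$NS, o$NS)
    expect_equal(d$ID, o$ID)
    expect_equal(d$L, o$L)
    expect_equal(d$pct, o$pct)
  }
})

test_that("adjacent gap runs in opposite rows count as separate events", {
  d <- count_divergence(c("AC--GTAC", "ACGT--AC"))
  expect_equal(d$ID, 2L)
})

test_that("N columns are not counted as substitutions", {
  d <- count_divergence(c("ANGT", "ACGT"))
  expect_equal(d$NS, 0L)
  expect_equal(d$L, 4L)
})

test_that("divergence is symmetric in the species pair", {
  set.seed(63)
  for (i in 1:8) {
    a <- random_dna_str(120)
    # derived sequence with substitutions and a deletion
    ch <- strsplit(a, "")[[1]]
    ch[sample(120, 6)] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    b <- paste(ch[-(50:54)], collapse = "")
    d1 <- count_divergence(align_pair(a, b))
    d2 <- count_divergence(align_pair(b, a))
    expect_equal(d1$NS, d2$NS)
    expect_equal(d1$ID, d2$ID)
    expect_equal(d1$L, d2$L)
  }
})

test_that("a k-bp gap counts as exactly one event for k = 1..10", {
  set.seed(64)
  base <- random_dna_str(200)
  for (k in 1:10) {
    del <- paste0(substr(base, 1, 95), substr(base, 96 + k, 200))
    d <- count_divergence(align_pair(base, del))
    expect_equal(d$ID, 1L, info = paste("k =", k))
    expect_equal(d$NS, 0L, info = paste("k =", k))
    expect_equal(d$L, 200L, info = paste("k =", k))
  }
})

test_that("locus summaries demand a complete pair set and average pct", {
  divs <- tibble::tibble(
    locus_name = "x",
    species_a = c("a", "a", "b"), species_b = c("b", "c", "c"),
    NS = 1L, ID = 0L, L = 100L, pct = c(10, 20, 30)
  )
  s <- summarize_locus(divs)
  expect_equal(s$mean_pct, 20)
  expect_equal(s$n_pairs, 3L)
  expect_error(summarize_locus(divs[-2, ], species = c("a", "b", "c")),
               "a vs c")
})

test_that("ranking sorts by pct with the length/name tie-break and screen", {
  summaries <- tibble::tibble(
    locus_name = c("w", "x", "y", "z"),
    ltype = "IGS", coding = FALSE,
    mean_pct = c(5, 9, 9, 2),
    avg_length_bp = c(1200, 200, 300, 500),
    n_pairs = 21L
  )
  r <- rank_loci(summaries, top_n = 3)
  expect_equal(r$locus_name, c("y", "x", "w", "z"))
  expect_equal(r$rank, 1:4)
  expect_equal(r$top, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$amplicon_ok, c(TRUE, TRUE, FALSE, TRUE))
  t <- tidy(r)
  expect_s3_class(t, "tbl_df")
  g <- glance(r)
  expect_equal(g$n_loci, 4L)
})

test_that("externally supplied alignments are used verbatim", {
  loci <- tibble::tibble(
    locus_name = "L1", ltype = "IGS", coding = FALSE,
    species_id = c("a", "b"), seq = c("ACGTACGT", "ACCTAGT")
  )
  ext <- list("L1|a|b" = c("ACGTACGT", "ACCTA-GT"))
  divs <- pairwise_divergence(loci, alignments = ext)
  expect_equal(divs$pct, 25.0)
})
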