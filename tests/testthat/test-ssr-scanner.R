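# Perfect-SSR scanning, motif canonicalization, homologous grouping

test_that("homopolymer threshold edge: ten units hit, nine do not", {
  hit <- scan_ssrs(paste0("G", strrep("A", 10), "G"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "A")
  expect_equal(hit$n_repeats, 10L)
  expect_equal(hit$canonical_class, "A/T")
  expect_equal(nrow(scan_ssrs(paste0("G", strrep("A", 9), "G"))), 0L)
})

test_that("a dinucleotide run is one primitive hit, not two homopolymers", {
  s <- paste0("GGC", strrep("AT", 6), "CGG")
  hit <- scan_ssrs(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$n_repeats, 6L)
  expect_equal(hit$end - hit$start, 12L)
})

test_that("scan equals the independent oracle on random sequences", {
  set.seed(41)
  for (i in 1:15) {
    s <- paste0(
      random_dna_str(400), strrep("A", sample(8:14, 1)),
      random_dna_str(150), strrep("AT", sample(4:8, 1)),
      random_dna_str(150), strrep("AAG", 5),
      random_dna_str(150), strrep("AAAT", 5),
      random_dna_str(150), strrep("ACGAGG", 5),
      random_dna_str(300), strrep("A", 20), strrep("AT", 6),
      random_dna_str(200)
    )
    expect_equal(canon_ssrs(scan_ssrs(s)), canon_ssrs(oracle_ssrs(s)),
                 info = paste("fixture", i))
  }
})

test_that("runs containing N are split at the N", {
  s <- paste0("GC", strrep("A", 6), "N", strrep("A", 11), "GC")
  hit <- scan_ssrs(s)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 9L)
  expect_equal(hit$n_repeats, 11L)
})

test_that("canonical classes match the published row-label convention", {
  expect_equal(canonical_class("TTC"), "AAG/CTT")
  expect_equal(canonical_class("T"), "A/T")
  expect_equal(canonical_class("AT"), "AT/AT")
  expect_error(canonical_class("ATAT"), "primitive")
})

test_that("canonical_class is invariant under rotation and strand flip", {
  rots <- function(x) {
    k <- nchar(x)
    vapply(seq_len(k) - 1L, function(i) {
      paste0(substr(x, i + 1L, k), substr(x, 1L, i))
    }, character(1))
  }
  is_prim <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(max(m - 1L, 0L))) {
      if (m %% d == 0L && strrep(substr(motif, 1, d), m %/% d) == motif)
        return(FALSE)
    }
    TRUE
  }
  bases <- c("A", "C", "G", "T")
  for (m in 1:6) {
    motifs <- apply(expand.grid(rep(list(bases), m)), 1, paste,
                    collapse = "")
    motifs <- motifs[vapply(motifs, is_prim, logical(1))]
    # exhaustive within each class orbit: every rotation and every
    # reverse-complement rotation maps to one label
    for (motif in motifs) {
      variants <- c(rots(motif), rots(revcomp(motif)))
      labels <- vapply(variants, canonical_class, character(1))
      expect_equal(length(unique(labels)), 1L,
                   info = paste("motif", motif))
    }
  }
})

test_that("strand flip preserves the class/repeat-count multiset", {
  set.seed(42)
  s <- paste0(random_dna_str(300), strrep("A", 12), random_dna_str(100),
              strrep("GA", 7), random_dna_str(100), strrep("CTT", 6),
              random_dna_str(300))
  fwd <- scan_ssrs(s)
  rev <- scan_ssrs(revcomp(s))
  key <- function(df) sort(paste(df$canonical_class, df$n_repeats))
  expect_equal(key(fwd), key(rev))
})

test_that("region labels partition the SSR total", {
  sim <- cached_sim("base", test_sim_config())
  rec <- sim$records[[1]]
  rm <- infer_region_map(rec)
  hits <- scan_ssrs(rec, region_map = rm)
  expect_false(any(is.na(hits$region)))
  expect_equal(sum(table(hits$region)), nrow(hits))
})

test_that("identical genomes group every SSR as shared, none variable", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  rec <- sim$records[[1]]
  clones <- lapply(1:3, function(i) {
    plastome_record(paste0("c", i), rec$sequence, rec$features)
  })
  groups <- group_homologous_ssrs(clones)
  expect_true(all(groups$shared_by_all))
  # identical genomes: identical spans, so no length variation anywhere
  expect_false(any(groups$length_variable))
})

test_that("planted length-variable homopolymers group across species", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  groups <- group_homologous_ssrs(sim$records)
  planted <- sim$manifest$planted_ssrs
  # every planted group is recovered as shared by all seven species
  for (g in unique(planted$group)) {
    p <- planted[planted$group == g, ]
    gid <- groups$group_id[groups$species_id == p$species_id[1] &
                             groups$start == p$start[1]]
    expect_length(gid, 1L)
    members <- groups[groups$group_id == gid, ]
    expect_true(all(members$shared_by_all))
    expect_equal(unique(members$length_variable),
                 length(unique(p$n_repeats)) > 1L)
  }
})

test_that("same-class SSRs in unrelated flank contexts stay separate", {
  set.seed(44)
  core <- strrep("A", 12)
  a <- plastome_record("a", paste0(random_dna_str(400), core,
                                   random_dna_str(400)))
  b <- plastome_record("b", paste0(random_dna_str(400), core,
                                   random_dna_str(400)))
  groups <- group_homologous_ssrs(list(a, b))
  expect_equal(length(unique(groups$group_id)), 2L)
  expect_false(any(groups$shared_by_all))
})
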