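# Locus catalogue derivation and cross-species intersection

test_that("a hand-built circular genome yields genes, IGS and the wrap gap", {
  rec <- toy_record()  # genes G1 [10,40) and G2 [60,90) on a 100 bp circle
  loci <- derive_loci(rec)
  expect_setequal(loci$locus_name, c("G1", "G2", "G1-G2", "G2-G1"))
  igs1 <- loci[loci$locus_name == "G1-G2", ]
  expect_equal(c(igs1$start, igs1$end), c(40L, 60L))
  wrap <- loci[loci$locus_name == "G2-G1", ]
  expect_equal(c(wrap$start, wrap$end), c(90L, 110L))
  expect_equal(nchar(wrap$seq), 20L)
  # strand-corrected gene sequence
  g2 <- loci[loci$locus_name == "G2", ]
  expect_equal(g2$seq, revcomp(substr(rec$sequence, 61, 90)))
})

test_that("multi-exon genes produce gene plus intron loci", {
  set.seed(51)
  seq <- random_dna_str(120)
  feats <- tibble::tibble(
    name = "gx", kind = "gene", start = 10L, end = 40L, strand = "+",
    wraps_origin = FALSE,
    parts = list(tibble::tibble(start = c(10L, 30L), end = c(20L, 40L)))
  )
  feats <- dplyr::bind_rows(feats, tibble::tibble(
    name = "gy", kind = "gene", start = 60L, end = 80L, strand = "+",
    wraps_origin = FALSE,
    parts = list(tibble::tibble(start = 60L, end = 80L))
  ))
  rec <- plastome_record("t2", seq, feats)
  loci <- derive_loci(rec)
  gx <- loci[loci$locus_name == "gx", ]
  expect_equal(nchar(gx$seq), 20L)  # exon union only
  intron <- loci[loci$locus_name == "gx.intron1", ]
  expect_equal(c(intron$start, intron$end), c(20L, 30L))
  expect_false(intron$coding)
})

test_that("abutting genes yield no IGS between them", {
  set.seed(52)
  feats <- tibble::tibble(
    name = c("a", "b"), kind = "gene", start = c(10L, 40L),
    end = c(40L, 70L), strand = "+", wraps_origin = FALSE
  )
  rec <- plastome_record("t3", random_dna_str(100), feats)
  loci <- derive_loci(rec)
  expect_false("a-b" %in% loci$locus_name)
  expect_true("b-a" %in% loci$locus_name)  # the wrap-around gap remains
})

test_that("locus spans tile the genome", {
  sim <- cached_sim("base", test_sim_config())
  rec <- sim$records[[1]]
  loci <- derive_loci(rec)
  # feature full spans (introns included) plus IGS gaps cover the circle
  # exactly once
  n <- rec$length_bp
  cover <- integer(n)
  add_span <- function(s, e) {
    idx <- (seq.int(s, e - 1L) %% n) + 1L
    cover[idx] <<- cover[idx] + 1L
  }
  for (i in seq_len(nrow(rec$features))) {
    add_span(rec$features$start[i], rec$features$end[i])
  }
  igs <- loci[loci$ltype == "IGS", ]
  for (i in seq_len(nrow(igs))) add_span(igs$start[i], igs$end[i])
  expect_true(all(cover == 1L))
})

test_that("identical genomes share every locus; a missing gene drops three", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  rec <- sim$records[[1]]
  clones <- lapply(1:3, function(i) {
    plastome_record(paste0("c", i), rec$sequence, rec$features)
  })
  cats <- lapply(clones, derive_loci)
  shared <- intersect_across_species(cats)
  expect_equal(length(unique(shared$match_key)),
               length(unique(cats[[1]]$match_key)))
  # drop one single-copy protein gene from the third clone (bare symbol,
  # so locus names contain it verbatim)
  ft <- rec$features
  syms_all <- sub("-[ACGTU]{3}$", "", ft$name)
  singles <- ft$name[ft$kind == "gene" & !grepl("-", ft$name) &
                       !(syms_all %in% syms_all[duplicated(syms_all)])]
  drop <- singles[5]
  c3 <- plastome_record("c3", rec$sequence, ft[ft$name != drop, ])
  cats2 <- list(cats[[1]], cats[[2]], derive_loci(c3))
  shared2 <- intersect_across_species(cats2)
  lost <- setdiff(unique(shared$locus_name), unique(shared2$locus_name))
  # the gene and both flanking spacers disappear; one new fused spacer
  expect_true(drop %in% lost)
  expect_equal(sum(grepl(drop, lost, fixed = TRUE)), 3L)
  unmatched <- attr(shared2, "unmatched")
  expect_true(any(grepl(drop, unmatched$locus_name, fixed = TRUE)))
})

test_that("an inverted SSC still matches IGS loci via the reversed name", {
  sim_inv <- cached_sim("inverted",
                        test_sim_config_frozen(invert_ssc_in = "sp7"))
  shared <- intersect_across_species(lapply(sim_inv$records, derive_loci))
  # SSC spacers are present for all species despite the inversion in sp7
  ssc_igs <- shared[shared$ltype == "IGS" & shared$region == "SSC", ]
  expect_gt(nrow(ssc_igs), 0)
  counts <- table(ssc_igs$match_key)
  expect_true(all(counts == length(sim_inv$records)))
})

test_that("coding/non-coding split partitions the shared set", {
  sim <- cached_sim("base", test_sim_config())
  shared <- intersect_across_species(lapply(sim$records, derive_loci))
  one <- shared[!duplicated(shared$match_key), ]
  expect_equal(sum(one$coding) + sum(!one$coding), nrow(one))
  expect_true(all(one$coding[one$ltype == "gene"]))
  expect_false(any(one$coding[one$ltype %in% c("IGS", "intron",
                                               "pseudogene")]))
  # the planted pseudogene is in the catalogue and non-coding
  psi <- one[one$ltype == "pseudogene", ]
  expect_gte(nrow(psi), 1L)
  expect_true(all(grepl("psi$", psi$locus_name)))
})

test_that("shared-locus count is invariant under genome rotation", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  recs <- sim$records
  rot <- rotate_plastome(recs[[2]], 7000L)
  recs2 <- recs
  recs2[[2]] <- plastome_record(recs[[2]]$species_id, rot$sequence,
                                rot$features)
  n1 <- length(unique(intersect_across_species(
    lapply(recs, derive_loci))$match_key))
  n2 <- length(unique(intersect_across_species(
    lapply(recs2, derive_loci))$match_key))
  expect_equal(n2, n1)
})
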