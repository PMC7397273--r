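# Generator ground truth: determinism, replay, planted elements, rates

test_that("identical seed and config give byte-identical datasets", {
  s1 <- simulate_plastomes(test_sim_config(seed = 77))
  s2 <- simulate_plastomes(test_sim_config(seed = 77))
  for (sp in names(s1$records)) {
    expect_identical(s1$records[[sp]]$sequence, s2$records[[sp]]$sequence)
  }
  expect_identical(s1$manifest$blocks$seq, s2$manifest$blocks$seq)
  s3 <- simulate_plastomes(test_sim_config(seed = 78))
  expect_false(identical(s1$records[[1]]$sequence,
                         s3$records[[1]]$sequence))
})

test_that("replaying the event log reproduces every emitted genome", {
  sim <- cached_sim("base", test_sim_config())
  expect_true(all(replay_manifest(sim)))
  sim_inv <- cached_sim("inverted",
                        test_sim_config_frozen(invert_ssc_in = "sp7"))
  expect_true(all(replay_manifest(sim_inv)))
})

test_that("zero rates give identical genomes and zero divergence", {
  cfg <- test_sim_config_frozen(planted_ssrs = list(),
                                planted_repeats = list())
  sim <- simulate_plastomes(cfg)
  seqs <- vapply(sim$records, function(r) r$sequence, character(1))
  expect_equal(length(unique(seqs)), 1L)
  shared <- intersect_across_species(lapply(sim$records, derive_loci))
  divs <- pairwise_divergence(shared[shared$locus_name %in%
                                       unique(shared$locus_name)[1:5], ])
  expect_true(all(divs$pct == 0))
})

test_that("insertion/deletion balance accounts for genome length changes", {
  sim <- cached_sim("base", test_sim_config())
  man <- sim$manifest
  anc_len <- sum(nchar(man$blocks$seq)) +
    sum(nchar(man$blocks$seq[man$blocks$region == "IRa"]))
  for (s in names(sim$records)[c(1, 4)]) {
    delta <- 0L
    for (bi in seq_len(nrow(man$blocks))) {
      w <- if (man$blocks$region[bi] == "IRa") 2L else 1L
      for (ev in man$events[[s]][[bi]]) {
        if (ev$type == "ins") delta <- delta + w * nchar(ev$payload)
        if (ev$type == "del") delta <- delta - w * as.integer(ev$payload)
      }
    }
    expect_equal(sim$records[[s]]$length_bp, anc_len + delta)
  }
})

test_that("planted SSRs are recovered perfectly on mutation-free genomes", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  planted <- sim$manifest$planted_ssrs
  for (s in names(sim$records)) {
    hits <- scan_ssrs(sim$records[[s]])
    p <- planted[planted$species_id == s, ]
    # 100% recall at exact coordinates
    found <- vapply(seq_len(nrow(p)), function(i) {
      any(hits$start == p$start[i] & hits$end == p$end[i] &
            hits$motif == p$motif[i] & hits$n_repeats == p$n_repeats[i])
    }, logical(1))
    expect_true(all(found))
    # false-positive rate zero: nothing beyond the manifest
    expect_equal(nrow(hits), nrow(p))
  }
})

test_that("planted repeats are recovered on mutation-free genomes", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  planted <- sim$manifest$planted_repeats
  for (s in names(sim$records)[c(1, 5)]) {
    rec <- sim$records[[s]]
    rm <- infer_region_map(rec)
    hits <- find_repeats(rec$sequence, min_len = 30, max_mm = 3,
                         region_map = rm)
    p <- planted[planted$species_id == s & planted$mismatches == 0, ]
    for (k in seq_len(nrow(p))) {
      cover <- hits[hits$rtype == p$rtype[k] &
                      hits$pos1 <= p$pos1[k] &
                      hits$pos1 + hits$length >= p$pos1[k] + p$length[k] &
                      hits$pos2 <= p$pos2[k] &
                      hits$pos2 + hits$length >= p$pos2[k] + p$length[k], ]
      expect_gte(nrow(cover), 1L)
    }
  }
})

test_that("higher planted rates produce higher divergence", {
  # two spacer-rate classes, clearly separated
  cfg <- test_sim_config(seed = 99, igs_rates = c(0.01, 0.10),
                         planted_ssrs = list(), planted_repeats = list())
  sim <- simulate_plastomes(cfg)
  shared <- intersect_across_species(lapply(sim$records, derive_loci))
  rates <- sim$manifest$locus_rates
  pure_igs <- rates[rates$ltype == "IGS" & rates$pure, ]
  lo <- pure_igs$locus_name[abs(pure_igs$rate - 0.01) < 1e-9]
  hi <- pure_igs$locus_name[abs(pure_igs$rate - 0.10) < 1e-9]
  sub <- shared[shared$locus_name %in% c(lo, hi), ]
  divs <- pairwise_divergence(sub)
  summ <- summarize_loci(divs, sub)
  mean_lo <- mean(summ$mean_pct[summ$locus_name %in% lo])
  mean_hi <- mean(summ$mean_pct[summ$locus_name %in% hi])
  expect_gt(mean_hi, mean_lo)
  # analytic anchor: pairwise tip-tip rate is bounded by twice the
  # root-to-tip rate; the empirical mean must sit below the upper
  # first-order expectation and well above the low-rate one
  expect_lt(mean_hi, expected_pct(2 * 0.10, cfg$indel_rate * 2))
})

test_that("expected_pct gives the first-order anchor", {
  expect_equal(expected_pct(0), 0)
  expect_equal(expected_pct(0.05, 0, 3, 1000), 5)
  # indels only: events enter the numerator once each
  e <- expected_pct(0, 0.002, 3, 1000)
  expect_equal(e, 100 * 2 / (1000 + 3))
})

test_that("a written dataset loads back through the GenBank reader", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  files <- list.files(dir, pattern = "\\.gb$", full.names = TRUE)
  expect_length(files, 7L)
  back <- read_genbank(files[1])
  sp <- sub("\\.gb$", "", basename(files[1]))
  expect_identical(back$sequence, sim$records[[sp]]$sequence)
  expect_true(file.exists(file.path(dir, "truth_manifest.json")))
})
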