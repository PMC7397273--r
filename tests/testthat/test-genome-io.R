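# GenBank / FASTA I/O and the plastome record container

test_that("a toy GenBank file parses with features, normalization and wrap", {
  gb <- c(
    "LOCUS       toy300 300 bp    DNA     circular PLN",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     gene            11..70",
    '                     /gene="geneA"',
    "     gene            complement(101..160)",
    '                     /gene="geneB"',
    "     gene            join(290..300,1..10)",
    '                     /gene="wrapper"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtuacgta", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    paste0("      121 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    paste0("      181 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    paste0("      241 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    "//"
  )
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_genbank(path)
  expect_s3_class(rec, "plastome_record")
  expect_equal(rec$length_bp, 300L)
  expect_equal(nrow(rec$features), 3L)
  # lowercase u mapped to uppercase T
  expect_false(grepl("[a-z]|U", rec$sequence))
  expect_equal(substr(rec$sequence, 5, 5), "T")
  # 1-based inclusive spans converted to 0-based half-open
  a <- rec$features[rec$features$name == "geneA", ]
  expect_equal(c(a$start, a$end), c(10L, 70L))
  b <- rec$features[rec$features$name == "geneB", ]
  expect_equal(b$strand, "-")
  # origin wrap: join(290..300,1..10) -> one feature of 21 bp
  w <- rec$features[rec$features$name == "wrapper", ]
  expect_true(w$wraps_origin)
  expect_equal(w$end - w$start, 21L)
  expect_equal(w$start, 289L)
})

test_that("GenBank write/read round-trips sequence and features exactly", {
  sim <- cached_sim("frozen", test_sim_config_frozen())
  rec <- sim$records[[1]]
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path, species_id = rec$species_id)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$length_bp, rec$length_bp)
  expect_equal(nrow(back$features), nrow(rec$features))
  o1 <- order(rec$features$start, rec$features$name)
  o2 <- order(back$features$start, back$features$name)
  for (col in c("name", "kind", "start", "end", "strand")) {
    expect_identical(back$features[[col]][o2], rec$features[[col]][o1])
  }
  # exon parts survive too
  multi <- which(vapply(rec$features$parts, nrow, integer(1)) > 1L)
  for (i in multi) {
    j <- which(back$features$name == rec$features$name[i] &
                 back$features$start == rec$features$start[i])
    expect_equal(as.data.frame(back$features$parts[[j]]),
                 as.data.frame(rec$features$parts[[i]]))
  }
})

test_that("records with no sequence error and zero features warn", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
  writeLines(c("LOCUS       x 10 bp", "ORIGIN",
               "        1 acgtacgtac", "//"), path)
  expect_warning(rec <- read_genbank(path), "no captured features")
  expect_equal(rec$length_bp, 10L)
})

test_that("FASTA plus feature TSV loads a record", {
  rec <- toy_record()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">toy", rec$sequence), fa)
  utils::write.table(
    rec$features[, c("name", "kind", "start", "end", "strand")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  back <- read_plastome_fasta(fa, tsv)
  expect_identical(back$sequence, rec$sequence)
  expect_equal(back$features$name, c("G1", "G2"))
  expect_equal(back$features$start, c(10L, 60L))
})

test_that("extract_span handles wrapping spans and minus strand", {
  rec <- toy_record()
  expect_equal(extract_span(rec, 0, 5), substr(rec$sequence, 1, 5))
  wrapped <- extract_span(rec, 95, 105)
  expect_equal(wrapped, paste0(substr(rec$sequence, 96, 100),
                               substr(rec$sequence, 1, 5)))
  expect_equal(extract_span(rec, 0, 5, strand = "-"),
               revcomp(substr(rec$sequence, 1, 5)))
  expect_error(extract_span(rec, 5, 5), "empty")
})

test_that("rotation remaps features consistently", {
  rec <- toy_record()
  rot <- rotate_plastome(rec, 30)
  expect_equal(rot$length_bp, rec$length_bp)
  g1 <- rot$features[rot$features$name == "G1", ]
  # G1 sequence is preserved under rotation
  expect_equal(extract_span(rot, g1$start, g1$end, g1$strand),
               extract_span(rec, 10, 40, "+"))
})
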