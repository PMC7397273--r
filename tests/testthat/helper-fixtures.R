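# Shared fixtures: small simulated datasets and canonical sorting for
# set comparisons.

canon_hits <- function(df) {
  df <- as.data.frame(df[, c("rtype", "pos1", "pos2", "length",
                             "mismatches")])
  df[order(df$rtype, df$pos1, df$pos2, df$length, df$mismatches), ,
     drop = FALSE] |> (\(x) {rownames(x) <- NULL; x})()
}

canon_ssrs <- function(df) {
  df <- as.data.frame(df[, c("motif", "start", "end", "n_repeats")])
  df[order(df$start, df$motif), , drop = FALSE] |>
    (\(x) {rownames(x) <- NULL; x})()
}

# small, fast simulation config used across tests
test_sim_config <- function(seed = 11, ...) {
  sim_config(seed = seed, genome_kb = 40, ir_len_bp = 5000,
             ssc_len_bp = 6000, n_genes = 30,
             gene_len_range = c(200L, 700L), ...)
}

# mutation-free variant (identical genomes apart from planted length
# variation)
test_sim_config_frozen <- function(seed = 11, ...) {
  test_sim_config(seed = seed, gene_rate_range = c(0, 0),
                  igs_rate_range = c(0, 0), indel_rate = 0, ...)
}

cached_sim <- local({
  cache <- list()
  function(key, cfg_fun) {
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_plastomes(cfg_fun)
    }
    cache[[key]]
  }
})

# toy annotated genome built by hand: two genes on a 100 bp circle
toy_record <- function() {
  set.seed(5)
  seq <- random_dna_str(100)
  feats <- tibble::tibble(
    name = c("G1", "G2"), kind = c("gene", "gene"),
    start = c(10L, 60L), end = c(40L, 90L), strand = c("+", "-"),
    wraps_origin = c(FALSE, FALSE)
  )
  plastome_record("toy", seq, feats)
}
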