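# Seeded simulator of annotated plastome datasets with full ground truth.
#
# The generator emulates the inputs of a comparative plastome screen:
# ~100-150 kb circular genomes with the quadripartite LSC/IRa/SSC/IRb
# structure (IRb is the exact reverse complement of IRa, evolving in
# concert), ~80-110 named genes (some with introns, one pseudogene),
# per-locus substitution rates (K2P-like, transition:transversion 2:1) and
# geometric-length indels along a 7-taxon tree, plus planted SSRs and
# planted long repeats of the four orientation types at annotated neutral
# positions.
#
# Testability choices (deliberate departures from full realism):
# * planted elements sit in dedicated immutable spacer gaps, with 100 bp
#   immutable flanks, so the planted truth stays exact;
# * four 1-bp "boundary guard" bases at the LSC and SSC edges are immutable
#   and chosen so the constructed IR boundaries can never extend by chance;
# * the ancestral background is scrubbed of incidental near-threshold SSRs
#   so the planted manifest is exhaustive on mutation-free genomes.

GENE_POOL_LSC <- c(
  "psbA", "trnK-UUU", "matK", "rps16", "trnQ-UUG", "psbK", "psbI",
  "trnS-GCU", "trnG-GCC", "trnR-UCU", "atpA", "atpF", "atpH", "atpI",
  "rps2", "rpoC2", "rpoC1", "rpoB", "trnC-GCA", "petN", "psbM",
  "trnD-GUC", "trnY-GUA", "trnE-UUC", "psbD", "psbC", "psbZ",
  "trnfM-CAU", "rps14", "psaB", "psaA", "ycf3", "rps4", "trnT-GGU",
  "trnL-UAA", "trnF-GAA", "ndhJ", "ndhK", "ndhC", "trnV-UAC",
  "trnM-CAU", "atpE", "atpB", "rbcL", "accD", "psaI", "ycf4", "cemA",
  "petA", "psbJ", "psbL", "psbF", "psbE", "petL", "petG", "trnW-CCA",
  "trnP-UGG", "psaJ", "rpl33", "rps18", "rpl20", "rps12", "clpP",
  "psbB", "psbT", "psbN", "psbH", "petB", "petD", "rpoA", "rps11",
  "rpl36", "infA", "rps8", "rpl14", "rpl16", "rps3", "rpl22", "rps19"
)
GENE_POOL_IR <- c(
  "rpl2", "rpl23", "ycf2", "ndhB", "rps7", "trnV-GAC", "rrn16",
  "trnI-GAU", "trnA-UGC", "rrn23", "rrn4.5", "rrn5", "trnR-ACG",
  "trnN-GUU"
)
GENE_POOL_SSC <- c(
  "ndhF", "rpl32", "trnL-UAG", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
  "ndhI", "ndhA", "ndhH", "rps15", "ycf1"
)

default_planted_ssrs <- function(n_species) {
  rep_n <- function(x) rep_len(x, n_species)
  list(
    list(motif = "A", units = rep_n(12L)),
    list(motif = "A", units = rep_n(14L)),
    list(motif = "A", units = rep_n(c(11L, 12L, 13L))),
    list(motif = "A", units = rep_n(c(12L, 14L, 12L, 13L))),
    list(motif = "T", units = rep_n(c(15L, 16L))),
    list(motif = "AT", units = rep_n(7L)),
    list(motif = "AAG", units = rep_n(5L))
  )
}

default_planted_repeats <- function() {
  list(
    list(rtype = "forward", length = 45L, mismatches = 0L),
    list(rtype = "palindromic", length = 40L, mismatches = 0L),
    list(rtype = "reverse", length = 36L, mismatches = 0L),
    list(rtype = "complement", length = 50L, mismatches = 0L),
    list(rtype = "forward", length = 70L, mismatches = 2L)
  )
}

#' Simulation configuration
#'
#' Study-scale defaults: seven species, ~120 kb genomes with 18 kb inverted
#' repeats and a 15 kb SSC, 90 named genes, gene substitution rates drawn
#' from 0.001-0.01 and spacer/intron rates from 0.005-0.08 expected
#' substitutions per site root-to-tip, indels at 0.002 events per site with
#' geometric lengths (p = 0.35, mean about 2.9 bp), and planted SSR groups
#' emulating shared homopolymer microsatellites (three of them
#' length-variable) plus planted repeats of all four orientation types.
#'
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   seed and configuration.
#' @param n_species Number of tip species (default 7).
#' @param tree `"balanced"` or a Newick string with branch lengths in
#'   expected substitutions per site (rate multiplier 1).
#' @param tree_depth Root-to-tip depth used for the balanced tree.
#' @param genome_kb Approximate genome size in kb.
#' @param ir_len_bp,ssc_len_bp Target IR arm and SSC lengths (bp).
#' @param n_genes Total gene count across regions.
#' @param gene_rate_range,igs_rate_range Uniform ranges for per-locus
#'   substitution rates (expected substitutions/site root-to-tip).
#' @param igs_rates Optional numeric vector recycled over the mutable
#'   spacer blocks in genome order (overrides `igs_rate_range`).
#' @param indel_rate Indel events per site root-to-tip.
#' @param indel_len_p Geometric length parameter for indel sizes.
#' @param planted_ssrs List of `list(motif=, units=)` planted SSR groups
#'   (`units` recycled over species; varying units make the group
#'   length-variable).
#' @param planted_repeats List of `list(rtype=, length=, mismatches=)`
#'   planted repeat pairs.
#' @param invert_ssc_in Character vector of species ids whose SSC is
#'   inverted (emulating an alternative genome arrangement).
#' @param gene_len_range,igs_len_range Uniform draw ranges (bp) for
#'   protein-gene lengths and spacer lengths (tRNA/rRNA genes have fixed
#'   realistic sizes).
#' @param intron_genes Named integer vector: genes to give this many
#'   introns (where present in the layout).
#' @param include_pseudogene Turn the `accD` copy into a pseudogene?
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 7L,
                       tree = "balanced",
                       tree_depth = 0.5,
                       genome_kb = 120,
                       ir_len_bp = 18000L,
                       ssc_len_bp = 15000L,
                       n_genes = 90L,
                       gene_rate_range = c(0.001, 0.01),
                       igs_rate_range = c(0.005, 0.08),
                       igs_rates = NULL,
                       indel_rate = 0.002,
                       indel_len_p = 0.35,
                       gene_len_range = c(250L, 1200L),
                       igs_len_range = c(80L, 400L),
                       planted_ssrs = default_planted_ssrs(n_species),
                       planted_repeats = default_planted_repeats(),
                       invert_ssc_in = character(0),
                       intron_genes = c(clpP = 2L, rpoC1 = 1L, ndhA = 1L),
                       include_pseudogene = TRUE) {
  glen <- genome_kb * 1000
  if (n_genes < 4L) abort("n_genes must be at least 4")
  if (ir_len_bp >= glen / 4) abort("ir_len_bp must be below genome_kb*1000/4")
  if (any(c(gene_rate_range, igs_rate_range, indel_rate) < 0)) {
    abort("rates must be non-negative")
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    tree = tree, tree_depth = tree_depth, genome_kb = genome_kb,
    ir_len_bp = as.integer(ir_len_bp), ssc_len_bp = as.integer(ssc_len_bp),
    n_genes = as.integer(n_genes), gene_rate_range = gene_rate_range,
    igs_rate_range = igs_rate_range, igs_rates = igs_rates,
    indel_rate = indel_rate, indel_len_p = indel_len_p,
    gene_len_range = as.integer(gene_len_range),
    igs_len_range = as.integer(igs_len_range),
    planted_ssrs = planted_ssrs, planted_repeats = planted_repeats,
    invert_ssc_in = invert_ssc_in, intron_genes = intron_genes,
    include_pseudogene = include_pseudogene
  ), class = "sim_config")
}

balanced_newick <- function(ids, depth) {
  build <- function(tips, avail) {
    if (length(tips) == 1L) return(list(str = tips, leaf = TRUE))
    h <- ceiling(length(tips) / 2)
    l <- build(tips[seq_len(h)], avail / 2)
    r <- build(tips[-seq_len(h)], avail / 2)
    el <- if (l$leaf) avail else avail / 2
    er <- if (r$leaf) avail else avail / 2
    list(str = sprintf("(%s:%g,%s:%g)", l$str, el, r$str, er),
         leaf = FALSE)
  }
  h <- ceiling(length(ids) / 2)
  l <- build(ids[seq_len(h)], depth)
  r <- build(ids[-seq_len(h)], depth)
  el <- if (l$leaf) depth else depth / 2
  er <- if (r$leaf) depth else depth / 2
  sprintf("(%s:%g,%s:%g);", l$str, el, r$str, er)
}

sim_tree <- function(cfg) {
  ids <- sprintf("sp%d", seq_len(cfg$n_species))
  nwk <- if (identical(cfg$tree, "balanced")) {
    balanced_newick(ids, cfg$tree_depth)
  } else {
    cfg$tree
  }
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr$edge.length)) abort("tree must carry branch lengths")
  tr
}

# K2P-like mutation of one branch; returns new chars + event log
mutate_branch <- function(chars, p_sub, indel_mean, indel_len_p) {
  events <- list()
  L <- length(chars)
  if (L > 0L && p_sub > 0) {
    nsub <- rbinom(1L, L, min(p_sub, 1))
    if (nsub > 0L) {
      pos <- sort(sample.int(L, nsub))
      transition <- c(A = "G", G = "A", C = "T", T = "C")
      for (p in pos) {
        from <- chars[p]
        if (!from %in% DNA_BASES) next
        to <- if (runif(1) < 2 / 3) {
          transition[[from]]
        } else {
          tv <- setdiff(DNA_BASES, c(from, transition[[from]]))
          tv[sample.int(2L, 1L)]
        }
        chars[p] <- to
        events[[length(events) + 1L]] <-
          list(type = "sub", pos = p, payload = paste0(from, ">", to))
      }
    }
  }
  L <- length(chars)
  if (L > 0L && indel_mean > 0) {
    nind <- rpois(1L, L * indel_mean)
    for (k in seq_len(nind)) {
      len <- min(rgeom(1L, indel_len_p) + 1L, 20L)
      if (runif(1) < 0.5 || length(chars) <= len + 2L) {
        pos <- sample.int(length(chars) + 1L, 1L) - 1L  # insert after pos
        ins <- sample(DNA_BASES, len, replace = TRUE)
        chars <- append(chars, ins, after = pos)
        events[[length(events) + 1L]] <-
          list(type = "ins", pos = pos, payload = paste(ins, collapse = ""))
      } else {
        pos <- sample.int(length(chars) - len, 1L)
        chars <- chars[-(pos:(pos + len - 1L))]
        events[[length(events) + 1L]] <-
          list(type = "del", pos = pos, payload = as.character(len))
      }
    }
  }
  list(chars = chars, events = events)
}

# evolve one block along the tree; returns per-tip sequences + event logs
evolve_block <- function(anc_seq, rate, irate, tr, indel_len_p) {
  tips <- tr$tip.label
  n_tip <- length(tips)
  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  seqs <- setNames(vector("list", n_tip), tips)
  logs <- setNames(vector("list", n_tip), tips)
  recurse <- function(node, chars, events) {
    for (ei in children[[as.character(node)]]) {
      child <- tr$edge[ei, 2]
      b <- tr$edge.length[ei]
      res <- mutate_branch(chars, rate * b, irate * b, indel_len_p)
      ev2 <- c(events, res$events)
      if (child <= n_tip) {
        seqs[[tips[child]]] <<- res$chars
        logs[[tips[child]]] <<- ev2
      } else {
        recurse(child, res$chars, ev2)
      }
    }
  }
  recurse(n_tip + 1L, strsplit(anc_seq, "", fixed = TRUE)[[1]], list())
  list(seqs = seqs, events = logs)
}

apply_events <- function(chars, events) {
  for (ev in events) {
    if (ev$type == "sub") {
      chars[ev$pos] <- sub(".*>", "", ev$payload)
    } else if (ev$type == "ins") {
      chars <- append(chars, strsplit(ev$payload, "", fixed = TRUE)[[1]],
                      after = ev$pos)
    } else {
      len <- as.integer(ev$payload)
      chars <- chars[-(ev$pos:(ev$pos + len - 1L))]
    }
  }
  chars
}

gene_kind <- function(symbol) {
  if (startsWith(symbol, "trn")) "tRNA"
  else if (startsWith(symbol, "rrn")) "rRNA"
  else "gene"
}

gene_length_for <- function(symbol, range) {
  if (startsWith(symbol, "trn")) {
    sample(70:90, 1L)
  } else if (symbol == "rrn16") 1490L
  else if (symbol == "rrn23") 2800L
  else if (symbol == "rrn4.5") 100L
  else if (symbol == "rrn5") 120L
  else sample(range[1]:range[2], 1L)
}

#' Generate a simulated annotated plastome dataset
#'
#' Fully deterministic given the seed in `cfg`. Returns the per-species
#' [plastome_record()]s and a truth manifest: the ancestral block table,
#' per-species event logs (replaying them on the ancestor reproduces each
#' genome exactly, see [replay_manifest()]), planted SSR/repeat coordinates
#' per species, true per-locus rates, per-species region boundaries, and
#' the tree.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `records` (named list of plastome records)
#'   and `manifest`.
#' @export
simulate_plastomes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tr <- sim_tree(cfg)
  species <- tr$tip.label
  n_species <- length(species)
  glen <- cfg$genome_kb * 1000
  lsc_len <- glen - 2L * cfg$ir_len_bp - cfg$ssc_len_bp
  if (lsc_len < cfg$ssc_len_bp) abort("LSC target smaller than SSC target")

  # ---- gene allocation -----------------------------------------------------
  n_ir <- max(3L, min(length(GENE_POOL_IR),
                      round(cfg$n_genes * cfg$ir_len_bp / glen)))
  n_ssc <- max(2L, min(length(GENE_POOL_SSC),
                       round(cfg$n_genes * cfg$ssc_len_bp / glen)))
  n_lsc <- cfg$n_genes - n_ir - n_ssc
  if (n_lsc < 2L) abort("n_genes too small for the region allocation")
  lsc_genes <- rep_len(GENE_POOL_LSC, max(n_lsc, 1L))[seq_len(n_lsc)]
  ir_genes <- GENE_POOL_IR[seq_len(n_ir)]
  ssc_genes <- GENE_POOL_SSC[seq_len(n_ssc)]

  draw_rate <- function(range) runif(1L, range[1], range[2])

  # planted elements occupy interior LSC gaps
  n_planted_slots <- length(cfg$planted_ssrs) + 2L * length(cfg$planted_repeats)
  if (n_planted_slots > n_lsc - 2L) {
    abort("too many planted elements for the LSC gap count (would overlap genes)")
  }
  planted_slot_gaps <- if (n_planted_slots > 0L) {
    slots <- unique(round(seq(2L, n_lsc - 1L, length.out = n_planted_slots)))
    if (length(slots) < n_planted_slots) slots <- seq(2L, 1L + n_planted_slots)
    slots
  } else {
    integer(0)
  }
  # planted payload builders keyed by slot
  repeat_words <- lapply(cfg$planted_repeats, function(pr) {
    random_dna(pr$length)
  })
  planted_payload <- list()
  slot_i <- 0L
  for (gi in seq_along(cfg$planted_ssrs)) {
    slot_i <- slot_i + 1L
    ps <- cfg$planted_ssrs[[gi]]
    planted_payload[[slot_i]] <- list(kind = "ssr", group = gi,
                                      motif = ps$motif,
                                      units = rep_len(ps$units, n_species))
  }
  for (ri in seq_along(cfg$planted_repeats)) {
    pr <- cfg$planted_repeats[[ri]]
    w <- repeat_words[[ri]]
    copy2 <- switch(pr$rtype,
                    forward = w,
                    reverse = reverse_dna(w),
                    palindromic = revcomp(w),
                    complement = complement_dna(w))
    if (pr$mismatches > 0L) {
      ch <- strsplit(copy2, "", fixed = TRUE)[[1]]
      mpos <- sample.int(length(ch), pr$mismatches)
      for (p in mpos) ch[p] <- pick_other_base(ch[p])
      copy2 <- paste(ch, collapse = "")
    }
    planted_payload[[slot_i + 1L]] <- list(kind = "repeat", group = ri,
                                           rtype = pr$rtype, copy = 1L,
                                           word = w,
                                           mismatches = pr$mismatches)
    planted_payload[[slot_i + 2L]] <- list(kind = "repeat", group = ri,
                                           rtype = pr$rtype, copy = 2L,
                                           word = copy2,
                                           mismatches = pr$mismatches)
    slot_i <- slot_i + 2L
  }

  planted_flank <- function() {
    # immutable 100 bp flanks; edge bases forced non-extending later
    random_dna(100L)
  }

  # ---- block layout per region --------------------------------------------
  make_region_blocks <- function(region, genes, target_len, guards) {
    blocks <- list()
    add <- function(role, gene = NA_character_, strand = "+", seq = "",
                    rate = 0, irate = 0, mutable = FALSE, exon = NA_integer_,
                    planted = NULL) {
      blocks[[length(blocks) + 1L]] <<- list(
        region = region, role = role, gene = gene, strand = strand,
        seq = seq, rate = rate, irate = irate, mutable = mutable,
        exon = exon, planted = planted
      )
    }
    if (guards) add("guard", seq = "A")
    gap_no <- 0L
    igs_block <- function() {
      gap_no <<- gap_no + 1L
      slot <- if (region == "LSC") match(gap_no, planted_slot_gaps) else NA
      if (!is.na(slot) && region == "LSC") {
        pay <- planted_payload[[slot]]
        core <- if (pay$kind == "ssr") {
          strrep(pay$motif, max(pay$units))
        } else {
          pay$word
        }
        fl <- planted_flank(); fr <- planted_flank()
        if (pay$kind == "ssr") {
          m <- nchar(pay$motif)
          # keep the run maximal exactly at the planted span
          substr(fl, 100L, 100L) <- pick_other_base(substr(pay$motif, m, m))
          substr(fr, 1L, 1L) <- pick_other_base(substr(pay$motif, 1L, 1L))
        }
        add("planted", seq = paste0(fl, core, fr), planted = pay)
      } else {
        add("igs", seq = random_dna(sample(cfg$igs_len_range[1]:cfg$igs_len_range[2], 1L)),
            rate = if (!is.null(cfg$igs_rates)) NA_real_ else
              draw_rate(cfg$igs_rate_range),
            irate = cfg$indel_rate, mutable = TRUE)
      }
    }
    for (g in genes) {
      igs_block()
      strand <- sample(c("+", "-"), 1L)
      sym <- strip_symbol(g)
      total <- gene_length_for(g, cfg$gene_len_range)
      grate <- draw_rate(cfg$gene_rate_range)
      n_int <- 0L
      if (sym %in% names(cfg$intron_genes) && total >= 400L) {
        n_int <- cfg$intron_genes[[sym]]
      }
      if (n_int == 0L) {
        add("exon", gene = g, strand = strand, seq = random_dna(total),
            rate = grate, irate = cfg$indel_rate, mutable = TRUE, exon = 1L)
      } else {
        exon_lens <- pmax(60L, round(total * rep(1 / (n_int + 1L),
                                                 n_int + 1L)))
        for (e in seq_len(n_int + 1L)) {
          add("exon", gene = g, strand = strand,
              seq = random_dna(exon_lens[e]),
              rate = grate, irate = cfg$indel_rate, mutable = TRUE,
              exon = e)
          if (e <= n_int) {
            add("intron", gene = g, strand = strand,
                seq = random_dna(sample(150:500, 1L)),
                rate = draw_rate(cfg$igs_rate_range),
                irate = cfg$indel_rate, mutable = TRUE)
          }
        }
      }
    }
    igs_block()
    if (guards) add("guard", seq = "A")
    # rescale plain igs blocks toward the target length
    lens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
    is_igs <- vapply(blocks, function(b) b$role == "igs", logical(1))
    fixed <- sum(lens[!is_igs])
    want <- target_len - fixed
    if (want < sum(is_igs) * 30L) {
      abort(sprintf("region %s too small for its gene content", region))
    }
    cur <- sum(lens[is_igs])
    scale <- want / cur
    idx <- which(is_igs)
    for (i in idx) {
      newl <- max(30L, as.integer(round(nchar(blocks[[i]]$seq) * scale)))
      if (newl <= nchar(blocks[[i]]$seq)) {
        blocks[[i]]$seq <- substr(blocks[[i]]$seq, 1L, newl)
      } else {
        blocks[[i]]$seq <- paste0(blocks[[i]]$seq,
                                  random_dna(newl - nchar(blocks[[i]]$seq)))
      }
    }
    blocks
  }

  lsc_blocks <- make_region_blocks("LSC", lsc_genes, lsc_len, guards = TRUE)
  ira_blocks <- make_region_blocks("IRa", ir_genes, cfg$ir_len_bp,
                                   guards = FALSE)
  ssc_blocks <- make_region_blocks("SSC", ssc_genes, cfg$ssc_len_bp,
                                   guards = TRUE)

  if (cfg$include_pseudogene) {
    # accD where present, otherwise the last single-exon protein gene
    syms_l <- vapply(lsc_blocks, function(b) b$gene %||% NA_character_,
                     character(1))
    cand <- unique(syms_l[!is.na(syms_l)])
    cand <- cand[!grepl("^(trn|rrn)", cand) &
                   !(strip_symbol(cand) %in% names(cfg$intron_genes))]
    target <- if ("accD" %in% cand) "accD" else utils::tail(cand, 1)
    if (length(target) == 1L && !is.na(target)) {
      for (i in seq_along(lsc_blocks)) {
        if (identical(lsc_blocks[[i]]$gene, target)) {
          lsc_blocks[[i]]$role <- "pseudo_exon"
        }
      }
    }
  }

  blocks <- c(lsc_blocks, ira_blocks, ssc_blocks)
  # explicit igs rates recycle over the mutable spacer blocks in order
  if (!is.null(cfg$igs_rates)) {
    igs_idx <- which(vapply(blocks, function(b) b$role == "igs", logical(1)))
    rates <- rep_len(cfg$igs_rates, length(igs_idx))
    for (j in seq_along(igs_idx)) blocks[[igs_idx[j]]]$rate <- rates[j]
  }

  # ---- scrub incidental SSRs from the ancestral background ----------------
  scrub_thresholds <- pmax(ssr_default_thresholds - 2L, 3L)
  scrub_thresholds["1"] <- max(scrub_thresholds["1"], 6L)
  block_lens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  offsets <- cumsum(c(0L, utils::head(block_lens, -1L)))
  protected <- logical(sum(block_lens))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b$role %in% c("guard", "planted")) {
      protected[(offsets[i] + 1L):(offsets[i] + block_lens[i])] <- TRUE
    }
  }
  anc <- paste(vapply(blocks, function(b) b$seq, character(1)),
               collapse = "")
  for (iter in 1:25) {
    hits <- scan_ssrs(anc, thresholds = scrub_thresholds)
    hits <- hits[!vapply(seq_len(nrow(hits)), function(i) {
      any(protected[(hits$start[i] + 1L):hits$end[i]])
    }, logical(1)), , drop = FALSE]
    if (nrow(hits) == 0L) break
    for (i in seq_len(nrow(hits))) {
      mid <- hits$start[i] + (hits$end[i] - hits$start[i]) %/% 2L
      substr(anc, mid + 1L, mid + 1L) <-
        pick_other_base(substr(anc, mid + 1L, mid + 1L))
    }
  }
  # write scrubbed content back into blocks
  for (i in seq_along(blocks)) {
    blocks[[i]]$seq <- substr(anc, offsets[i] + 1L,
                              offsets[i] + block_lens[i])
  }

  # ---- evolution -----------------------------------------------------------
  n_blocks <- length(blocks)
  tip_seqs <- vector("list", n_blocks)
  tip_events <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    b <- blocks[[i]]
    if (b$mutable) {
      res <- evolve_block(b$seq, b$rate, b$irate, tr, cfg$indel_len_p)
      tip_seqs[[i]] <- lapply(res$seqs, paste, collapse = "")
      tip_events[[i]] <- res$events
    } else {
      sq <- b$seq
      evs <- setNames(rep(list(list()), n_species), species)
      if (!is.null(b$planted) && b$planted$kind == "ssr") {
        # per-species unit counts become recorded indel events
        m <- nchar(b$planted$motif)
        u0 <- max(b$planted$units)
        for (s in seq_along(species)) {
          us <- b$planted$units[s]
          if (us < u0) {
            evs[[s]] <- list(list(type = "del", pos = 101L,
                                  payload = as.character((u0 - us) * m)))
          }
        }
      }
      tip_seqs[[i]] <- setNames(lapply(seq_along(species), function(s) {
        paste(apply_events(strsplit(sq, "", fixed = TRUE)[[1]], evs[[s]]),
              collapse = "")
      }), species)
      tip_events[[i]] <- evs
    }
  }

  # ---- assembly per species ------------------------------------------------
  region_of <- vapply(blocks, function(b) b$region, character(1))
  order_template <- list(
    LSC = which(region_of == "LSC"),
    IRa = which(region_of == "IRa"),
    SSC = which(region_of == "SSC")
  )

  records <- list()
  regions_truth <- list()
  planted_ssr_truth <- list()
  planted_rep_truth <- list()

  for (s in species) {
    ssc_inverted <- s %in% cfg$invert_ssc_in
    # block order: LSC, IRa, SSC (possibly inverted), IRb (= revcomp IRa)
    seq_parts <- character(0)
    feat_rows <- list()
    pos <- 0L
    region_bounds <- list()
    planted_here <- list()

    emit_block <- function(i, seq, strand_flip = FALSE) {
      b <- blocks[[i]]
      start <- pos
      len <- nchar(seq)
      seq_parts[length(seq_parts) + 1L] <<- seq
      pos <<- pos + len
      strand <- if (strand_flip) {
        if (b$strand == "+") "-" else "+"
      } else {
        b$strand
      }
      list(block = i, start = start, end = pos, strand = strand)
    }

    assemble_region <- function(idx, region_label, mirror = FALSE,
                                inverted = FALSE) {
      r_start <- pos
      ord <- idx
      if (mirror || inverted) ord <- rev(idx)
      gene_segs <- list()  # gene -> list of exon spans, in emit order
      for (i in ord) {
        b <- blocks[[i]]
        sq <- tip_seqs[[i]][[s]]
        if (mirror || inverted) sq <- revcomp(sq)
        info <- emit_block(i, sq, strand_flip = mirror || inverted)
        if (b$role %in% c("exon", "pseudo_exon")) {
          key <- b$gene
          gene_segs[[key]] <- c(gene_segs[[key]],
                                list(c(info$start, info$end,
                                       match(info$strand, c("+", "-")),
                                       b$role == "pseudo_exon")))
        }
        if (b$role == "planted") {
          pay <- b$planted
          if (pay$kind == "ssr") {
            m <- nchar(pay$motif)
            units <- pay$units[match(s, species)]
            planted_here[[length(planted_here) + 1L]] <<- tibble(
              kind = "ssr", group = pay$group, motif = pay$motif,
              start = info$start + 100L,
              end = info$start + 100L + units * m,
              n_repeats = units, rtype = NA_character_,
              copy = NA_integer_, mismatches = NA_integer_
            )
          } else {
            planted_here[[length(planted_here) + 1L]] <<- tibble(
              kind = "repeat", group = pay$group, motif = NA_character_,
              start = info$start + 100L,
              end = info$start + 100L + nchar(pay$word),
              n_repeats = NA_integer_, rtype = pay$rtype,
              copy = pay$copy, mismatches = pay$mismatches
            )
          }
        }
      }
      # one feature per gene: exon-part union
      for (g in names(gene_segs)) {
        segs <- gene_segs[[g]]
        starts <- vapply(segs, `[`, numeric(1), 1L)
        ends <- vapply(segs, `[`, numeric(1), 2L)
        strand <- c("+", "-")[segs[[1]][3]]
        pseudo <- segs[[1]][4] == 1
        sym <- g
        kind <- if (pseudo) "pseudogene" else gene_kind(sym)
        ord2 <- order(starts)
        feat_rows[[length(feat_rows) + 1L]] <<- tibble(
          name = sym, kind = kind,
          start = as.integer(min(starts)), end = as.integer(max(ends)),
          strand = strand, wraps_origin = FALSE,
          parts = list(tibble(start = as.integer(starts[ord2]),
                              end = as.integer(ends[ord2])))
        )
      }
      region_bounds[[length(region_bounds) + 1L]] <<- tibble(
        region = region_label, start = r_start, end = pos
      )
    }

    assemble_region(order_template$LSC, "LSC")
    assemble_region(order_template$IRa, "IRa")
    assemble_region(order_template$SSC, "SSC", inverted = ssc_inverted)
    assemble_region(order_template$IRa, "IRb", mirror = TRUE)

    genome <- paste(seq_parts, collapse = "")
    features <- bind_rows(feat_rows) %>% arrange(.data$start)
    records[[s]] <- plastome_record(s, genome, features)
    regions_truth[[s]] <- bind_rows(region_bounds) %>%
      mutate(species_id = s)
    if (length(planted_here)) {
      planted_df <- bind_rows(planted_here) %>% mutate(species_id = s)
      planted_ssr_truth[[s]] <- filter(planted_df, .data$kind == "ssr")
      planted_rep_truth[[s]] <- filter(planted_df, .data$kind == "repeat")
    }
  }

  # planted repeats: pair the two copies into pos1/pos2 rows
  planted_repeats_tbl <- if (length(planted_rep_truth)) {
    bind_rows(planted_rep_truth) %>%
      select("species_id", "group", "rtype", "copy", "start", "end",
             "mismatches") %>%
      tidyr::pivot_wider(names_from = "copy",
                         values_from = c("start", "end")) %>%
      mutate(pos1 = pmin(.data$start_1, .data$start_2),
             pos2 = pmax(.data$start_1, .data$start_2),
             length = .data$end_1 - .data$start_1) %>%
      select("species_id", "group", "rtype", "pos1", "pos2", "length",
             "mismatches")
  } else {
    tibble()
  }

  # ---- per-locus true rates (weighted over blocks of each derived gap) ----
  locus_rates <- sim_locus_rates(blocks)

  manifest <- list(
    seed = cfg$seed,
    tree = ape::write.tree(tr),
    species = species,
    blocks = tibble(
      block = seq_len(n_blocks),
      region = region_of,
      role = vapply(blocks, function(b) b$role, character(1)),
      gene = vapply(blocks, function(b) b$gene %||% NA_character_,
                    character(1)),
      strand = vapply(blocks, function(b) b$strand, character(1)),
      rate = vapply(blocks, function(b) b$rate, numeric(1)),
      indel_rate = vapply(blocks, function(b) b$irate, numeric(1)),
      mutable = vapply(blocks, function(b) b$mutable, logical(1)),
      seq = vapply(blocks, function(b) b$seq, character(1))
    ),
    events = setNames(lapply(species, function(s) {
      lapply(tip_events, function(ev) ev[[s]])
    }), species),
    ssc_inverted = cfg$invert_ssc_in,
    planted_ssrs = if (length(planted_ssr_truth)) {
      bind_rows(planted_ssr_truth) %>%
        mutate(canonical_class = vapply(.data$motif, canonical_class,
                                        character(1), USE.NAMES = FALSE)) %>%
        select("species_id", "group", "motif", "canonical_class", "start",
               "end", "n_repeats")
    } else {
      tibble()
    },
    planted_repeats = planted_repeats_tbl,
    regions = bind_rows(regions_truth),
    locus_rates = locus_rates
  )
  list(records = records, manifest = manifest)
}

# true per-locus rates, as the catalogue module will name the loci:
# genes by bare symbol, introns gene.intronN, gaps A-B; composite gaps
# (guards/planted flanks inside) get length-weighted rates
sim_locus_rates <- function(blocks) {
  rows <- list()
  syms <- vapply(blocks, function(b) {
    if (is.na(b$gene %||% NA_character_)) NA_character_
    else strip_symbol(b$gene)
  }, character(1))
  roles <- vapply(blocks, function(b) b$role, character(1))
  # gene + intron loci
  i <- 1L
  while (i <= length(blocks)) {
    b <- blocks[[i]]
    if (roles[i] %in% c("exon", "pseudo_exon")) {
      nm <- if (roles[i] == "pseudo_exon") paste0(syms[i], "psi") else syms[i]
      rows[[length(rows) + 1L]] <- tibble(
        locus_name = nm,
        ltype = if (roles[i] == "pseudo_exon") "pseudogene" else "gene",
        rate = b$rate, pure = TRUE
      )
      intron_no <- 0L
      j <- i + 1L
      while (j <= length(blocks) && roles[j] %in% c("intron", "exon",
                                                    "pseudo_exon") &&
             identical(syms[j], syms[i])) {
        if (roles[j] == "intron") {
          intron_no <- intron_no + 1L
          rows[[length(rows) + 1L]] <- tibble(
            locus_name = sprintf("%s.intron%d", syms[i], intron_no),
            ltype = "intron", rate = blocks[[j]]$rate, pure = TRUE
          )
        }
        j <- j + 1L
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  # gaps between consecutive genes (guards and planted flanks included)
  gene_block <- !is.na(syms) & roles %in% c("exon", "pseudo_exon")
  gene_ids <- unique(syms[gene_block])
  # walk blocks; a gap is a run of non-gene blocks between two gene symbols
  gap_rows <- list()
  cur_gap <- integer(0)
  prev_sym <- NA_character_
  first_sym <- NA_character_
  leading_gap <- integer(0)
  for (i in seq_along(blocks)) {
    if (gene_block[i] || roles[i] == "intron") {
      if (gene_block[i]) {
        if (is.na(prev_sym)) {
          first_sym <- syms[i]
          leading_gap <- cur_gap
        } else if (length(cur_gap) && syms[i] != prev_sym) {
          gap_rows[[length(gap_rows) + 1L]] <-
            list(a = prev_sym, b = syms[i], blocks = cur_gap)
        }
        prev_sym <- syms[i]
        cur_gap <- integer(0)
      }
    } else {
      cur_gap <- c(cur_gap, i)
    }
  }
  # the closing arc of the circle runs through the mirrored IRb, which is
  # not in the block table; its gaps mirror IRa gaps, so no closing row
  invisible(leading_gap)
  for (g in gap_rows) {
    lens <- vapply(g$blocks, function(i) nchar(blocks[[i]]$seq), integer(1))
    rates <- vapply(g$blocks, function(i) blocks[[i]]$rate, numeric(1))
    mut <- vapply(g$blocks, function(i) blocks[[i]]$mutable, logical(1))
    if (sum(lens) == 0L) next
    rows[[length(rows) + 1L]] <- tibble(
      locus_name = paste0(g$a, "-", g$b),
      ltype = "IGS",
      rate = sum(rates * lens * mut) / sum(lens),
      pure = all(mut)
    )
  }
  bind_rows(rows)
}

#' Replay a truth manifest
#'
#' Applies each species' recorded event log to the ancestral blocks and
#' re-assembles the genome; the result must equal the emitted sequence
#' exactly.
#'
#' @param sim Output of [simulate_plastomes()].
#' @return Named logical vector: per species, does the replay match?
#' @export
replay_manifest <- function(sim) {
  man <- sim$manifest
  blocks <- man$blocks
  vapply(man$species, function(s) {
    ev <- man$events[[s]]
    per_block <- vapply(seq_len(nrow(blocks)), function(i) {
      paste(apply_events(strsplit(blocks$seq[i], "", fixed = TRUE)[[1]],
                         ev[[i]]), collapse = "")
    }, character(1))
    region <- blocks$region
    inv <- s %in% man$ssc_inverted
    seg <- function(idx, rc = FALSE) {
      x <- per_block[idx]
      if (rc) paste(revcomp(rev(x)), collapse = "") else
        paste(x, collapse = "")
    }
    genome <- paste0(
      seg(which(region == "LSC")),
      seg(which(region == "IRa")),
      seg(which(region == "SSC"), rc = inv),
      seg(which(region == "IRa"), rc = TRUE)
    )
    identical(genome, sim$records[[s]]$sequence)
  }, logical(1))
}

#' First-order expected percent variation
#'
#' Analytic anchor for the divergence statistic on simulated loci:
#' `100 * (NS + ID) / L` with `NS ~ rate * locus_len`,
#' `ID ~ indel_rate * locus_len` events, and `L` inflated by half the
#' inserted bases. Multiple hits at higher rates make the empirical value
#' fall below this expectation.
#'
#' @param rate Expected substitutions/site between the two tips.
#' @param indel_rate Expected indel events/site between the two tips.
#' @param mean_indel_len Mean indel length (bp).
#' @param locus_len Unaligned locus length (bp).
#' @return Expected percent variation (0-100 scale).
#' @export
expected_pct <- function(rate, indel_rate = 0, mean_indel_len = 3,
                         locus_len = 1000) {
  events <- indel_rate * locus_len
  L <- locus_len + 0.5 * events * mean_indel_len
  100 * (rate * locus_len + events) / L
}

#' Write a simulated dataset to disk
#'
#' GenBank flat files per species plus the truth manifest as JSON.
#'
#' @param sim Output of [simulate_plastomes()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$records)) {
    write_genbank(sim$records[[s]], file.path(dir, paste0(s, ".gb")))
  }
  man <- sim$manifest
  jsonlite::write_json(
    list(seed = man$seed, tree = man$tree, species = man$species,
         planted_ssrs = man$planted_ssrs,
         planted_repeats = man$planted_repeats,
         regions = man$regions, locus_rates = man$locus_rates),
    file.path(dir, "truth_manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
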