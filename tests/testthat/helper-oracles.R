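# Independent brute-force oracles and small fixture builders shared across
# the test files. The per-base evaluator deliberately avoids interval
# arithmetic: it marks boolean arrays position by position.

# Build a contig_genome_map directly from synthetic qualifying hits.
make_cmap <- function(hits, contig_lengths) {
  if (!"genome_seq_id" %in% names(hits)) hits$genome_seq_id <- hits$genome_id
  if (!"percent_identity" %in% names(hits)) hits$percent_identity <- 100
  if (!"alignment_length" %in% names(hits)) {
    hits$alignment_length <- hits$c_end - hits$c_start
  }
  magbench::filter_qualifying(hits, contig_lengths)
}

# Per-base boolean-array evaluator: tp/fn over genome positions, fp over
# contig positions of the representative bin.
brute_force_genome_eval <- function(genome_id, genome_seq_lengths, bin_contigs,
                                    cmap) {
  covered <- lapply(genome_seq_lengths, function(L) logical(L))
  h <- cmap$hits
  h <- h[h$genome_id == genome_id & h$contig_id %in% bin_contigs, ]
  if (nrow(h) > 0) {
    for (i in seq_len(nrow(h))) {
      sid <- h$genome_seq_id[i]
      idx <- seq.int(h$g_start[i] + 1, h$g_end[i])
      covered[[sid]][idx] <- TRUE
    }
  }
  tp <- sum(vapply(covered, sum, 0))
  fn <- sum(unlist(genome_seq_lengths)) - tp
  fp <- 0
  hg <- cmap$hits[cmap$hits$genome_id == genome_id, ]
  for (cid in bin_contigs) {
    mask <- logical(cmap$contig_lengths[[cid]])
    hc <- hg[hg$contig_id == cid, ]
    if (nrow(hc) > 0) {
      for (i in seq_len(nrow(hc))) {
        mask[seq.int(hc$c_start[i] + 1, hc$c_end[i])] <- TRUE
      }
    }
    fp <- fp + sum(!mask)
  }
  list(tp = tp, fn = fn, fp = fp)
}

# Random evaluator instance: genomes (single-sequence), contigs with
# qualifying hits (splits, repeats, shared contigs, foreign contigs), and a
# random bin partition. Returns everything needed for both evaluators.
random_eval_instance <- function(seed, n_genomes = 3, n_contigs = 30,
                                 genome_len = 50000) {
  withr::with_seed(seed, {
    genome_ids <- paste0("g", seq_len(n_genomes))
    glen <- stats::setNames(rep(genome_len, n_genomes), genome_ids)
    hits <- list()
    contig_lengths <- numeric(0)
    for (i in seq_len(n_contigs)) {
      cid <- sprintf("c%03d", i)
      lc <- sample(500:3000, 1)
      contig_lengths[cid] <- lc
      kind <- sample(c("plain", "split", "shared", "foreign"), 1,
                     prob = c(0.5, 0.2, 0.2, 0.1))
      gid <- sample(genome_ids, 1)
      add_hit <- function(g, gs, cs, ce) {
        tibble::tibble(contig_id = cid, genome_id = g, genome_seq_id = g,
                       percent_identity = 100, alignment_length = ce - cs,
                       c_start = cs, c_end = ce,
                       g_start = gs, g_end = gs + (ce - cs), strand = "+")
      }
      if (kind == "foreign") next
      gs <- sample.int(genome_len - lc, 1)
      if (kind == "plain") {
        hits[[length(hits) + 1]] <- add_hit(gid, gs, 0, lc)
      } else if (kind == "split") {
        cut <- sample(100:(lc - 100), 1)
        gs2 <- sample.int(genome_len - lc, 1)
        hits[[length(hits) + 1]] <- add_hit(gid, gs, 0, cut)
        hits[[length(hits) + 1]] <- add_hit(gid, gs2, cut, lc)
      } else { # shared between two genomes
        gid2 <- sample(setdiff(genome_ids, gid), 1)
        gs2 <- sample.int(genome_len - lc, 1)
        hits[[length(hits) + 1]] <- add_hit(gid, gs, 0, lc)
        hits[[length(hits) + 1]] <- add_hit(gid2, gs2, 0, lc)
      }
    }
    # split hits have alignment_length < 0.99 * lc, so build the map without
    # re-filtering: these are "given" qualifying hits for the equivalence test
    cmap <- structure(list(contig_lengths = contig_lengths,
                           hits = dplyr::bind_rows(hits)),
                      class = "contig_genome_map")
    bin_ids <- paste0("b", sample.int(n_genomes + 1, length(contig_lengths),
                                      replace = TRUE))
    bins <- tibble::tibble(contig_id = names(contig_lengths), bin_id = bin_ids)
    list(genome_ids = genome_ids, genome_lengths = glen, cmap = cmap,
         bins = bins)
  })
}

# Small two-species / two-strain collection used by several files.
tiny_collection <- function(seed = 1, ...) {
  magbench::generate_collection(magbench::fixture_spec(
    seed = seed, n_species = 2, strains_per_species = 2,
    genome_length = 20000, strain_substitution_rate = 0.01, ...))
}

# A strain-clustered db for mirror-spec tests, built directly (no ANI calls).
toy_db <- function() {
  g <- tibble::tibble(
    genome_id = c("isoA", "magB", "magC", "isoD", "magE"),
    is_isolate = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    species_cluster_id = c("sp1", "sp1", "sp1", "sp2", "sp2"),
    is_species_representative = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    strain_cluster_id = c("sp1.s1", "sp1.s1", "sp1.s2", "sp2.s1", "sp2.s1"),
    total_length = c(50000, 52000, 48000, 60000, 59000),
    n50 = c(9000, 12000, 8000, 20000, 15000),
    fasta_path = NA_character_)
  seqs <- lapply(g$genome_id, function(id) {
    s <- Biostrings::DNAStringSet(paste(rep("ACGT", 250), collapse = ""))
    names(s) <- paste0(id, "_c1")
    s
  })
  names(seqs) <- g$genome_id
  magbench:::new_reference_db(g, seqs)
}

query_row <- function(genome_id, ani, token, ci) {
  tibble::tibble(genome_id = genome_id, adjusted_ani = ani,
                 ani_ci_lower = ci, eff_lambda_token = token)
}
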