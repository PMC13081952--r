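hit_row <- function(cid, gid, gs, ge, cs = 0, ce = ge - gs) {
  tibble::tibble(contig_id = cid, genome_id = gid, genome_seq_id = gid,
                 percent_identity = 100, alignment_length = ce - cs,
                 c_start = cs, c_end = ce, g_start = gs, g_end = ge,
                 strand = "+")
}

direct_cmap <- function(hits, lens) {
  structure(list(contig_lengths = lens, hits = hits),
            class = "contig_genome_map")
}

test_that("recall uses interval unions over genome basepairs", {
  cmap <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "g", 0, 4000), hit_row("c2", "g", 3000, 8000)),
    c(c1 = 4000, c2 = 5000))
  r <- genome_bin_recall(10000, "g", c("c1", "c2"), cmap)
  expect_equal(r$tp, 8000)
  expect_equal(r$fn, 2000)

  r0 <- genome_bin_recall(10000, "g", character(0), cmap)
  expect_equal(r0$tp, 0)
  expect_equal(r0$fn, 10000)

  cmap2 <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "g", 0, 4000), hit_row("c2", "g", 0, 4000)),
    c(c1 = 4000, c2 = 4000))
  expect_equal(genome_bin_recall(10000, "g", c("c1", "c2"), cmap2)$tp, 4000)
})

test_that("representative bin is argmax recall with lexicographic ties", {
  cmap <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "g", 0, 4000), hit_row("c2", "g", 0, 9000),
                     hit_row("c3", "g", 0, 5000), hit_row("c4", "g", 5000, 10000)),
    c(c1 = 4000, c2 = 9000, c3 = 5000, c4 = 5000))
  bins <- list(b1 = "c1", b2 = "c2")
  expect_equal(select_representative(10000, "g", bins, cmap)$bin_id, "b2")

  tie_bins <- list(b2 = "c4", b1 = "c3")
  sel <- select_representative(10000, "g", tie_bins, cmap)
  expect_equal(sel$bin_id, "b1")
  expect_equal(sel$tp, 5000)

  none <- select_representative(10000, "g", list(), cmap)
  expect_true(is.na(none$bin_id))
  expect_equal(none$fn, 10000)

  # two genomes may share one representative bin
  cmap2 <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "gA", 0, 3000), hit_row("c2", "gB", 0, 3000)),
    c(c1 = 3000, c2 = 3000))
  both <- list(b = c("c1", "c2"))
  expect_equal(select_representative(3000, "gA", both, cmap2)$bin_id, "b")
  expect_equal(select_representative(3000, "gB", both, cmap2)$bin_id, "b")
})

test_that("false positives count unmapped contig bases of the representative", {
  cmap <- direct_cmap(
    hit_row("c1", "g", 0, 5000),
    c(c1 = 5000, foreign = 1000))
  p <- genome_precision("g", c("c1", "foreign"), cmap, tp = 5000, fn = 0)
  expect_equal(p$fp, 1000)
  expect_equal(p$precision, 5000 / 6000)

  pclean <- genome_precision("g", "c1", cmap, tp = 5000, fn = 0)
  expect_equal(pclean$fp, 0)
  expect_equal(pclean$precision, 1)

  # harmonic mean of equal recall and precision
  cmap2 <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "g", 0, 8000)),
    c(c1 = 8000, x = 2000))
  p2 <- genome_precision("g", c("c1", "x"), cmap2, tp = 8000, fn = 2000)
  expect_equal(p2$fscore, 0.8)
})

test_that("interval evaluator equals the per-base oracle on random instances", {
  for (s in 1:12) {
    inst <- random_eval_instance(s)
    bins <- split(inst$bins$contig_id, inst$bins$bin_id)
    for (gid in inst$genome_ids) {
      glen <- inst$genome_lengths[[gid]]
      seq_lens <- stats::setNames(list(glen), gid)
      for (b in names(bins)) {
        fast <- genome_bin_recall(glen, gid, bins[[b]], inst$cmap)
        slow <- brute_force_genome_eval(gid, seq_lens, bins[[b]], inst$cmap)
        expect_equal(c(fast$tp, fast$fn), c(slow$tp, slow$fn))
        prec <- genome_precision(gid, bins[[b]], inst$cmap, fast$tp, fast$fn)
        expect_equal(prec$fp, slow$fp)
      }
    }
  }
})

test_that("evaluation table satisfies the conservation and bound invariants", {
  inst <- random_eval_instance(99)
  genomes <- tibble::tibble(genome_id = inst$genome_ids,
                            total_length = unname(inst$genome_lengths))
  ev <- evaluate_bins(genomes, inst$bins, inst$cmap, "s1", "p1")
  expect_equal(ev$tp_bp + ev$fn_bp, genomes$total_length)
  both_pos <- ev$recall > 0 & ev$precision > 0
  expect_true(all(ev$fscore[both_pos] >=
                    pmin(ev$recall, ev$precision)[both_pos]))
  expect_true(all(ev$fscore[both_pos] <=
                    pmax(ev$recall, ev$precision)[both_pos]))
  expect_error(evaluate_bins(genomes, dplyr::bind_rows(inst$bins, inst$bins[1, ]),
                             inst$cmap), "more than one bin")
})

test_that("recoverable set requires both gates in a single pipeline", {
  ev <- function(r, p, pipe) {
    tibble::tibble(genome_id = "g", sample_id = "s", pipeline = pipe,
                   recall = r, precision = p)
  }
  expect_equal(nrow(recoverable_set(ev(0.71, 0.91, "a"))), 1)
  expect_equal(nrow(recoverable_set(
    dplyr::bind_rows(ev(0.9, 0.89, "a"), ev(0.69, 0.99, "b")))), 0)
  expect_equal(nrow(recoverable_set(ev(0.7, 0.9, "a"))), 1)
  expect_equal(nrow(recoverable_set(ev(0.699999, 0.95, "a"))), 0)
})

test_that("coverage filter keeps genomes at or above the threshold", {
  db <- magbench:::new_reference_db(
    tibble::tibble(genome_id = c("g1", "g2"), is_isolate = TRUE,
                   species_cluster_id = "sp", is_species_representative = c(TRUE, FALSE),
                   strain_cluster_id = "sp.s1",
                   total_length = c(400000, 401000), n50 = 1, fasta_path = NA),
    list(g1 = Biostrings::DNAStringSet("A"), g2 = Biostrings::DNAStringSet("A")))
  spec <- tibble::tibble(sample_id = "s", genome_id = c("g1", "g2"),
                         relative_abundance = 0.5, source = "x",
                         seed = 1L, num_reads = 10000L)
  # g1: exactly 2.5x; g2: just under
  expect_equal(coverage_filter(spec, db, threshold = 2.5, read_length = 100),
               "g1")
  expect_setequal(coverage_filter(spec, db, threshold = 0, read_length = 100),
                  c("g1", "g2"))
})

test_that("MIMAG classification matches the printed thresholds", {
  expect_equal(classify_mimag(95, 3), "HQ")
  expect_equal(classify_mimag(95, 8), "MQ")
  expect_equal(classify_mimag(40, 12), "UNCLASSIFIED")
  expect_equal(classify_mimag(40, 9), "LQ")
  expect_error(classify_mimag(101, 1), "completeness")
  expect_error(classify_mimag(50, -1), "contamination")
  # contamination can exceed 100
  expect_equal(classify_mimag(80, 150), "UNCLASSIFIED")
})

test_that("GUNC filtering removes failed representatives and summarizes them", {
  ev <- tibble::tibble(
    genome_id = paste0("g", 1:4), sample_id = "s", pipeline = "p",
    representative_bin = paste0("b", 1:4),
    tp_bp = 1, fn_bp = 1, fp_bp = 1,
    recall = c(0.9, 0.8, 0.4, 0.2), precision = c(0.95, 0.9, 0.5, 0.4),
    fscore = 0.5, degenerate = FALSE)
  qc <- tibble::tibble(bin_id = paste0("b", 1:4),
                       gunc_pass = c(TRUE, TRUE, TRUE, TRUE))
  res <- apply_gunc_filter(ev, qc)
  expect_equal(nrow(res$kept), 4)
  expect_equal(res$summary$n_removed, 0)

  qc2 <- dplyr::mutate(qc, gunc_pass = c(TRUE, FALSE, FALSE, TRUE))
  res2 <- apply_gunc_filter(ev, qc2)
  expect_equal(nrow(res2$kept), 2)
  expect_equal(res2$summary$removed_fraction, 0.5)
  expect_equal(res2$summary$removed_mean_recall, mean(c(0.8, 0.4)))
  expect_equal(res2$summary$removed_mean_one_minus_precision,
               mean(1 - c(0.9, 0.5)))

  expect_error(apply_gunc_filter(ev, qc2[1:2, ]), "missing from the GUNC")
  res3 <- apply_gunc_filter(ev, qc2[1:2, ], missing = "pass")
  expect_equal(nrow(res3$kept), 3)
})

test_that("assembly recall restricts the denominator to assembled bases", {
  # genome 10000 bp; only [0, 5000) assembled, all of it in the bin
  cmap <- direct_cmap(hit_row("c1", "g", 0, 5000), c(c1 = 5000))
  bins <- list(b = "c1")
  expect_equal(assembly_recall(10000, "g", bins, cmap), 1)
  expect_equal(genome_bin_recall(10000, "g", "c1", cmap)$tp / 10000, 0.5)

  # nothing assembled
  cmap0 <- direct_cmap(hit_row("c1", "other", 0, 5000), c(c1 = 5000))
  expect_true(is.na(assembly_recall(10000, "g", bins, cmap0)))

  # fully assembled: assembly recall equals plain recall
  cmap_full <- direct_cmap(
    dplyr::bind_rows(hit_row("c1", "g", 0, 5000), hit_row("c2", "g", 5000, 10000)),
    c(c1 = 5000, c2 = 5000))
  expect_equal(assembly_recall(10000, "g", list(b = c("c1", "c2")), cmap_full), 1)
  expect_equal(assembly_recall(10000, "g", list(b = "c1"), cmap_full), 0.5)
})

test_that("quality report adapters parse their dialects", {
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "checkm2.tsv")
  readr::write_tsv(tibble::tibble(Name = c("b1", "b2"),
                                  Completeness = c(95, 40),
                                  Contamination = c(3, 12)), cpath)
  cm <- read_checkm2(cpath)
  expect_equal(cm$mimag_class, c("HQ", "UNCLASSIFIED"))

  gpath <- file.path(dir, "gunc.tsv")
  readr::write_tsv(tibble::tibble(genome = c("b1", "b2"),
                                  `pass.GUNC` = c(TRUE, FALSE)), gpath)
  g <- read_gunc(gpath)
  expect_equal(g$gunc_pass, c(TRUE, FALSE))
})
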