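test_that("tetranucleotide composition pools reverse complements", {
  v <- tetranucleotide_composition("AAAA")
  expect_length(v, 136)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["AAAA"]), 1)

  withr::with_seed(3, {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  })
  expect_equal(tetranucleotide_composition(s),
               tetranucleotide_composition(magbench:::reverse_complement(s)))

  # brute-force window enumeration of ACGTACGT (5 windows)
  v2 <- tetranucleotide_composition("ACGTACGT")
  windows <- c("ACGT", "CGTA", "GTAC", "TACG", "ACGT")
  canon <- vapply(windows, function(w) {
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", w), NULL)[[1]]),
                collapse = "")
    min(w, rc)
  }, "")
  brute <- table(canon) / length(canon)
  for (nm in names(brute)) {
    expect_equal(unname(v2[nm]), unname(as.numeric(brute[nm])))
  }
  expect_equal(sum(v2[setdiff(names(v2), names(brute))]), 0)

  # N-containing windows are skipped
  expect_equal(unname(tetranucleotide_composition("AAAANAAAA")["AAAA"]), 1)
  expect_error(tetranucleotide_composition("ANNNA"), "no valid")
})

test_that("composition distance is the cosine distance", {
  expect_equal(composition_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(composition_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(composition_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(composition_distance(c(0, 0), c(1, 0)), "zero vector")
  expect_error(composition_distance(c(1, 0, 0), c(1, 0)), "length")
})

test_that("coverage distance is Euclidean", {
  expect_equal(coverage_distance(c(5, 5), c(5, 5)), 0)
  expect_equal(coverage_distance(10, 7), 3)
  expect_equal(coverage_distance(c(1, 2, 3), c(1, 2, 7)), 4)
  expect_error(coverage_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("percentile discretization follows the midpoint inequality", {
  # 100 equal-length items with strictly increasing distance -> item i in p = i-1
  items <- tibble::tibble(sample_id = "s", contig_id = sprintf("c%03d", 1:100),
                          genome_id = "g", length = 1000,
                          distance = seq_len(100))
  a <- percentile_discretize(items)
  expect_equal(a$percentile, 0:99)

  # first item has s_c = 0, so p = 0 whenever l_c/2 <= bases
  expect_equal(a$percentile[1], 0)

  # conservation: percentile masses partition the total
  expect_equal(sum(a$length), sum(items$length))
  expect_equal(length(unique(table(a$percentile))), 1)
  expect_error(percentile_discretize(items[0, ]), "no items")
})

test_that("percentile discretization partitions random inputs item-by-item", {
  for (s in 1:10) {
    items <- withr::with_seed(s, tibble::tibble(
      sample_id = sample(c("s1", "s2"), 300, TRUE),
      contig_id = sprintf("c%03d", 1:300),
      genome_id = sample(c("gA", "gB"), 300, TRUE),
      length = sample(500:3000, 300, TRUE),
      distance = stats::runif(300)))
    a <- percentile_discretize(items)
    expect_equal(nrow(a), nrow(items))
    expect_true(all(a$percentile >= 0 & a$percentile <= 99))
    # verbatim midpoint inequality per item
    mid <- a$s_c + a$length / 2
    expect_true(all(a$percentile * a$bases < mid))
    expect_true(all(mid <= (a$percentile + 1) * a$bases))
    # bp conservation and within-(max item) balance per percentile
    expect_equal(sum(a$length), sum(items$length))
    mass <- tapply(a$length, factor(a$percentile, levels = 0:99), sum)
    mass[is.na(mass)] <- 0
    expect_true(all(abs(mass - a$bases[1]) <= max(a$length) + 1e-9))
  }
})

test_that("percentile recall scores correctness against representative bins", {
  items <- tibble::tibble(sample_id = "s", contig_id = paste0("c", 1:4),
                          genome_id = "g", length = c(1000, 1000, 1000, 1000),
                          distance = 1:4)
  a <- percentile_discretize(items)
  bins <- tibble::tibble(contig_id = paste0("c", 1:3),
                         bin_id = c("good", "good", "bad"))  # c4 unbinned
  rep_map <- tibble::tibble(sample_id = "s", genome_id = "g",
                            representative_bin = "good")
  pr <- percentile_recall(a, list(s = bins), rep_map)
  items_flagged <- attr(pr, "items")
  expect_equal(items_flagged$correct[order(items_flagged$contig_id)],
               c(TRUE, TRUE, FALSE, FALSE))
  total <- dplyr::summarise(pr, tp = sum(tp_bp), fn = sum(fn_bp))
  expect_equal(total$tp, 2000)
  expect_equal(total$fn, 2000)

  # all correct -> recall 1 in every populated percentile
  bins_all <- tibble::tibble(contig_id = paste0("c", 1:4), bin_id = "good")
  pr2 <- percentile_recall(a, list(s = bins_all), rep_map)
  expect_true(all(pr2$recall == 1))
})

test_that("planted distance-dependent misbinning yields a decreasing curve", {
  rhos <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 400
      items <- tibble::tibble(
        sample_id = "s", contig_id = sprintf("c%04d", 1:n), genome_id = "g",
        length = sample(800:1200, n, TRUE), distance = stats::runif(n))
      a <- percentile_discretize(items)
      # misbinning probability rises with distance
      bins <- tibble::tibble(contig_id = a$contig_id,
                             bin_id = ifelse(stats::runif(nrow(a)) < a$distance^2,
                                             "wrong", "good"))
      rep_map <- tibble::tibble(sample_id = "s", genome_id = "g",
                                representative_bin = "good")
      pr <- percentile_recall(a, list(s = bins), rep_map)
      sm <- magbench:::rolling_mean(pr$recall[order(pr$percentile)], 9)
      suppressWarnings(stats::cor(seq_along(sm), sm, method = "spearman"))
    })
  }, 0)
  expect_true(sum(rhos < 0) >= 9)
})

test_that("prophage classification implements the three containment rules", {
  prov <- tibble::tibble(genome_id = "g", start = 120, end = 180)
  hit <- function(gs, ge, g = "g") {
    tibble::tibble(genome_id = g, g_start = gs, g_end = ge)
  }
  expect_true(classify_prophage(hit(130, 150), prov))   # inside provirus
  expect_true(classify_prophage(hit(100, 200), prov))   # contains provirus
  prov100 <- tibble::tibble(genome_id = "g", start = 0, end = 100)
  expect_true(classify_prophage(hit(75, 150), prov100))   # overlap 25 of 100
  expect_false(classify_prophage(hit(76, 150), prov100))  # overlap 24
  expect_false(classify_prophage(hit(130, 150, "other"), prov))
  expect_false(classify_prophage(hit(130, 150)[0, ], prov))

  # monotone under contig extension
  for (ext in c(0, 10, 50, 500)) {
    expect_true(classify_prophage(hit(75 - ext, 150 + ext), prov100))
  }
})

test_that("shared classification counts distinct recoverable genomes", {
  hits <- dplyr::bind_rows(
    tibble::tibble(contig_id = "c1", genome_id = c("gA", "gB"),
                   genome_seq_id = c("gA", "gB"), percent_identity = 100,
                   alignment_length = 100, c_start = 0, c_end = 100,
                   g_start = 0, g_end = 100, strand = "+"),
    tibble::tibble(contig_id = "c2", genome_id = c("gA", "gX"),
                   genome_seq_id = c("gA", "gX"), percent_identity = 100,
                   alignment_length = 100, c_start = 0, c_end = 100,
                   g_start = 0, g_end = 100, strand = "+"),
    tibble::tibble(contig_id = "c3", genome_id = c("gA", "gA"),
                   genome_seq_id = c("gA", "gA"), percent_identity = 100,
                   alignment_length = 100, c_start = 0, c_end = 100,
                   g_start = c(0, 500), g_end = c(100, 600), strand = "+"))
  cmap <- structure(list(contig_lengths = c(c1 = 100, c2 = 100, c3 = 100),
                         hits = hits), class = "contig_genome_map")
  recoverable <- c("gA", "gB")
  expect_true(classify_shared("c1", cmap, recoverable))
  expect_false(classify_shared("c2", cmap, recoverable))
  expect_false(classify_shared("c3", cmap, recoverable))
})

test_that("group recall aggregates correct basepairs per group", {
  items <- tibble::tibble(
    genome_id = "g", sample_id = "s",
    length = c(1000, 3000, 2000), correct = c(TRUE, FALSE, TRUE),
    prophage = c(TRUE, TRUE, FALSE), shared = FALSE)
  expect_equal(group_recall(items, "g", "s", "prophage"), 0.25)
  expect_equal(group_recall(items, "g", "s", "all"), 3000 / 6000)
  expect_true(is.na(group_recall(items, "g", "s", "shared")))
})

test_that("the geNomad adapter filters by virus score and parses coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    seq_name = c("gA_s1", "gA_s1", "gB_s1"),
    coordinates = c("121-180", "500-900", "10-20"),
    virus_score = c(0.95, 0.5, 0.92)), path)
  prov <- read_genomad_provirus(path, c(gA_s1 = "gA", gB_s1 = "gB"))
  expect_equal(nrow(prov), 2)
  expect_equal(prov$start, c(120, 9))
  expect_equal(prov$end, c(180, 20))
  expect_equal(prov$genome_id, c("gA", "gB"))
})

test_that("truth-derived coverage and the feature table work end to end", {
  fx <- magbench::generate_collection(magbench::fixture_spec(
    seed = 41, n_species = 2, strains_per_species = 1, genome_length = 15000,
    prophage_plan = tibble::tibble(genome = "sp1_st1", length = 4000,
                                   position = 5000)))
  db <- fx$db
  spec <- tibble::tibble(sample_id = "s", genome_id = c("sp1_st1", "sp2_st1"),
                         relative_abundance = c(0.6, 0.4), source = "x",
                         seed = 1L, num_reads = 800L)
  rs <- simulate_reads(spec, db, seed = 8, write_fastq = FALSE)
  fa <- fragment_assembly(db, mean_len = 1000, loss_fraction = 0, seed = 9)
  cmap <- filter_qualifying(
    oracle_align(fa$contigs, db),
    stats::setNames(Biostrings::width(fa$contigs), names(fa$contigs)))
  cov <- truth_contig_coverage(fa$truth, list(s = rs))
  expect_true(all(cov$mean_depth >= 0))
  prov_iv <- dplyr::mutate(fx$truth$prophage,
                           seq_id = paste0(genome_id, "_c1"))
  feats <- contig_feature_table(cmap, fa$contigs, db, cov,
                                recoverable_genomes = c("sp1_st1", "sp2_st1"),
                                provirus_intervals = prov_iv, sample_id = "s")
  expect_true(nrow(feats) >= nrow(fa$truth))
  expect_true(all(feats$composition_distance >= 0))
  # contigs inside the planted prophage are flagged
  tr1 <- fa$truth[fa$truth$genome_id == "sp1_st1", ]
  inside <- tr1$contig_id[tr1$start >= 5000 & tr1$end <= 9000]
  outside <- tr1$contig_id[tr1$end <= 5000 | tr1$start >= 9000]
  expect_gt(length(inside), 0)
  expect_true(all(feats$prophage[feats$contig_id %in% inside]))
  expect_false(any(feats$prophage[feats$contig_id %in% outside]))
  # GC-shifted prophage contigs sit farther from the genome composition
  pro <- feats$composition_distance[feats$contig_id %in% inside &
                                      feats$genome_id == "sp1_st1"]
  bg <- feats$composition_distance[feats$contig_id %in% outside &
                                     feats$genome_id == "sp1_st1"]
  expect_gt(mean(pro), mean(bg))
})
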