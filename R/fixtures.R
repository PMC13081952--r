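#' Describe a synthetic genome collection
#'
#' The fixture plan for [generate_collection()]: a species/strain-structured
#' collection with optional verbatim shared segments and composition-shifted
#' prophage-like insertions, all seed-deterministic.
#'
#' @param seed Integer seed.
#' @param n_species Number of species clusters.
#' @param strains_per_species Integer vector (recycled) of strains per
#'   species.
#' @param genome_length Ancestral genome length in bp.
#' @param strain_substitution_rate Per-base substitution rate from the
#'   ancestor to each non-first strain.
#' @param gc Background GC content.
#' @param shared_segment_plan Optional tibble with `donor`, `recipient`,
#'   `length` and optionally `donor_start`, `recipient_start` (0-based);
#'   genome names are `sp<i>_st<j>`.
#' @param prophage_plan Optional tibble with `genome`, `length`, `position`
#'   (0-based insertion point); inserted segments have GC elevated by
#'   `prophage_gc_shift`.
#' @param prophage_gc_shift GC shift of prophage segments (default +0.15).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_species = 3L, strains_per_species = 2L,
                         genome_length = 40000L,
                         strain_substitution_rate = 0.01, gc = 0.45,
                         shared_segment_plan = NULL, prophage_plan = NULL,
                         prophage_gc_shift = 0.15) {
  stopifnot(strain_substitution_rate >= 0, strain_substitution_rate <= 1,
            gc > 0, gc < 1, n_species >= 1, genome_length >= 1000)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 strains_per_species = rep_len(as.integer(strains_per_species),
                                               n_species),
                 genome_length = as.integer(genome_length),
                 strain_substitution_rate = strain_substitution_rate, gc = gc,
                 shared_segment_plan = shared_segment_plan,
                 prophage_plan = prophage_plan,
                 prophage_gc_shift = prophage_gc_shift),
            class = "fixture_spec")
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_sequence <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, NULL)[[1]]
  n_mut <- stats::rbinom(1, length(chars), rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(length(chars), n_mut)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  pick <- sample.int(3, n_mut, replace = TRUE)
  chars[pos] <- substr(alt[chars[pos]], pick, pick)
  paste(chars, collapse = "")
}

#' Generate a synthetic genome collection with planted structure
#'
#' Ancestral genomes are drawn i.i.d. per species; strains are derived at the
#' substitution rate (the first strain of each species is the untouched
#' ancestor, flagged as the isolate and species representative). Shared
#' segments are then copied verbatim donor -> recipient, and prophage-like
#' segments with elevated GC are inserted, with every planted interval
#' recorded in the truth tables.
#'
#' @param fspec A [fixture_spec()].
#' @return List with `db` (a `reference_db`, strain clusters labelled from
#'   the construction) and `truth` (list of tibbles: `genomes`, `shared`,
#'   `prophage`; intervals 0-based half-open on the final genomes).
#' @export
generate_collection <- function(fspec) {
  with_seed(fspec$seed, {
    seqs <- list(); meta <- list()
    for (i in seq_len(fspec$n_species)) {
      ancestor <- random_dna(fspec$genome_length, fspec$gc)
      for (j in seq_len(fspec$strains_per_species[i])) {
        gid <- sprintf("sp%d_st%d", i, j)
        s <- if (j == 1) ancestor else
          mutate_sequence(ancestor, fspec$strain_substitution_rate)
        seqs[[gid]] <- s
        meta[[gid]] <- tibble::tibble(
          genome_id = gid, is_isolate = j == 1,
          species_cluster_id = sprintf("sp%d", i),
          is_species_representative = j == 1,
          strain_cluster_id = sprintf("sp%d.fix%d", i, j))
      }
    }
    shared_truth <- tibble::tibble()
    if (!is.null(fspec$shared_segment_plan)) {
      plan <- fspec$shared_segment_plan
      for (r in seq_len(nrow(plan))) {
        don <- plan$donor[r]; rec <- plan$recipient[r]; len <- plan$length[r]
        ds <- if ("donor_start" %in% names(plan)) plan$donor_start[r] else
          sample.int(nchar(seqs[[don]]) - len, 1) - 1L
        rs <- if ("recipient_start" %in% names(plan)) plan$recipient_start[r] else
          sample.int(nchar(seqs[[rec]]) - len, 1) - 1L
        segment <- substr(seqs[[don]], ds + 1L, ds + len)
        substr(seqs[[rec]], rs + 1L, rs + len) <- segment
        shared_truth <- dplyr::bind_rows(shared_truth, tibble::tibble(
          donor = don, recipient = rec, length = len,
          donor_start = ds, donor_end = ds + len,
          recipient_start = rs, recipient_end = rs + len))
      }
    }
    prophage_truth <- tibble::tibble()
    if (!is.null(fspec$prophage_plan)) {
      plan <- dplyr::arrange(fspec$prophage_plan, .data$genome,
                             dplyr::desc(.data$position))
      for (g in unique(plan$genome)) {
        pg <- plan[plan$genome == g, ]
        if (nrow(pg) > 1) {
          iv <- pg[order(pg$position), ]
          if (any(iv$position[-1] < iv$position[-nrow(iv)] + iv$length[-nrow(iv)])) {
            stop("overlapping planned prophage insertions in ", g)
          }
        }
      }
      for (r in seq_len(nrow(plan))) {
        g <- plan$genome[r]; len <- plan$length[r]; pos <- plan$position[r]
        stopifnot(pos >= 0, pos <= nchar(seqs[[g]]))
        segment <- random_dna(len, min(0.95, fspec$gc + fspec$prophage_gc_shift))
        seqs[[g]] <- paste0(substr(seqs[[g]], 1, pos), segment,
                            substr(seqs[[g]], pos + 1L, nchar(seqs[[g]])))
        prophage_truth <- dplyr::bind_rows(prophage_truth, tibble::tibble(
          genome_id = g, start = pos, end = pos + len))
      }
      # positions were processed high-to-low per genome, so earlier-recorded
      # (higher) intervals are unaffected by later insertions
    }
    genomes <- dplyr::bind_rows(meta)
    dna <- lapply(names(seqs), function(g) {
      ss <- Biostrings::DNAStringSet(seqs[[g]])
      names(ss) <- paste0(g, "_c1")
      ss
    })
    names(dna) <- names(seqs)
    genomes$fasta_path <- NA_character_
    genomes$total_length <- unname(vapply(dna, function(s) sum(Biostrings::width(s)), 0))
    genomes$n50 <- unname(vapply(dna, function(s) n50(Biostrings::width(s)), 0))
    db <- new_reference_db(genomes, dna)
    list(db = db,
         truth = list(genomes = genomes[, c("genome_id", "species_cluster_id",
                                            "strain_cluster_id", "is_isolate")],
                      shared = shared_truth, prophage = prophage_truth))
  })
}

#' Write a collection to FASTA files plus a metadata TSV
#'
#' @param db A `reference_db`.
#' @param dir Output directory.
#' @return Path of the metadata TSV.
#' @export
write_collection <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(db$genomes$genome_id, function(g) {
    p <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(genome_sequences(db, g), p)
    p
  }, "")
  meta <- dplyr::mutate(
    dplyr::select(db$genomes, "genome_id", "is_isolate", "species_cluster_id",
                  "is_species_representative"),
    fasta_path = unname(paths),
    is_isolate = as.integer(.data$is_isolate),
    is_species_representative = as.integer(.data$is_species_representative))
  meta_path <- file.path(dir, "genomes.tsv")
  readr::write_tsv(meta[, c("genome_id", "fasta_path", "is_isolate",
                            "species_cluster_id", "is_species_representative")],
                   meta_path)
  meta_path
}

#' Fragment genomes into an assembly-like contig set
#'
#' Each genome sequence is cut at seeded breakpoints into contigs with
#' roughly geometric lengths around `mean_len`; a seeded subset of contigs
#' covering approximately `loss_fraction` of the bases is withheld to mimic
#' unassembled regions. Contigs are exact substrings of the genomes.
#'
#' @param db A `reference_db` (or named list of `DNAStringSet`).
#' @param mean_len Mean contig length (>= 500 bp).
#' @param loss_fraction Fraction of bases withheld, in `[0, 1)`.
#' @param seed Integer seed.
#' @param min_len Minimum contig length (shorter trailing pieces merge into
#'   the previous contig).
#' @return List with `contigs` (named `DNAStringSet`) and `truth` (tibble:
#'   `contig_id`, `genome_id`, `seq_id`, `start`, `end`, `length`,
#'   0-based half-open source intervals of retained contigs).
#' @export
fragment_assembly <- function(db, mean_len = 2000L, loss_fraction = 0,
                              seed = 1L, min_len = 500L) {
  stopifnot(mean_len >= 500, loss_fraction >= 0, loss_fraction < 1)
  seqs <- if (inherits(db, "reference_db")) db$sequences else db
  with_seed(seed, {
    truth <- list(); contig_seqs <- character(0)
    for (gid in names(seqs)) {
      for (si in seq_along(seqs[[gid]])) {
        s <- as.character(seqs[[gid]][[si]])
        sid <- names(seqs[[gid]])[si]
        L <- nchar(s); pos <- 0L; k <- 0L
        while (pos < L) {
          len <- min_len + stats::rgeom(1, 1 / (mean_len - min_len))
          if (pos + len > L || L - (pos + len) < min_len) len <- L - pos
          k <- k + 1L
          cid <- sprintf("%s_ctg%03d", sid, k)
          contig_seqs[cid] <- substr(s, pos + 1L, pos + len)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            contig_id = cid, genome_id = gid, seq_id = sid,
            start = pos, end = pos + len, length = len)
          pos <- pos + len
        }
      }
    }
    truth <- dplyr::bind_rows(truth)
    if (loss_fraction > 0) {
      ord <- sample.int(nrow(truth))
      cum <- cumsum(truth$length[ord])
      drop_idx <- ord[cum <= loss_fraction * sum(truth$length)]
      # drop at least one contig if any loss was requested
      if (length(drop_idx) == 0) drop_idx <- ord[1]
      truth <- truth[-drop_idx, ]
      contig_seqs <- contig_seqs[truth$contig_id]
    }
    contigs <- Biostrings::DNAStringSet(contig_seqs)
    names(contigs) <- names(contig_seqs)
    list(contigs = contigs, truth = truth)
  })
}

#' Build oracle or corrupted bin tables from a fragmentation truth map
#'
#' Oracle mode bins contigs by source genome. Corrupted mode starts from the
#' oracle and reassigns a seeded subset of contigs covering approximately
#' `swap_fraction` of the bases to a random other bin, then unbins a subset
#' covering approximately `drop_fraction`.
#'
#' @param truth Fragmentation truth tibble from [fragment_assembly()].
#' @param mode `"oracle"` or `"corrupted"`.
#' @param swap_fraction,drop_fraction Corruption levels in `[0, 1]`.
#' @param seed Integer seed (corrupted mode).
#' @return Bin table tibble (`contig_id`, `bin_id`).
#' @export
make_bins <- function(truth, mode = c("oracle", "corrupted"),
                      swap_fraction = 0, drop_fraction = 0, seed = 1L) {
  mode <- match.arg(mode)
  bins <- tibble::tibble(contig_id = truth$contig_id,
                         bin_id = paste0("bin_", truth$genome_id))
  if (mode == "oracle") return(bins)
  with_seed(seed, {
    all_bins <- unique(bins$bin_id)
    total <- sum(truth$length)
    ord <- sample.int(nrow(bins))
    cum <- cumsum(truth$length[ord])
    swap_idx <- ord[cum <= swap_fraction * total]
    rest <- setdiff(ord, swap_idx)
    cum2 <- cumsum(truth$length[rest])
    drop_idx <- rest[cum2 <= drop_fraction * total]
    for (i in swap_idx) {
      others <- setdiff(all_bins, bins$bin_id[i])
      if (length(others) > 0) bins$bin_id[i] <- sample(others, 1)
    }
    if (length(drop_idx) > 0) bins <- bins[-drop_idx, ]
    bins
  })
}

#' Emit synthetic CheckM2- and GUNC-dialect quality tables
#'
#' Completeness is `100 * recall` plus optional bias and Normal noise
#' (clamped to `[0, 100]`); contamination is `100 * (1 - precision)` plus
#' bias and noise (clamped at 0). The GUNC pass flag is
#' `true contamination < gunc_threshold`, flipped at a seeded error rate.
#' These are synthetic stand-ins emulating external QC reports for testing
#' the adapters and filters.
#'
#' @param evals Evaluation tibble (one representative bin per row).
#' @param completeness_bias,contamination_bias Additive bias in percent.
#' @param noise_sd Normal noise sd in percent.
#' @param gunc_threshold Contamination percent above which GUNC flags a bin.
#' @param flip_rate Probability of flipping the GUNC flag.
#' @param seed Integer seed.
#' @return List with `checkm2` and `gunc` tibbles in the adapters' dialects
#'   (`Name`/`Completeness`/`Contamination` and `genome`/`pass.GUNC`).
#' @export
make_quality_tables <- function(evals, completeness_bias = 0,
                                contamination_bias = 0, noise_sd = 0,
                                gunc_threshold = 10, flip_rate = 0, seed = 1L) {
  ev <- evals[!is.na(evals$representative_bin), ]
  ev <- ev[!duplicated(ev$representative_bin), ]
  with_seed(seed, {
    n <- nrow(ev)
    comp <- pmin(100, pmax(0, 100 * ev$recall + completeness_bias +
                             stats::rnorm(n, 0, noise_sd)))
    cont <- pmax(0, 100 * (1 - ev$precision) + contamination_bias +
                   stats::rnorm(n, 0, noise_sd))
    pass <- (100 * (1 - ev$precision)) < gunc_threshold
    flip <- stats::runif(n) < flip_rate
    list(checkm2 = tibble::tibble(Name = ev$representative_bin,
                                  Completeness = comp, Contamination = cont),
         gunc = tibble::tibble(genome = ev$representative_bin,
                               `pass.GUNC` = xor(pass, flip)))
  })
}
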