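#' Build the two-level reference database from a genome collection
#'
#' Reads a genome metadata table plus the multi-FASTA file of each genome and
#' assembles the reference database the simulator draws from. Genomes arrive
#' preclustered at the species level (95% ANI, one flagged representative per
#' cluster); strain-level clusters (98% ANI) are assigned later by
#' [cluster_strains()].
#'
#' @param metadata A data frame (or path to a TSV) with columns `genome_id`,
#'   `fasta_path`, `is_isolate` (0/1 or logical), `species_cluster_id`,
#'   `is_species_representative` (0/1 or logical).
#' @param genome_dir Optional directory prepended to relative `fasta_path`s.
#'
#' @return A `reference_db`: a list with `genomes` (a tibble, one row per
#'   genome, with `total_length` and `n50` computed and `strain_cluster_id`
#'   set to `NA` until [cluster_strains()] runs) and `sequences` (a named list
#'   of [Biostrings::DNAStringSet], one per genome).
#' @export
load_genome_collection <- function(metadata, genome_dir = NULL) {
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  req <- c("genome_id", "fasta_path", "is_isolate", "species_cluster_id",
           "is_species_representative")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    stop("genome metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  meta <- tibble::as_tibble(metadata)
  if (anyDuplicated(meta$genome_id)) stop("duplicate genome_id in metadata")
  meta$is_isolate <- as.logical(as.integer(meta$is_isolate))
  meta$is_species_representative <- as.logical(as.integer(meta$is_species_representative))

  seqs <- vector("list", nrow(meta))
  names(seqs) <- meta$genome_id
  for (i in seq_len(nrow(meta))) {
    path <- meta$fasta_path[i]
    if (!is.null(genome_dir)) path <- file.path(genome_dir, path)
    if (!file.exists(path)) {
      stop("FASTA for genome '", meta$genome_id[i], "' not found: ", path)
    }
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L || any(Biostrings::width(ss) == 0L)) {
      stop("genome '", meta$genome_id[i], "' has an empty sequence")
    }
    names(ss) <- sub("\\s.*$", "", names(ss))
    seqs[[i]] <- ss
  }

  genomes <- dplyr::mutate(
    meta,
    total_length = unname(vapply(seqs, function(s) sum(Biostrings::width(s)), 0)),
    n50 = unname(vapply(seqs, function(s) n50(Biostrings::width(s)), 0)),
    strain_cluster_id = NA_character_
  )
  db <- new_reference_db(genomes, seqs)
  validate_species_clusters(db)
  db
}

new_reference_db <- function(genomes, sequences) {
  structure(list(genomes = tibble::as_tibble(genomes), sequences = sequences),
            class = "reference_db")
}

validate_species_clusters <- function(db) {
  reps <- dplyr::summarise(
    dplyr::group_by(db$genomes, .data$species_cluster_id),
    n_rep = sum(.data$is_species_representative), .groups = "drop"
  )
  bad <- reps[reps$n_rep != 1L, ]
  if (nrow(bad) > 0) {
    stop("species cluster(s) without exactly one representative: ",
         paste(bad$species_cluster_id, collapse = ", "))
  }
  invisible(db)
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x$genomes), " genomes, ",
      dplyr::n_distinct(x$genomes$species_cluster_id), " species clusters, ",
      if (all(is.na(x$genomes$strain_cluster_id))) "strains unclustered"
      else paste0(dplyr::n_distinct(x$genomes$strain_cluster_id), " strain clusters"),
      "\n", sep = "")
  invisible(x)
}

genome_sequences <- function(db, genome_id) {
  s <- db$sequences[[genome_id]]
  if (is.null(s)) stop("unknown genome_id: ", genome_id)
  s
}

#' N50 of a set of sequence lengths
#'
#' Length at which the cumulative sum of descending-sorted lengths first
#' reaches half the total.
#'
#' @param lengths Integer or numeric vector of sequence lengths.
#' @return The N50 in basepairs.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1]]
}

#' Containment-based ANI estimate between two genomes
#'
#' Estimates average nucleotide identity from canonical k-mer sets: with
#' containment `c = |K_a intersect K_b| / min(|K_a|, |K_b|)`, the estimate is
#' `100 * (1 + ln(2c / (1 + c)) / k)`, clamped to `[0, 100]`; `c = 0` yields 0.
#' This is the built-in desk-scale estimator used when no externally computed
#' pairwise-ANI table is supplied to [cluster_strains()].
#'
#' @param a,b Character vectors of DNA sequences (or `DNAStringSet`s), one
#'   genome each.
#' @param k K-mer size (default 21).
#' @return ANI percent in `[0, 100]`.
#' @export
estimate_ani <- function(a, b, k = 21L) {
  ka <- canonical_kmer_set(a, k)
  kb <- canonical_kmer_set(b, k)
  if (length(ka) == 0L || length(kb) == 0L) {
    stop("sequence shorter than k: no valid ", k, "-mers")
  }
  kmer_set_ani(ka, kb, k)
}

kmer_set_ani <- function(ka, kb, k) {
  cont <- sum(ka %in% kb) / min(length(ka), length(kb))
  if (cont == 0) return(0)
  max(0, min(100, 100 * (1 + log(2 * cont / (1 + cont)) / k)))
}

#' Assign strain clusters within each species cluster
#'
#' Greedy seed-based agglomeration at 98% ANI: within each species cluster,
#' genomes are taken in descending `total_length` order (ties broken by
#' `genome_id`); each genome joins the first existing strain cluster whose
#' seed genome has ANI >= `ani_cutoff` with it, otherwise it seeds a new
#' cluster. Singleton species clusters become singleton strain clusters.
#'
#' @param db A `reference_db` from [load_genome_collection()].
#' @param ani_table Optional data frame (or TSV path) of externally computed
#'   pairwise ANI with columns `genome_a`, `genome_b`, `ani_percent` (e.g.
#'   parsed dRep output); used verbatim when given, otherwise [estimate_ani()]
#'   is called on within-species pairs.
#' @param ani_cutoff Strain cluster ANI threshold in percent (default 98).
#' @param k K-mer size for the built-in estimator.
#' @return The `reference_db` with `strain_cluster_id` filled in.
#' @export
cluster_strains <- function(db, ani_table = NULL, ani_cutoff = 98, k = 21L) {
  if (!is.null(ani_table)) {
    if (is.character(ani_table) && length(ani_table) == 1L) {
      ani_table <- readr::read_tsv(ani_table, show_col_types = FALSE)
    }
    unknown <- setdiff(unique(c(ani_table$genome_a, ani_table$genome_b)),
                       db$genomes$genome_id)
    if (length(unknown) > 0) {
      stop("ani_table references unknown genome_id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  pair_ani <- function(ga, gb) {
    if (!is.null(ani_table)) {
      hit <- ani_table[(ani_table$genome_a == ga & ani_table$genome_b == gb) |
                       (ani_table$genome_a == gb & ani_table$genome_b == ga), ]
      if (nrow(hit) == 0) return(0)
      return(max(hit$ani_percent))
    }
    estimate_ani(genome_sequences(db, ga), genome_sequences(db, gb), k = k)
  }

  g <- db$genomes
  g$strain_cluster_id <- NA_character_
  for (sp in unique(g$species_cluster_id)) {
    idx <- which(g$species_cluster_id == sp)
    ord <- idx[order(-g$total_length[idx], g$genome_id[idx])]
    seeds <- character(0)
    for (i in ord) {
      gid <- g$genome_id[i]
      joined <- FALSE
      for (ci in seq_along(seeds)) {
        if (pair_ani(seeds[ci], gid) >= ani_cutoff) {
          g$strain_cluster_id[i] <- paste0(sp, ".s", ci)
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        seeds <- c(seeds, gid)
        g$strain_cluster_id[i] <- paste0(sp, ".s", length(seeds))
      }
    }
  }
  db$genomes <- g
  db
}
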