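#' Gate query rows into potential strain genomes
#'
#' A genome of the species cluster is a potential strain genome when its
#' effective k-mer coverage token is not `"LOW"`, its coverage-adjusted ANI is
#' at least `ani_gate`, and — unless coverage is `"HIGH"` — the lower bound of
#' the ANI confidence interval is at least `ci_gate`.
#'
#' @param query_rows Query tibble (see [parse_query_table()]).
#' @param db A `reference_db` with strain clusters assigned.
#' @param species_cluster_id The species cluster to gate within.
#' @param ani_gate,ci_gate Gate thresholds in percent (defaults 99.8 / 99.5).
#' @return A tibble of candidates (`genome_id`, `strain_cluster_id`,
#'   `adjusted_ani`, `ani_ci_lower`, `eff_lambda_token`, `is_isolate`, `n50`),
#'   possibly empty.
#' @export
select_strain_candidates <- function(query_rows, db, species_cluster_id,
                                     ani_gate = 99.8, ci_gate = 99.5) {
  members <- dplyr::filter(db$genomes, .data$species_cluster_id == !!species_cluster_id)
  rows <- dplyr::inner_join(query_rows, members, by = "genome_id")
  passes <- !is.na(rows$eff_lambda_token) & rows$eff_lambda_token != "LOW" &
    !is.na(rows$adjusted_ani) & rows$adjusted_ani >= ani_gate &
    (rows$eff_lambda_token == "HIGH" |
       (!is.na(rows$ani_ci_lower) & rows$ani_ci_lower >= ci_gate))
  dplyr::select(rows[passes, ], "genome_id", "strain_cluster_id",
                "adjusted_ani", "ani_ci_lower", "eff_lambda_token",
                "is_isolate", "n50")
}

#' Pick the representative genome of one strain cluster
#'
#' Isolates are prioritized over MAGs; among equals, higher N50, then higher
#' adjusted ANI, then lexicographically smaller genome id.
#'
#' @param candidates Candidate tibble restricted to one strain cluster.
#' @return The chosen `genome_id`.
#' @export
pick_strain_representative <- function(candidates) {
  if (nrow(candidates) == 0) stop("no candidates to pick a strain representative from")
  ord <- order(-candidates$is_isolate, -candidates$n50,
               -candidates$adjusted_ani, candidates$genome_id)
  candidates$genome_id[ord[1]]
}

#' Cap the number of strain clusters per species at three
#'
#' When more than `max_strains` strain clusters pass the gate, `max_strains`
#' are chosen uniformly at random (consuming the current RNG stream, which
#' [build_specification()] seeds per sample); otherwise the input is returned
#' unchanged, order preserved.
#'
#' @param cluster_ids Character vector of strain cluster ids.
#' @param max_strains Cap (default 3).
#' @return Character vector of at most `max_strains` ids.
#' @export
cap_strain_clusters <- function(cluster_ids, max_strains = 3L) {
  if (length(cluster_ids) <= max_strains) return(cluster_ids)
  sample(cluster_ids, max_strains)
}

#' Split a species abundance across its selected strains
#'
#' Each strain receives the species abundance multiplied by `d_i / S`, where
#' `d_i ~ logNormal(mu = 1, sigma = 2)` (i.e. `exp` of a Normal with mean 1
#' and sd 2 on the log scale) and `S` is the sum of the draws. A single strain
#' receives the species abundance exactly.
#'
#' @param species_abundance Nonnegative fraction.
#' @param n_strains Number of selected strains (>= 1).
#' @param meanlog,sdlog logNormal parameters on the log scale.
#' @return Numeric vector of length `n_strains` summing to
#'   `species_abundance`.
#' @export
assign_strain_abundances <- function(species_abundance, n_strains,
                                     meanlog = 1, sdlog = 2) {
  if (n_strains < 1) stop("n_strains must be >= 1")
  stopifnot(species_abundance >= 0)
  d <- stats::rlnorm(n_strains, meanlog = meanlog, sdlog = sdlog)
  species_abundance * d / sum(d)
}

#' Species-level fallback representative
#'
#' When no genome of a profiled species passes the strain gate, one genome of
#' the species cluster is selected, prioritizing isolates, then adjusted ANI,
#' then N50 (genomes absent from the query table rank as ANI `-Inf`), ties by
#' genome id.
#'
#' @inheritParams select_strain_candidates
#' @return The chosen `genome_id`.
#' @export
fallback_species_representative <- function(query_rows, db, species_cluster_id) {
  members <- dplyr::filter(db$genomes, .data$species_cluster_id == !!species_cluster_id)
  if (nrow(members) == 0) stop("empty species cluster: ", species_cluster_id)
  rows <- dplyr::left_join(members, query_rows, by = "genome_id")
  ani <- ifelse(is.na(rows$adjusted_ani), -Inf, rows$adjusted_ani)
  ord <- order(-rows$is_isolate, -ani, -rows$n50, rows$genome_id)
  rows$genome_id[ord[1]]
}

#' Build the mirror specification of a sample
#'
#' Converts a sample's species profile and per-genome query report into the
#' ground-truth genome set and abundances of its simulated mirror. For each
#' profiled species: gate candidates ([select_strain_candidates()]), group by
#' strain cluster, cap at `max_strains` clusters ([cap_strain_clusters()]),
#' pick one genome per cluster ([pick_strain_representative()]), and split the
#' species abundance ([assign_strain_abundances()]); species with no passing
#' candidate contribute a single fallback genome
#' ([fallback_species_representative()]) at the species abundance. Entry
#' abundances are finally renormalized to sum to 1.
#'
#' @param profile Profile tibble keyed by species representative id.
#' @param query Query tibble.
#' @param db A `reference_db` with strain clusters assigned.
#' @param num_reads Total read count of the mirrored sample.
#' @param seed Integer seed; all randomness of the specification (cluster
#'   capping, abundance splitting) derives from it.
#' @param sample_id Sample label recorded in the specification.
#' @param ani_gate,ci_gate,max_strains Gate thresholds and strain-cluster cap.
#' @return A tibble (the specification manifest) with columns `sample_id`,
#'   `genome_id`, `relative_abundance`, `source` (`"strain_evidence"` or
#'   `"species_fallback"`), `seed`, `num_reads`.
#' @export
build_specification <- function(profile, query, db, num_reads, seed,
                                sample_id = "sample", ani_gate = 99.8,
                                ci_gate = 99.5, max_strains = 3L) {
  rep_to_species <- db$genomes$species_cluster_id[db$genomes$is_species_representative]
  names(rep_to_species) <- db$genomes$genome_id[db$genomes$is_species_representative]
  unknown <- setdiff(profile$species_representative_id, names(rep_to_species))
  if (length(unknown) > 0) {
    stop("profiled species absent from the reference database: ",
         paste(unknown, collapse = ", "))
  }
  if (any(is.na(db$genomes$strain_cluster_id))) {
    stop("strain clusters are unassigned; run cluster_strains() first")
  }
  entries <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(profile)), function(i) {
      sp <- unname(rep_to_species[profile$species_representative_id[i]])
      ab <- profile$relative_abundance[i]
      cand <- select_strain_candidates(query, db, sp,
                                       ani_gate = ani_gate, ci_gate = ci_gate)
      if (nrow(cand) == 0) {
        gid <- fallback_species_representative(query, db, sp)
        return(tibble::tibble(genome_id = gid, relative_abundance = ab,
                              source = "species_fallback"))
      }
      clusters <- sort(unique(cand$strain_cluster_id))
      clusters <- cap_strain_clusters(clusters, max_strains = max_strains)
      picks <- vapply(clusters, function(cl) {
        pick_strain_representative(cand[cand$strain_cluster_id == cl, ])
      }, character(1))
      tibble::tibble(genome_id = unname(picks),
                     relative_abundance = assign_strain_abundances(ab, length(picks)),
                     source = "strain_evidence")
    })
  })
  if (nrow(entries) == 0) stop("empty profile: no specification entries")
  if (anyDuplicated(entries$genome_id)) {
    stop("internal error: duplicate genome in specification")
  }
  entries$relative_abundance <- entries$relative_abundance / sum(entries$relative_abundance)
  tibble::tibble(sample_id = sample_id, genome_id = entries$genome_id,
                 relative_abundance = entries$relative_abundance,
                 source = entries$source, seed = as.integer(seed),
                 num_reads = as.integer(num_reads))
}

#' Read / write a specification manifest TSV
#'
#' The manifest is the ground truth consumed by the read simulator and the
#' evaluator: one row per genome with columns `sample_id`, `genome_id`,
#' `relative_abundance`, `source`, `seed`, `num_reads`.
#'
#' @param spec Specification tibble.
#' @param path TSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_specification <- function(spec, path) {
  readr::write_tsv(spec, path)
  invisible(path)
}

#' @rdname write_specification
#' @export
read_specification <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), genome_id = readr::col_character(),
    relative_abundance = readr::col_double(), source = readr::col_character(),
    seed = readr::col_integer(), num_reads = readr::col_integer()))
}
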