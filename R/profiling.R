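#' Column dialect for profiler report tables
#'
#' Profiler report column names are pinned in one descriptor rather than
#' hard-coded in parse logic, since they drift between tool versions. The
#' defaults follow the Sylph tabular dialect: `profile` tables carry a genome
#' name and a relative taxonomic abundance in percent; `query` tables carry a
#' coverage-adjusted ANI, its percentile confidence interval (formatted
#' `"lo-hi"`), and an effective k-mer coverage token (`"LOW"`, `"HIGH"`, or a
#' number).
#'
#' @param profile_genome,profile_abundance,query_genome,query_ani,query_ci,query_lambda
#'   Column names.
#' @param abundance_percent Is the profile abundance column in percent?
#' @return A named list describing the dialect.
#' @export
sylph_dialect <- function(profile_genome = "Genome_file",
                          profile_abundance = "Taxonomic_abundance",
                          abundance_percent = TRUE,
                          query_genome = "Genome_file",
                          query_ani = "Adjusted_ANI",
                          query_ci = "ANI_5-95_percentile",
                          query_lambda = "Eff_lambda") {
  list(profile_genome = profile_genome,
       profile_abundance = profile_abundance,
       abundance_percent = abundance_percent,
       query_genome = query_genome,
       query_ani = query_ani,
       query_ci = query_ci,
       query_lambda = query_lambda)
}

read_tsv_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

require_columns <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
}

#' Parse a species-level profile table
#'
#' @param path TSV path (header-driven, per `dialect`).
#' @param id_map Optional named character vector mapping the genome-name
#'   column onto species representative ids; unnamed entries pass through.
#' @param dialect A [sylph_dialect()] descriptor.
#' @return A tibble with `species_representative_id` and `relative_abundance`
#'   (fraction); zero-abundance rows are dropped.
#' @export
parse_profile_table <- function(path, id_map = NULL, dialect = sylph_dialect()) {
  tab <- read_tsv_chr(path)
  if (nrow(tab) == 0) {
    return(tibble::tibble(species_representative_id = character(0),
                          relative_abundance = numeric(0)))
  }
  require_columns(tab, c(dialect$profile_genome, dialect$profile_abundance),
                  "profile table")
  ab_raw <- tab[[dialect$profile_abundance]]
  ab <- suppressWarnings(as.numeric(ab_raw))
  bad <- which(is.na(ab) & !is.na(ab_raw))
  if (length(bad) > 0) {
    stop("non-numeric abundance in profile table at data line ", bad[1],
         ": '", ab_raw[bad[1]], "'")
  }
  if (dialect$abundance_percent) ab <- ab / 100
  ids <- tab[[dialect$profile_genome]]
  if (!is.null(id_map)) {
    mapped <- unname(id_map[ids])
    ids <- ifelse(is.na(mapped), ids, mapped)
  }
  out <- tibble::tibble(species_representative_id = ids, relative_abundance = ab)
  dplyr::filter(out, .data$relative_abundance > 0)
}

#' Parse a per-genome query table
#'
#' @inheritParams parse_profile_table
#' @return A tibble with `genome_id`, `adjusted_ani`, `ani_ci_lower`
#'   (lower bound of the ANI confidence interval) and `eff_lambda_token`
#'   (preserved verbatim). Blank ANI/CI fields become `NA`.
#' @export
parse_query_table <- function(path, dialect = sylph_dialect()) {
  tab <- read_tsv_chr(path)
  if (nrow(tab) == 0) {
    return(tibble::tibble(genome_id = character(0), adjusted_ani = numeric(0),
                          ani_ci_lower = numeric(0), eff_lambda_token = character(0)))
  }
  require_columns(tab, c(dialect$query_genome, dialect$query_ani,
                         dialect$query_ci, dialect$query_lambda),
                  "query table")
  ids <- tab[[dialect$query_genome]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate genome_id in query table: ", paste(unique(dup), collapse = ", "))
  }
  parse_num <- function(x) suppressWarnings(as.numeric(x))
  ani <- parse_num(tab[[dialect$query_ani]])
  ci_raw <- tab[[dialect$query_ci]]
  ci_lower <- rep(NA_real_, length(ci_raw))
  nonblank <- !is.na(ci_raw) & nzchar(trimws(ci_raw)) & trimws(ci_raw) != "NA"
  if (any(nonblank)) {
    lo <- sub("^([0-9.]+).*$", "\\1", trimws(ci_raw[nonblank]))
    lo_num <- parse_num(lo)
    if (anyNA(lo_num)) {
      bad <- which(nonblank)[which(is.na(lo_num))[1]]
      stop("unparseable ANI confidence interval at data line ", bad,
           ": '", ci_raw[bad], "'")
    }
    ci_lower[nonblank] <- lo_num
  }
  tibble::tibble(genome_id = ids, adjusted_ani = ani, ani_ci_lower = ci_lower,
                 eff_lambda_token = as.character(tab[[dialect$query_lambda]]))
}

#' Write profile / query tables in the pinned dialect
#'
#' Inverse of the parsers, used for round-tripping fixtures through the
#' tabular interfaces.
#'
#' @param profile,query Tibbles as returned by the parsers.
#' @param path Output TSV path.
#' @param dialect A [sylph_dialect()] descriptor.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path, dialect = sylph_dialect()) {
  ab <- profile$relative_abundance
  if (dialect$abundance_percent) ab <- ab * 100
  out <- tibble::tibble(a = profile$species_representative_id, b = ab)
  names(out) <- c(dialect$profile_genome, dialect$profile_abundance)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_profile_table
#' @export
write_query_table <- function(query, path, dialect = sylph_dialect()) {
  ci <- ifelse(is.na(query$ani_ci_lower), "",
               paste0(query$ani_ci_lower, "-", pmin(100, query$adjusted_ani)))
  out <- tibble::tibble(a = query$genome_id,
                        b = ifelse(is.na(query$adjusted_ani), "", query$adjusted_ani),
                        c = ci, d = query$eff_lambda_token)
  names(out) <- c(dialect$query_genome, dialect$query_ani, dialect$query_ci,
                  dialect$query_lambda)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Built-in desk-scale profiler
#'
#' A k-mer containment profiler used so the simulator can be exercised without
#' an external profiler. Species abundances are estimated by assigning each
#' read to the species representative with the highest canonical k-mer
#' containment and renormalizing the read counts. Per-genome adjusted ANI is
#' estimated from the containment of each genome's k-mer set in the pooled
#' read k-mer set; the effective-coverage token is `"LOW"` when fewer than
#' `read_floor` reads match the genome, `"HIGH"` at `>= 10 * read_floor`, and
#' the numeric fold-coverage estimate otherwise.
#'
#' @param reads Character vector of read sequences, a `DNAStringSet`, or
#'   FASTQ path(s).
#' @param db A `reference_db`.
#' @param k K-mer size.
#' @param read_floor Matched-read floor for the coverage token.
#' @param min_read_containment Fraction of a genome's k-mers a read must share
#'   to count as matching that genome.
#' @return A list with `profile` and `query` tibbles (the parsers' shapes).
#'   If no read matches any representative the profile is empty and a warning
#'   is recorded in the `warnings` element.
#' @export
builtin_profile <- function(reads, db, k = 21L, read_floor = 20L,
                            min_read_containment = 0.5) {
  reads <- load_reads(reads)
  if (length(reads) == 0L) stop("no reads supplied")
  mean_read_len <- mean(nchar(reads))

  # one pass over the concatenated reads; map each valid k-mer window back to
  # its read of origin
  L <- nchar(reads)
  concat <- paste(reads, collapse = "N")
  codes <- base_codes(concat)
  fwd <- stats::filter(codes, 4^(0:(k - 1L)), sides = 1)
  rev <- stats::filter(3 - codes, 4^((k - 1L):0), sides = 1)
  v_at_start <- c(pmin(as.numeric(fwd), as.numeric(rev))[k:length(codes)],
                  rep(NA_real_, k - 1L))
  off <- cumsum(c(0, L + 1L))[seq_along(L)]
  nwin <- pmax(0L, L - k + 1L)
  starts <- rep(off + 1, nwin) + sequence(nwin) - 1
  ridx <- rep(seq_along(L), nwin)
  vv <- v_at_start[starts]
  keep <- !is.na(vv)
  vv <- vv[keep]
  ridx <- ridx[keep]
  n_valid <- tabulate(ridx, nbins = length(reads))

  reps <- dplyr::filter(db$genomes, .data$is_species_representative)
  reps <- dplyr::arrange(reps, .data$genome_id)
  rep_sets <- lapply(reps$genome_id,
                     function(g) canonical_kmer_set(genome_sequences(db, g), k))
  cont <- matrix(0, nrow = length(reads), ncol = nrow(reps))
  for (j in seq_len(nrow(reps))) {
    m <- vv %in% rep_sets[[j]]
    cont[, j] <- ifelse(n_valid > 0, tabulate(ridx[m], nbins = length(reads)) / n_valid, 0)
  }
  best <- max.col(cont, ties.method = "first")
  best_cont <- cont[cbind(seq_len(nrow(cont)), best)]
  assigned <- best_cont > 0
  warnings <- character(0)
  if (!any(assigned)) {
    warnings <- "no read matched any species representative"
    profile <- tibble::tibble(species_representative_id = character(0),
                              relative_abundance = numeric(0))
  } else {
    counts <- tabulate(best[assigned], nbins = nrow(reps))
    profile <- tibble::tibble(species_representative_id = reps$genome_id,
                              relative_abundance = counts / sum(counts))
    profile <- dplyr::filter(profile, .data$relative_abundance > 0)
  }

  # per-genome query rows from pooled read k-mers
  pooled <- unique(vv)
  query <- purrr::map_dfr(seq_len(nrow(db$genomes)), function(i) {
    gid <- db$genomes$genome_id[i]
    gset <- canonical_kmer_set(genome_sequences(db, gid), k)
    c_obs <- sum(gset %in% pooled) / length(gset)
    ani <- if (c_obs == 0) 0 else
      max(0, min(100, 100 * (1 + log(2 * c_obs / (1 + c_obs)) / k)))
    c_lo <- max(0, c_obs - 1.96 * sqrt(c_obs * (1 - c_obs) / length(gset)))
    ani_lo <- if (c_lo == 0) 0 else
      max(0, min(100, 100 * (1 + log(2 * c_lo / (1 + c_lo)) / k)))
    gm <- vv %in% gset
    per_read <- ifelse(n_valid > 0, tabulate(ridx[gm], nbins = length(reads)) / n_valid, 0)
    matched <- sum(per_read >= min_read_containment)
    coverage <- matched * mean_read_len / db$genomes$total_length[i]
    token <- if (matched < read_floor) "LOW"
             else if (matched >= 10 * read_floor) "HIGH"
             else formatC(coverage, format = "f", digits = 3)
    tibble::tibble(genome_id = gid, adjusted_ani = ani, ani_ci_lower = ani_lo,
                   eff_lambda_token = token)
  })
  list(profile = profile, query = query, warnings = warnings)
}

load_reads <- function(reads) {
  if (inherits(reads, "XStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) >= 1L && all(file.exists(reads))) {
    return(unlist(lapply(reads, function(p) {
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
    }), use.names = FALSE))
  }
  as.character(reads)
}
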