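#' Simulate paired-end reads from a mirror specification
#'
#' A desk-scale read sampler with exact provenance. Per-genome read-pair
#' counts are drawn multinomially from the specification abundances (used
#' directly as sequence abundances by default; set `length_weighted = TRUE`
#' to convert taxonomic to sequence abundance by genome length). Fragments
#' start uniformly over the valid positions of a length-weighted random
#' sequence of the genome; mate 1 is the fragment's leading bases, mate 2 the
#' reverse complement of its trailing bases. Substitution errors are i.i.d.
#' at `error_rate`; qualities are constant Phred 30.
#'
#' @param spec Specification tibble from [build_specification()].
#' @param db A `reference_db` holding every specification genome.
#' @param out_dir Directory for the FASTQ pair (created if needed).
#' @param read_length Read length in bp (default 126).
#' @param insert_mean,insert_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Integer seed; defaults to the specification's recorded seed.
#' @param count_mode `"pairs"` interprets `num_reads` as read pairs
#'   (default); `"reads"` as single reads (pairs = `num_reads / 2`).
#' @param length_weighted Reweight abundances by genome length before
#'   sampling.
#' @param write_fastq Write the FASTQ pair (default). With `FALSE` only the
#'   provenance and realized counts are produced (the read sequences are
#'   still returned when `return_reads = TRUE`).
#' @param return_reads Keep the read sequences in the returned object
#'   (elements `reads_r1`, `reads_r2`).
#' @return A `simulated_read_set`: list with `fastq_r1`, `fastq_r2`,
#'   `provenance` (tibble: `read_id`, `genome_id`, `seq_id`, `start` 0-based,
#'   `end`, `strand`) and `realized_counts` (named vector of read-pair counts).
#' @export
simulate_reads <- function(spec, db, out_dir = tempfile("reads"),
                           read_length = 126L, insert_mean = 300L,
                           insert_sd = 25L, error_rate = 0, seed = NULL,
                           count_mode = c("pairs", "reads"),
                           length_weighted = FALSE, write_fastq = TRUE,
                           return_reads = FALSE) {
  count_mode <- match.arg(count_mode)
  if (is.null(seed)) seed <- spec$seed[1]
  n_pairs <- if (count_mode == "pairs") spec$num_reads[1] else spec$num_reads[1] %/% 2L
  if (is.na(n_pairs) || n_pairs <= 0) stop("num_reads must be positive")
  missing <- setdiff(spec$genome_id, db$genomes$genome_id)
  if (length(missing) > 0) {
    stop("specification genome(s) absent from the database: ",
         paste(missing, collapse = ", "))
  }
  lens <- db$genomes$total_length[match(spec$genome_id, db$genomes$genome_id)]
  w <- spec$relative_abundance
  if (length_weighted) w <- w * lens
  if (sum(w) <= 0) stop("abundance weight sum is zero")
  for (i in seq_along(spec$genome_id)) {
    widths <- Biostrings::width(genome_sequences(db, spec$genome_id[i]))
    if (max(widths) < max(2L * read_length, insert_mean)) {
      stop("genome '", spec$genome_id[i], "' is shorter than the insert length")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_pairs, w / sum(w)))
    names(counts) <- spec$genome_id
    prov <- vector("list", length(counts))
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    pair_i <- 0L
    for (gi in seq_along(counts)) {
      ng <- counts[gi]
      if (ng == 0L) { prov[[gi]] <- NULL; next }
      gid <- spec$genome_id[gi]
      seqs <- genome_sequences(db, gid)
      widths <- Biostrings::width(seqs)
      ok <- widths >= 2L * read_length
      seq_pick <- sample.int(length(seqs), ng, replace = TRUE,
                             prob = widths * ok)
      ins <- pmax(2L * read_length,
                  as.integer(round(stats::rnorm(ng, insert_mean, insert_sd))))
      ins <- pmin(ins, widths[seq_pick])
      start <- 1L + as.integer(floor(stats::runif(ng) *
                                       (widths[seq_pick] - ins + 1L)))
      frag_seq <- as.character(seqs)[seq_pick]
      frag <- substring(frag_seq, start, start + ins - 1L)
      m1 <- substring(frag, 1L, read_length)
      m2 <- reverse_complement(substring(frag, ins - read_length + 1L, ins))
      if (error_rate > 0) {
        m1 <- mutate_reads(m1, error_rate)
        m2 <- mutate_reads(m2, error_rate)
      }
      idx <- pair_i + seq_len(ng)
      r1[idx] <- m1; r2[idx] <- m2
      start0 <- start - 1L  # 0-based fragment interval [start0, start0 + ins)
      prov[[gi]] <- tibble::tibble(
        read_id = sprintf("read_%07d", idx), genome_id = gid,
        seq_id = names(seqs)[seq_pick], start = start0,
        end = start0 + ins, strand = "+")
      pair_i <- pair_i + ng
    }
    list(counts = counts, prov = dplyr::bind_rows(prov), r1 = r1, r2 = r2)
  })

  ids <- sim$prov$read_id
  f1 <- f2 <- NA_character_
  if (write_fastq) {
    f1 <- file.path(out_dir, "reads_R1.fastq")
    f2 <- file.path(out_dir, "reads_R2.fastq")
    write_fastq_file(sim$r1, paste0(ids, "/1"), f1)
    write_fastq_file(sim$r2, paste0(ids, "/2"), f2)
  }
  out <- list(fastq_r1 = f1, fastq_r2 = f2, provenance = sim$prov,
              realized_counts = sim$counts)
  if (return_reads) {
    out$reads_r1 <- sim$r1
    out$reads_r2 <- sim$r2
  }
  structure(out, class = "simulated_read_set")
}

mutate_reads <- function(reads, rate) {
  n_mut <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_mut > 0)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_mut[i])
    chars <- strsplit(reads[i], NULL)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

write_fastq_file <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::PhredQuality(strrep("?", nchar(seqs)))
  xs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xs, path, compress = FALSE)
  invisible(path)
}

#' @export
print.simulated_read_set <- function(x, ...) {
  cat("<simulated_read_set> ", sum(x$realized_counts), " read pairs from ",
      length(x$realized_counts), " genomes\n", sep = "")
  invisible(x)
}

#' Emit the external-simulator command for a specification
#'
#' Writes the draft genome list and the abundance file for an InSilicoSeq run
#' and returns the full command string (model HiSeq, `--n_reads` from the
#' specification). Abundances are renormalized to sum to 1.
#'
#' @param spec Specification tibble.
#' @param db A `reference_db` whose metadata retains `fasta_path`.
#' @param output_prefix Prefix for the simulator's own outputs.
#' @param dir Directory in which the two list files are written.
#' @return List with `command`, `draft_list`, `abundance_list` (paths).
#' @export
emit_insilicoseq_command <- function(spec, db, output_prefix = "simulated",
                                     dir = tempfile("iss")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- db$genomes[match(spec$genome_id, db$genomes$genome_id), ]
  if (!"fasta_path" %in% names(g) || anyNA(g$fasta_path)) {
    stop("database metadata lacks fasta_path; cannot emit a draft list")
  }
  draft <- file.path(dir, "draft_list.txt")
  writeLines(g$fasta_path, draft)
  ab_file <- file.path(dir, "abundance_list.txt")
  ab <- spec$relative_abundance / sum(spec$relative_abundance)
  writeLines(paste(spec$genome_id, format(ab, digits = 17, scientific = FALSE,
                                          trim = TRUE), sep = "\t"), ab_file)
  command <- paste("iss generate --draft", draft, "--abundance_file", ab_file,
                   "--n_reads", spec$num_reads[1], "--model HiSeq",
                   "--output", output_prefix)
  list(command = command, draft_list = draft, abundance_list = ab_file)
}

#' Expected fold-coverage of a specification genome
#'
#' `abundance * num_reads * read_length * (2 if pairs) / genome_length`.
#'
#' @param spec Specification tibble.
#' @param db A `reference_db`.
#' @param genome_id Genome to evaluate.
#' @param read_length Read length in bp.
#' @param pairs Does `num_reads` count pairs (each contributing two reads)?
#' @return Expected fold-coverage.
#' @export
expected_coverage <- function(spec, db, genome_id, read_length = 126L,
                              pairs = TRUE) {
  row <- spec[spec$genome_id == genome_id, ]
  if (nrow(row) == 0) stop("genome '", genome_id, "' not in the specification")
  len <- db$genomes$total_length[db$genomes$genome_id == genome_id]
  if (length(len) == 0 || len == 0) stop("zero-length or unknown genome: ", genome_id)
  row$relative_abundance[1] * row$num_reads[1] * read_length *
    (if (pairs) 2 else 1) / len
}
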