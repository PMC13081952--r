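#' Parse BLAST tabular (outfmt 6) alignments
#'
#' Reads the standard 12-column nucleotide alignment table and converts both
#' coordinate systems to 0-based half-open intervals; subject intervals are
#' orientation-normalized (`g_start < g_end`), with the strand recorded.
#' Subject sequence ids are resolved to genome ids via `seqid_to_genome`.
#'
#' @param path Tabular alignment TSV (no header).
#' @param contig_lengths Named vector of query contig lengths (bp).
#' @param seqid_to_genome Named character vector mapping subject sequence ids
#'   to genome ids.
#' @return A tibble of alignment records: `contig_id`, `genome_id`,
#'   `genome_seq_id`, `percent_identity`, `alignment_length`, `c_start`,
#'   `c_end`, `g_start`, `g_end`, `strand`.
#' @export
parse_blast_tabular <- function(path, contig_lengths, seqid_to_genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 12L)) {
    stop("malformed tabular alignment (expected >= 12 columns) at line ",
         which(ncols < 12L)[1])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  qseqid <- m[, 1]; sseqid <- m[, 2]
  pident <- as.numeric(m[, 3]); alen <- as.numeric(m[, 4])
  qstart <- as.numeric(m[, 7]); qend <- as.numeric(m[, 8])
  sstart <- as.numeric(m[, 9]); send <- as.numeric(m[, 10])
  if (any(is.na(pident) | is.na(alen) | is.na(qstart) | is.na(qend) |
          is.na(sstart) | is.na(send))) {
    stop("non-numeric coordinate field in tabular alignment")
  }
  if (any(qend < qstart)) {
    stop("qend < qstart at line ", which(qend < qstart)[1],
         " (queries must be plus-strand)")
  }
  unknown <- setdiff(unique(sseqid), names(seqid_to_genome))
  if (length(unknown) > 0) {
    stop("unknown subject sequence id(s): ", paste(unknown, collapse = ", "))
  }
  tibble::tibble(
    contig_id = qseqid,
    genome_id = unname(seqid_to_genome[sseqid]),
    genome_seq_id = sseqid,
    percent_identity = pident,
    alignment_length = alen,
    c_start = qstart - 1, c_end = qend,
    g_start = pmin(sstart, send) - 1, g_end = pmax(sstart, send),
    strand = ifelse(send >= sstart, "+", "-"))
}

empty_alignments <- function() {
  tibble::tibble(contig_id = character(0), genome_id = character(0),
                 genome_seq_id = character(0), percent_identity = numeric(0),
                 alignment_length = numeric(0), c_start = numeric(0),
                 c_end = numeric(0), g_start = numeric(0), g_end = numeric(0),
                 strand = character(0))
}

#' Keep qualifying alignments and build the contig-genome map
#'
#' An alignment qualifies as ground truth when its percent identity is at
#' least `identity_gate` and its length lies within `length_gate` times the
#' contig length (defaults: identity >= 99, length within 99-101% of the
#' contig). All qualifying hits are retained, including multiple hits of one
#' contig to one genome (unioned downstream) and hits of one contig to many
#' genomes.
#'
#' @param records Alignment tibble from [parse_blast_tabular()] or
#'   [oracle_align()].
#' @param contig_lengths Named vector covering every query contig in the
#'   assembly (binned or not).
#' @param identity_gate Minimum percent identity.
#' @param length_gate Length-ratio window `c(lo, hi)`.
#' @return A `contig_genome_map`: list with `contig_lengths` and `hits`
#'   (the qualifying records).
#' @export
filter_qualifying <- function(records, contig_lengths,
                              identity_gate = 99, length_gate = c(0.99, 1.01)) {
  missing <- setdiff(unique(records$contig_id), names(contig_lengths))
  if (length(missing) > 0) {
    stop("contig_lengths does not cover: ", paste(missing, collapse = ", "))
  }
  lc <- unname(contig_lengths[records$contig_id])
  keep <- records$percent_identity >= identity_gate &
    records$alignment_length >= length_gate[1] * lc &
    records$alignment_length <= length_gate[2] * lc
  structure(list(contig_lengths = contig_lengths, hits = records[keep, ]),
            class = "contig_genome_map")
}

#' @export
print.contig_genome_map <- function(x, ...) {
  cat("<contig_genome_map> ", length(x$contig_lengths), " contigs, ",
      nrow(x$hits), " qualifying hits to ",
      dplyr::n_distinct(x$hits$genome_id), " genomes\n", sep = "")
  invisible(x)
}

#' Write / read a contig-genome map as TSV
#'
#' @param cmap A `contig_genome_map`.
#' @param path TSV path.
#' @return The path (write) or the map (read).
#' @export
write_contig_genome_map <- function(cmap, path) {
  out <- dplyr::mutate(cmap$hits,
                       contig_length = unname(cmap$contig_lengths[.data$contig_id]))
  readr::write_tsv(out, path)
  lens <- tibble::tibble(contig_id = names(cmap$contig_lengths),
                         contig_length = unname(cmap$contig_lengths))
  readr::write_tsv(lens, paste0(path, ".lengths"))
  invisible(path)
}

#' @rdname write_contig_genome_map
#' @export
read_contig_genome_map <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE)
  lens <- readr::read_tsv(paste0(path, ".lengths"), show_col_types = FALSE)
  cl <- lens$contig_length
  names(cl) <- lens$contig_id
  structure(list(contig_lengths = cl,
                 hits = dplyr::select(hits, -"contig_length")),
            class = "contig_genome_map")
}

#' Exact-substring aligner for fixtures
#'
#' Finds every occurrence of each contig in each genome by exact substring
#' search on both strands and emits one full-length, 100%-identity alignment
#' record per occurrence, in the same shape as [parse_blast_tabular()].
#' Intended for fixtures whose contigs are exact (possibly
#' reverse-complemented) substrings of the genomes.
#'
#' @param contigs Named character vector or `DNAStringSet` of contigs.
#' @param genomes A `reference_db` or a named list of `DNAStringSet`s
#'   (genome id -> sequences).
#' @return Alignment record tibble.
#' @export
oracle_align <- function(contigs, genomes) {
  if (inherits(genomes, "reference_db")) genomes <- genomes$sequences
  contigs <- if (inherits(contigs, "XStringSet")) {
    stats::setNames(as.character(contigs), names(contigs))
  } else contigs
  recs <- list()
  for (gid in names(genomes)) {
    seqs <- genomes[[gid]]
    for (si in seq_along(seqs)) {
      subject <- seqs[[si]]
      sid <- names(seqs)[si]
      for (ci in seq_along(contigs)) {
        patt <- Biostrings::DNAString(contigs[[ci]])
        lc <- length(patt)
        for (strand in c("+", "-")) {
          p <- if (strand == "+") patt else Biostrings::reverseComplement(patt)
          hits <- Biostrings::matchPattern(p, subject)
          if (length(hits) == 0) next
          recs[[length(recs) + 1L]] <- tibble::tibble(
            contig_id = names(contigs)[ci], genome_id = gid,
            genome_seq_id = sid, percent_identity = 100,
            alignment_length = lc, c_start = 0, c_end = lc,
            g_start = BiocGenerics::start(hits) - 1,
            g_end = BiocGenerics::end(hits), strand = strand)
        }
      }
    }
  }
  if (length(recs) == 0) return(empty_alignments())
  dplyr::bind_rows(recs)
}
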