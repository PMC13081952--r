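# Canonical tetranucleotide index: each 4-mer is pooled with its reverse
# complement; 16 palindromic 4-mers + 120 pooled pairs = 136 features.
.tetra_names <- local({
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste,
                collapse = "")
  rc <- vapply(all4, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), NULL)[[1]]), collapse = "")
  }, "")
  canon <- pmin(all4, rc)
  list(all4 = all4, canon = canon, levels = sort(unique(canon)))
})

#' Canonical tetranucleotide composition of a sequence
#'
#' Counts all 4-mer windows (windows containing non-ACGT bases are skipped),
#' pools each 4-mer with its reverse complement (136 canonical features), and
#' normalizes to sum 1.
#'
#' @param sequence Character scalar, `DNAString`, or `DNAStringSet` (counts
#'   pooled over sequences).
#' @return Named numeric vector of 136 canonical 4-mer frequencies.
#' @export
tetranucleotide_composition <- function(sequence) {
  ss <- if (inherits(sequence, "DNAStringSet")) sequence
        else Biostrings::DNAStringSet(as.character(sequence))
  counts <- colSums(Biostrings::oligonucleotideFrequency(ss, 4))
  pooled <- tapply(counts[.tetra_names$all4], .tetra_names$canon, sum)
  out <- as.numeric(pooled[.tetra_names$levels])
  names(out) <- .tetra_names$levels
  if (sum(out) == 0) stop("no valid 4-mer window in sequence")
  out / sum(out)
}

#' Cosine distance between composition vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `1 - cos(u, v)`, in `[0, 2]`.
#' @export
composition_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector")
  1 - sum(u * v) / (nu * nv)
}

#' Euclidean coverage distance
#'
#' Distance between a contig's per-sample coverage vector and the mean
#' coverage vector of all contigs assigned to its ground-truth genome, both
#' computed across the dataset.
#'
#' @param contig_cov,genome_mean_cov Numeric vectors, one entry per dataset
#'   sample.
#' @return Euclidean norm of the difference.
#' @export
coverage_distance <- function(contig_cov, genome_mean_cov) {
  if (length(contig_cov) != length(genome_mean_cov)) {
    stop("coverage vectors differ in length")
  }
  sqrt(sum((contig_cov - genome_mean_cov)^2))
}

#' Truth-derived contig coverage table
#'
#' Computes per-contig mean depth in each sample directly from read
#' provenance: the basepairs of simulated fragments overlapping the contig's
#' source interval, divided by the contig length. An external depth table
#' (columns `contig_id`, `sample_id`, `mean_depth`) can be used instead via
#' [read_depth_table()].
#'
#' @param contig_truth Tibble with `contig_id`, `genome_id`, `seq_id`,
#'   `start`, `end` (0-based half-open source interval).
#' @param read_sets Named list (sample id -> `simulated_read_set`).
#' @return Tibble with `contig_id`, `sample_id`, `mean_depth`.
#' @export
truth_contig_coverage <- function(contig_truth, read_sets) {
  purrr::map_dfr(names(read_sets), function(sid) {
    prov <- read_sets[[sid]]$provenance
    depth <- vapply(seq_len(nrow(contig_truth)), function(i) {
      ct <- contig_truth[i, ]
      p <- prov[prov$genome_id == ct$genome_id & prov$seq_id == ct$seq_id, ]
      if (nrow(p) == 0) return(0)
      ov <- pmax(0, pmin(p$end, ct$end) - pmax(p$start, ct$start))
      sum(ov) / (ct$end - ct$start)
    }, 0)
    tibble::tibble(contig_id = contig_truth$contig_id, sample_id = sid,
                   mean_depth = depth)
  })
}

#' @rdname truth_contig_coverage
#' @param path Depth table TSV.
#' @export
read_depth_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("contig_id", "sample_id", "mean_depth"), "depth table")
  tibble::as_tibble(tab)
}

#' Discretize contig distances into base-pair percentiles
#'
#' Items (one per contig x mapped genome, pooled across samples) are ordered
#' by ascending distance (ties broken by `sample_id`, `contig_id`,
#' `genome_id`). With `s_c` the cumulative length of strictly preceding items
#' and `bases = sum(length) / 100`, item `c` lands in percentile `p`
#' (0-99) satisfying `p * bases < s_c + l_c / 2 <= (p + 1) * bases`.
#'
#' @param items Tibble with `sample_id`, `contig_id`, `genome_id`, `length`,
#'   `distance`.
#' @return The tibble ordered as used, with `s_c`, `bases` and `percentile`
#'   columns added.
#' @export
percentile_discretize <- function(items) {
  if (nrow(items) == 0) stop("no items to discretize")
  it <- dplyr::arrange(items, .data$distance, .data$sample_id,
                       .data$contig_id, .data$genome_id)
  s_c <- cumsum(c(0, it$length))[seq_len(nrow(it))]
  bases <- sum(it$length) / 100
  mid <- s_c + it$length / 2
  p <- ceiling(mid / bases) - 1
  # float-safe fix-up so the defining inequality holds verbatim
  low_bad <- p * bases >= mid
  p[low_bad] <- p[low_bad] - 1
  high_bad <- mid > (p + 1) * bases
  p[high_bad] <- p[high_bad] + 1
  p <- pmin(99, pmax(0, p))
  dplyr::mutate(it, s_c = s_c, bases = bases, percentile = as.integer(p))
}

#' Per-percentile recall of binning
#'
#' A contig-genome item is correctly binned in its sample when the contig's
#' bin equals the representative bin of its ground-truth genome in that
#' sample (unbinned contigs count as incorrect). Per percentile, recall is
#' correct basepairs / total basepairs.
#'
#' @param assignments Output of [percentile_discretize()].
#' @param bin_tables Named list (sample id -> bin table with `contig_id`,
#'   `bin_id`), or a single bin table used for all samples.
#' @param representative_map Tibble with `sample_id`, `genome_id`,
#'   `representative_bin`.
#' @return Tibble with `percentile`, `tp_bp`, `fn_bp`, `recall`, plus the
#'   item-level `correct` flags as attribute `"items"`.
#' @export
percentile_recall <- function(assignments, bin_tables, representative_map) {
  items <- flag_correct(assignments, bin_tables, representative_map)
  out <- dplyr::summarise(
    dplyr::group_by(items, .data$percentile),
    tp_bp = sum(.data$length[.data$correct]),
    fn_bp = sum(.data$length[!.data$correct]),
    recall = .data$tp_bp / (.data$tp_bp + .data$fn_bp), .groups = "drop")
  attr(out, "items") <- items
  out
}

flag_correct <- function(items, bin_tables, representative_map) {
  if (is.data.frame(bin_tables)) {
    bin_tables <- stats::setNames(rep(list(bin_tables),
                                      length(unique(items$sample_id))),
                                  unique(items$sample_id))
  }
  bin_of <- purrr::map_dfr(names(bin_tables), function(sid) {
    tibble::tibble(sample_id = sid,
                   contig_id = bin_tables[[sid]]$contig_id,
                   bin_id = as.character(bin_tables[[sid]]$bin_id))
  })
  it <- dplyr::left_join(items, bin_of, by = c("sample_id", "contig_id"))
  it <- dplyr::left_join(it, representative_map, by = c("sample_id", "genome_id"))
  dplyr::mutate(it, correct = !is.na(.data$bin_id) &
                  !is.na(.data$representative_bin) &
                  .data$bin_id == .data$representative_bin)
}

#' Classify a contig as prophage
#'
#' A contig is a prophage contig when, in at least one genome it maps to, it
#' is entirely contained within a provirus interval, contains an entire
#' provirus, or covers at least 25% of a provirus.
#'
#' @param contig_hits Tibble of the contig's qualifying genome intervals
#'   (`genome_id`, `g_start`, `g_end`; 0-based half-open; the provirus
#'   intervals must be on the same coordinates).
#' @param provirus_intervals Tibble with `genome_id`, `start`, `end`.
#' @param min_provirus_coverage Minimum covered fraction of a provirus
#'   (default 0.25).
#' @return Logical scalar.
#' @export
classify_prophage <- function(contig_hits, provirus_intervals,
                              min_provirus_coverage = 0.25) {
  if (nrow(contig_hits) == 0 || nrow(provirus_intervals) == 0) return(FALSE)
  j <- dplyr::inner_join(contig_hits, provirus_intervals, by = "genome_id",
                         relationship = "many-to-many")
  if (nrow(j) == 0) return(FALSE)
  ov <- pmax(0, pmin(j$g_end, j$end) - pmax(j$g_start, j$start))
  contained_in <- j$g_start >= j$start & j$g_end <= j$end
  contains <- j$start >= j$g_start & j$end <= j$g_end
  covers <- ov / (j$end - j$start) >= min_provirus_coverage
  any(contained_in | contains | covers)
}

#' Classify a contig as shared
#'
#' A contig is shared when it has qualifying alignments to two or more
#' distinct recoverable genomes.
#'
#' @param contig_id The contig.
#' @param cmap A `contig_genome_map` (qualifying hits).
#' @param recoverable_genomes Character vector of recoverable genome ids.
#' @return Logical scalar.
#' @export
classify_shared <- function(contig_id, cmap, recoverable_genomes) {
  h <- cmap$hits[cmap$hits$contig_id == contig_id, ]
  dplyr::n_distinct(intersect(h$genome_id, recoverable_genomes)) >= 2
}

#' Read a geNomad-dialect provirus table
#'
#' Keeps high-confidence provirus annotations (virus score >= `score_min`)
#' and parses `coordinates` (`"start-end"`, 1-based inclusive) into 0-based
#' half-open intervals on the named sequence.
#'
#' @param path TSV with columns `seq_name`, `coordinates`, `virus_score`.
#' @param seqid_to_genome Named map from sequence id to genome id.
#' @param score_min Minimum virus score (default 0.9).
#' @return Tibble with `genome_id`, `seq_id`, `start`, `end`.
#' @export
read_genomad_provirus <- function(path, seqid_to_genome, score_min = 0.9) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("seq_name", "coordinates", "virus_score"),
                  "provirus table")
  tab <- tab[tab$virus_score >= score_min, ]
  parts <- strsplit(as.character(tab$coordinates), "-", fixed = TRUE)
  tibble::tibble(
    genome_id = unname(seqid_to_genome[as.character(tab$seq_name)]),
    seq_id = as.character(tab$seq_name),
    start = vapply(parts, function(x) as.numeric(x[1]), 0) - 1,
    end = vapply(parts, function(x) as.numeric(x[2]), 0))
}

#' Recall of a contig group within a genome and sample
#'
#' Over the genome's mapped contig items belonging to the group: correct
#' basepairs / total basepairs; `NA` when the genome has no contig in the
#' group.
#'
#' @param items Item tibble with `genome_id`, `sample_id`, `length`,
#'   `correct`, and logical group columns (`prophage`, `shared`) as produced
#'   by [contig_feature_table()] + [flag_correct()].
#' @param genome_id,sample_id The genome and sample.
#' @param group One of `"all"`, `"prophage"`, `"shared"`.
#' @return Recall fraction or `NA`.
#' @export
group_recall <- function(items, genome_id, sample_id, group = c("all", "prophage", "shared")) {
  group <- match.arg(group)
  it <- items[items$genome_id == genome_id & items$sample_id == sample_id, ]
  if (group != "all") it <- it[it[[group]], ]
  if (nrow(it) == 0) return(NA_real_)
  sum(it$length[it$correct]) / sum(it$length)
}

#' Build the contig feature table
#'
#' One row per (contig, mapped genome): length, composition distance to the
#' genome, coverage distance to the genome's mean contig coverage, prophage
#' and shared flags. Restricted to the supplied recoverable genomes.
#'
#' @param cmap A `contig_genome_map`.
#' @param contig_seqs Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param genome_seqs Named list (genome id -> `DNAStringSet`) or a
#'   `reference_db`.
#' @param coverage Depth tibble (`contig_id`, `sample_id`, `mean_depth`).
#' @param recoverable_genomes Character vector of recoverable genome ids.
#' @param provirus_intervals Tibble for [classify_prophage()] (may be empty).
#' @param sample_id Sample label for the items.
#' @return Tibble with `sample_id`, `contig_id`, `genome_id`, `length`,
#'   `composition_distance`, `coverage_distance`, `prophage`, `shared`.
#' @export
contig_feature_table <- function(cmap, contig_seqs, genome_seqs, coverage,
                                 recoverable_genomes,
                                 provirus_intervals = NULL,
                                 sample_id = "sample") {
  if (inherits(genome_seqs, "reference_db")) genome_seqs <- genome_seqs$sequences
  if (inherits(contig_seqs, "XStringSet")) {
    contig_seqs <- stats::setNames(as.character(contig_seqs), names(contig_seqs))
  }
  pairs <- dplyr::distinct(cmap$hits[cmap$hits$genome_id %in% recoverable_genomes, ],
                           .data$contig_id, .data$genome_id)
  if (nrow(pairs) == 0) return(tibble::tibble())
  gcomp <- lapply(genome_seqs[unique(pairs$genome_id)], tetranucleotide_composition)
  ccomp <- lapply(contig_seqs[unique(pairs$contig_id)], tetranucleotide_composition)
  cov_wide <- tidyr::pivot_wider(coverage, id_cols = "contig_id",
                                 names_from = "sample_id",
                                 values_from = "mean_depth", values_fill = 0)
  cov_mat <- as.matrix(cov_wide[, -1, drop = FALSE])
  rownames(cov_mat) <- cov_wide$contig_id
  # genome mean = unweighted mean over contigs mapped to the genome
  gmean <- lapply(split(pairs$contig_id, pairs$genome_id), function(cids) {
    colMeans(cov_mat[cids, , drop = FALSE])
  })
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    cid <- pairs$contig_id[i]; gid <- pairs$genome_id[i]
    hits <- cmap$hits[cmap$hits$contig_id == cid, ]
    tibble::tibble(
      sample_id = sample_id, contig_id = cid, genome_id = gid,
      length = unname(cmap$contig_lengths[cid]),
      composition_distance = composition_distance(ccomp[[cid]], gcomp[[gid]]),
      coverage_distance = coverage_distance(cov_mat[cid, ], gmean[[gid]]),
      prophage = if (is.null(provirus_intervals)) FALSE else
        classify_prophage(hits[, c("genome_id", "g_start", "g_end")],
                          provirus_intervals),
      shared = classify_shared(cid, cmap, recoverable_genomes))
  })
}
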