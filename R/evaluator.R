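# Interval helpers over a contig-genome map. Genome positions live on the
# concatenation key (genome_seq_id, start, end); unions are computed per
# sequence and summed.

union_width <- function(starts, ends, seq_ids) {
  if (length(starts) == 0) return(0)
  total <- 0
  for (sid in unique(seq_ids)) {
    i <- seq_ids == sid
    ir <- IRanges::reduce(IRanges::IRanges(start = starts[i] + 1, end = ends[i]))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

genome_hit_ranges <- function(cmap, genome_id, contig_ids = NULL) {
  h <- cmap$hits[cmap$hits$genome_id == genome_id, ]
  if (!is.null(contig_ids)) h <- h[h$contig_id %in% contig_ids, ]
  h
}

#' Base-pair recall of one bin against one ground-truth genome
#'
#' True positives are the genome basepairs covered by the union of qualifying
#' genome-side intervals of the bin's contigs; false negatives are the
#' remaining genome basepairs.
#'
#' @param genome_length Total genome length in bp.
#' @param genome_id Ground-truth genome.
#' @param bin_contigs Character vector of the bin's contig ids.
#' @param cmap A `contig_genome_map` over the sample's assembly.
#' @return Named list with `tp`, `fn`.
#' @export
genome_bin_recall <- function(genome_length, genome_id, bin_contigs, cmap) {
  h <- genome_hit_ranges(cmap, genome_id, bin_contigs)
  tp <- union_width(h$g_start, h$g_end, h$genome_seq_id)
  list(tp = tp, fn = genome_length - tp)
}

#' Select the representative bin of a genome
#'
#' The representative is the bin with the highest recall; ties are broken by
#' lexicographically smallest bin id. A representative is returned even when
#' every bin has zero recall; with no bins at all the representative is `NA`.
#'
#' @inheritParams genome_bin_recall
#' @param bins Named list: bin id -> character vector of contig ids.
#' @return List with `bin_id` (or `NA`), `tp`, `fn`.
#' @export
select_representative <- function(genome_length, genome_id, bins, cmap) {
  if (length(bins) == 0) {
    return(list(bin_id = NA_character_, tp = 0, fn = genome_length))
  }
  ids <- sort(names(bins))
  tps <- vapply(ids, function(b) {
    genome_bin_recall(genome_length, genome_id, bins[[b]], cmap)$tp
  }, 0)
  best <- ids[which.max(tps)]  # which.max takes the first (smallest id) on ties
  list(bin_id = best, tp = unname(tps[best]), fn = genome_length - unname(tps[best]))
}

#' False positives and precision of a representative bin
#'
#' False positives are the contig-side basepairs of the representative bin
#' not covered by any qualifying alignment of that contig to the genome, so a
#' contig with no qualifying hit to the genome contributes its full length,
#' while shared contigs mapping to the genome contribute (essentially) none.
#' Precision is `tp / (tp + fp)`, defined as 0 when `tp = fp = 0`; the
#' F-score is the harmonic mean of recall and precision (0 when both are 0).
#'
#' @inheritParams genome_bin_recall
#' @param tp,fn True/false negative basepairs of the representative bin.
#' @return List with `fp`, `precision`, `fscore`.
#' @export
genome_precision <- function(genome_id, bin_contigs, cmap, tp, fn) {
  fp <- 0
  h <- genome_hit_ranges(cmap, genome_id, bin_contigs)
  for (cid in bin_contigs) {
    hc <- h[h$contig_id == cid, ]
    covered <- if (nrow(hc) == 0) 0 else
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = hc$c_start + 1, end = hc$c_end))))
    fp <- fp + unname(cmap$contig_lengths[cid]) - covered
  }
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  fscore <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(fp = fp, precision = precision, fscore = fscore)
}

#' Evaluate a binning result against the ground truth
#'
#' Per ground-truth genome: select the representative bin (highest recall),
#' then score TP/FN/FP in basepairs and recall / precision / F-score. This is
#' the tidy per-genome table handed to downstream statistics.
#'
#' @param genomes Data frame with `genome_id` and `total_length` (e.g. the
#'   specification genomes joined to the database), one row per ground-truth
#'   genome.
#' @param bin_table Data frame with `contig_id`, `bin_id`; contigs absent
#'   from it are unbinned. A contig may appear in at most one bin.
#' @param cmap A `contig_genome_map` over the sample's assembly.
#' @param sample_id,pipeline Labels recorded in the output.
#' @return A tibble, one row per genome: `genome_id`, `sample_id`,
#'   `pipeline`, `representative_bin`, `tp_bp`, `fn_bp`, `fp_bp`, `recall`,
#'   `precision`, `fscore`, `degenerate` (TRUE when the representative is
#'   absent/empty so precision's 0/0 convention applied).
#' @export
evaluate_bins <- function(genomes, bin_table, cmap, sample_id = "sample",
                          pipeline = "pipeline") {
  if (anyDuplicated(bin_table$contig_id)) {
    stop("a contig is assigned to more than one bin")
  }
  bins <- split(bin_table$contig_id, bin_table$bin_id)
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    gid <- genomes$genome_id[i]
    glen <- genomes$total_length[i]
    rep <- select_representative(glen, gid, bins, cmap)
    if (is.na(rep$bin_id)) {
      prec <- list(fp = 0, precision = 0, fscore = 0)
    } else {
      prec <- genome_precision(gid, bins[[rep$bin_id]], cmap, rep$tp, rep$fn)
    }
    tibble::tibble(
      genome_id = gid, sample_id = sample_id, pipeline = pipeline,
      representative_bin = rep$bin_id, tp_bp = rep$tp, fn_bp = rep$fn,
      fp_bp = prec$fp, recall = rep$tp / glen, precision = prec$precision,
      fscore = prec$fscore,
      degenerate = rep$tp == 0 && prec$fp == 0)
  })
}

#' Recoverable (genome, sample) pairs
#'
#' A pair is recoverable when at least one evaluated pipeline achieves both
#' recall >= `recall_gate` and precision >= `precision_gate` (inclusive).
#'
#' @param evals Evaluation tibble from [evaluate_bins()] (rows across
#'   pipelines).
#' @param recall_gate,precision_gate Inclusive thresholds (defaults 0.7, 0.9).
#' @return Tibble of distinct recoverable `genome_id`, `sample_id` pairs.
#' @export
recoverable_set <- function(evals, recall_gate = 0.7, precision_gate = 0.9) {
  ok <- dplyr::filter(evals, .data$recall >= recall_gate,
                      .data$precision >= precision_gate)
  dplyr::distinct(ok, .data$genome_id, .data$sample_id)
}

#' Genomes passing the expected-coverage filter
#'
#' @param spec Specification tibble.
#' @param db A `reference_db`.
#' @param threshold Minimum expected fold-coverage (default 2.5).
#' @param read_length,pairs Passed to [expected_coverage()].
#' @return Character vector of genome ids with expected coverage >= threshold.
#' @export
coverage_filter <- function(spec, db, threshold = 2.5, read_length = 126L,
                            pairs = TRUE) {
  cov <- vapply(spec$genome_id, function(g) {
    expected_coverage(spec, db, g, read_length = read_length, pairs = pairs)
  }, 0)
  spec$genome_id[cov >= threshold]
}

#' MIMAG-style quality class from completeness / contamination estimates
#'
#' High quality: completeness > 90 and contamination < 5; medium:
#' completeness >= 50 and contamination < 10; low: contamination < 10
#' (any completeness); otherwise unclassified.
#'
#' @param completeness Percent in `[0, 100]`.
#' @param contamination Percent, >= 0 (may exceed 100).
#' @return Character vector over `"HQ"`, `"MQ"`, `"LQ"`, `"UNCLASSIFIED"`.
#' @export
classify_mimag <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    stop("completeness must be in [0, 100]")
  }
  if (any(contamination < 0, na.rm = TRUE)) stop("contamination must be >= 0")
  dplyr::case_when(
    completeness > 90 & contamination < 5 ~ "HQ",
    completeness >= 50 & contamination < 10 ~ "MQ",
    contamination < 10 ~ "LQ",
    TRUE ~ "UNCLASSIFIED")
}

#' Read a CheckM2-dialect quality report
#'
#' @param path TSV with columns `Name`, `Completeness`, `Contamination`.
#' @return Tibble with `bin_id`, `checkm2_completeness`,
#'   `checkm2_contamination`, `mimag_class`.
#' @export
read_checkm2 <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("Name", "Completeness", "Contamination"),
                  "CheckM2 report")
  tibble::tibble(bin_id = as.character(tab$Name),
                 checkm2_completeness = as.numeric(tab$Completeness),
                 checkm2_contamination = as.numeric(tab$Contamination),
                 mimag_class = classify_mimag(as.numeric(tab$Completeness),
                                              as.numeric(tab$Contamination)))
}

#' Read a GUNC-dialect report
#'
#' @param path TSV with a bin-name column (`genome`) and a `pass.GUNC`
#'   column.
#' @return Tibble with `bin_id`, `gunc_pass`.
#' @export
read_gunc <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  require_columns(tab, c("genome", "pass.GUNC"), "GUNC report")
  tibble::tibble(bin_id = as.character(tab$genome),
                 gunc_pass = as.logical(tab$`pass.GUNC`))
}

#' Filter evaluations by GUNC pass/fail
#'
#' Excludes evaluation rows whose representative bin is flagged by GUNC as
#' contaminated, and summarizes what was removed.
#'
#' @param evals Evaluation tibble.
#' @param quality_rows Tibble with `bin_id`, `gunc_pass` (see [read_gunc()]).
#' @param missing How to treat representative bins absent from the report:
#'   `"error"` (default) or `"pass"`.
#' @return List with `kept` and `removed` evaluation tibbles and `summary`
#'   (one row: `n_total`, `n_removed`, `removed_fraction`,
#'   `removed_mean_recall`, `removed_mean_one_minus_precision`).
#' @export
apply_gunc_filter <- function(evals, quality_rows, missing = c("error", "pass")) {
  missing <- match.arg(missing)
  pass <- quality_rows$gunc_pass
  names(pass) <- quality_rows$bin_id
  has_bin <- !is.na(evals$representative_bin)
  known <- evals$representative_bin %in% names(pass)
  if (missing == "error" && any(has_bin & !known)) {
    stop("representative bin(s) missing from the GUNC report: ",
         paste(unique(evals$representative_bin[has_bin & !known]), collapse = ", "))
  }
  bin_pass <- rep(TRUE, nrow(evals))
  bin_pass[has_bin & known] <- unname(pass[evals$representative_bin[has_bin & known]])
  kept <- evals[bin_pass, ]
  removed <- evals[!bin_pass, ]
  summary <- tibble::tibble(
    n_total = nrow(evals), n_removed = nrow(removed),
    removed_fraction = if (nrow(evals) == 0) 0 else nrow(removed) / nrow(evals),
    removed_mean_recall = if (nrow(removed) == 0) NA_real_ else mean(removed$recall),
    removed_mean_one_minus_precision =
      if (nrow(removed) == 0) NA_real_ else mean(1 - removed$precision))
  list(kept = kept, removed = removed, summary = summary)
}

#' Assembly recall of a genome
#'
#' Recall restricted to the assembled portion of the genome: the denominator
#' is the union of genome intervals over all qualifying contigs in the
#' assembly (binned or not), the numerator the representative bin's true
#' positives intersected with that union. `NA` when nothing of the genome
#' was assembled.
#'
#' @inheritParams select_representative
#' @return Assembly recall fraction, or `NA`.
#' @export
assembly_recall <- function(genome_length, genome_id, bins, cmap) {
  all_h <- genome_hit_ranges(cmap, genome_id)
  denom <- union_width(all_h$g_start, all_h$g_end, all_h$genome_seq_id)
  if (denom == 0) return(NA_real_)
  rep <- select_representative(genome_length, genome_id, bins, cmap)
  rep$tp / denom
}
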