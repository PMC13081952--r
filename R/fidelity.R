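#' Shannon alpha diversity of an abundance profile
#'
#' `-sum(p_i * ln(p_i))` over the nonzero taxa of the renormalized profile.
#'
#' @param profile Numeric abundance vector, or a data frame with a
#'   `rel_abundance` column.
#' @return Nonnegative real.
#' @export
shannon_alpha <- function(profile) {
  p <- if (is.data.frame(profile)) profile$rel_abundance else as.numeric(profile)
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0) stop("empty profile")
  as.numeric(vegan::diversity(p / sum(p), index = "shannon"))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum(|p_i - q_i|) / sum(p_i + q_i)` over a shared taxon universe
#' (missing taxa are zero).
#'
#' @param p,q Named or plain numeric abundance vectors.
#' @return Distance in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    taxa <- union(names(p), names(q))
    pp <- stats::setNames(rep(0, length(taxa)), taxa); pp[names(p)] <- p
    qq <- stats::setNames(rep(0, length(taxa)), taxa); qq[names(q)] <- q
    p <- pp; q <- qq
  }
  if (length(p) != length(q)) stop("profiles differ in length and are unnamed")
  if (sum(p) + sum(q) == 0) stop("both profiles are all-zero")
  as.numeric(vegan::vegdist(rbind(p, q), method = "bray"))
}

#' Regression of simulated on original pairwise beta diversity
#'
#' Ordinary least squares of the simulated-pair dissimilarities on the
#' original-pair dissimilarities, pair for pair; a through-origin fit is
#' reported alongside.
#'
#' @param orig_pairwise,sim_pairwise Aligned numeric vectors (>= 3 pairs).
#' @return A `paired_beta_fit` with elements `slope`, `intercept`,
#'   `r_squared`, `slope_origin`, `r_squared_origin`, `n`, and the `lm` fit
#'   in `model`. Supports [generics::tidy()] and [generics::glance()].
#' @export
paired_beta_regression <- function(orig_pairwise, sim_pairwise) {
  if (length(orig_pairwise) != length(sim_pairwise)) {
    stop("pairwise vectors differ in length")
  }
  if (length(orig_pairwise) < 3) stop("need at least 3 pairs")
  if (stats::var(orig_pairwise) == 0) stop("zero variance in original distances")
  fit <- stats::lm(sim_pairwise ~ orig_pairwise)
  fit0 <- stats::lm(sim_pairwise ~ 0 + orig_pairwise)
  # summary.lm warns on an exactly collinear (perfect) fit; that is a
  # legitimate input here (sim == orig), not a numerical problem
  s1 <- suppressWarnings(summary(fit))
  s0 <- suppressWarnings(summary(fit0))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s1$r.squared,
    slope_origin = unname(stats::coef(fit0)[1]),
    r_squared_origin = s0$r.squared,
    n = length(orig_pairwise), model = fit), class = "paired_beta_fit")
}

#' @export
print.paired_beta_fit <- function(x, ...) {
  cat(sprintf("<paired_beta_fit> n = %d, slope = %.4f, intercept = %.4f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname paired_beta_regression
#' @param x A `paired_beta_fit`.
#' @param ... Unused.
#' @export
tidy.paired_beta_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @rdname paired_beta_regression
#' @export
glance.paired_beta_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, slope_origin = x$slope_origin,
                 r_squared_origin = x$r_squared_origin, n = x$n)
}

#' Bottom-s MinHash sketch of a sequence set
#'
#' The `s` smallest seeded hashes of the canonical k-mer set, used for
#' Mash-style distance estimation between samples.
#'
#' @param sequences Character vector, `DNAStringSet`, or FASTQ/FASTA paths.
#' @param k K-mer size (default 21).
#' @param s Sketch size (default 1000).
#' @param hash_seed Hash seed shared by comparable sketches.
#' @return A `minhash_sketch`: list with `k`, `s`, `hash_seed`, and the
#'   ascending `hashes`.
#' @export
minhash_sketch <- function(sequences, k = 21L, s = 1000L, hash_seed = 42L) {
  sequences <- load_reads(sequences)
  kset <- canonical_kmer_set(sequences, k)
  h <- sort(unique(hash_kmers(kset, hash_seed)))
  structure(list(k = as.integer(k), s = as.integer(s),
                 hash_seed = as.integer(hash_seed),
                 hashes = utils::head(h, s)), class = "minhash_sketch")
}

#' Mash-style distance between two sketches
#'
#' Jaccard similarity `j` is estimated over the bottom-`s` of the merged hash
#' union; the distance is `-(1/k) * ln(2j / (1 + j))`, with `j = 0` reported
#' as the sentinel distance 1.
#'
#' @param a,b `minhash_sketch` objects with identical `k`, `s`, `hash_seed`.
#' @return Distance >= 0.
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) stop("k-mer size mismatch between sketches")
  if (a$hash_seed != b$hash_seed || a$s != b$s) {
    stop("sketch parameters (s, hash_seed) mismatch")
  }
  merged <- utils::head(sort(unique(c(a$hashes, b$hashes))), a$s)
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / length(merged)
  if (j == 0) return(1)
  max(0, -(1 / a$k) * log(2 * j / (1 + j)))
}

#' Write / read a sketch as a plain-text table
#'
#' @param sketch A `minhash_sketch`.
#' @param path TSV path.
#' @return The path (write) or the sketch (read).
#' @export
write_sketch <- function(sketch, path) {
  writeLines(c(paste("#k", sketch$k, "s", sketch$s, "hash_seed",
                     sketch$hash_seed, sep = "\t"),
               format(sketch$hashes, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  structure(list(k = as.integer(hdr[2]), s = as.integer(hdr[4]),
                 hash_seed = as.integer(hdr[6]),
                 hashes = as.numeric(lines[-1])), class = "minhash_sketch")
}

#' Select the partial multi-sample binning context
#'
#' The `D` non-target samples closest to the target by Mash distance (ties
#' broken by sample id). When `D` or fewer other samples exist, all of them
#' are returned with a warning.
#'
#' @param target_sample Sample id of the target.
#' @param sketches Named list (sample id -> `minhash_sketch`) covering the
#'   target and all candidates.
#' @param D Context size (default 20).
#' @return Character vector of selected sample ids.
#' @export
select_partial_context <- function(target_sample, sketches, D = 20L) {
  others <- setdiff(names(sketches), target_sample)
  if (!target_sample %in% names(sketches)) stop("target sample has no sketch")
  if (length(others) <= D) {
    warning("only ", length(others), " candidate samples for a context of ", D)
    return(sort(others))
  }
  d <- vapply(others, function(s) {
    mash_distance(sketches[[target_sample]], sketches[[s]])
  }, 0)
  others[order(d, others)][seq_len(D)]
}
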