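#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# 2-bit base codes; anything outside A/C/G/T (N, IUPAC ambiguity) -> NA so that
# every k-mer window touching it is dropped.
.code_lookup <- local({
  lut <- rep(NA_real_, 128)
  lut[utf8ToInt("A")] <- 0
  lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2
  lut[utf8ToInt("T")] <- 3
  lut
})

base_codes <- function(seq) {
  .code_lookup[utf8ToInt(toupper(seq))]
}

# Canonical k-mer values (numeric, exact for k <= 25): each k-mer is encoded in
# base 4 (A<C<G<T) and pooled with its reverse complement by taking the numeric
# minimum, which equals the lexicographic minimum under this encoding.
canonical_kmers <- function(seq, k = 21L) {
  stopifnot(k >= 1L, k <= 25L)
  codes <- base_codes(seq)
  n <- length(codes)
  if (n < k) return(numeric(0))
  fwd <- stats::filter(codes, 4^(0:(k - 1L)), sides = 1)
  rev <- stats::filter(3 - codes, 4^((k - 1L):0), sides = 1)
  v <- pmin(as.numeric(fwd), as.numeric(rev))[k:n]
  v[!is.na(v)]
}

# Canonical k-mer set of a collection of sequences (joined by 'N' so windows
# never span sequence boundaries).
canonical_kmer_set <- function(seqs, k = 21L) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) return(numeric(0))
  unique(canonical_kmers(paste(seqs, collapse = "N"), k = k))
}

# Seeded integer hash of k-mer values, exact in double arithmetic (values and
# all intermediates stay below 2^53). 31-bit output range.
hash_kmers <- function(v, seed = 0L) {
  M <- 2147483647
  s <- as.numeric(seed) %% M
  h <- v %% M
  h <- (h * 1103515 + (v %/% M) * 1282163 + s) %% M
  (h * 1103515 + 12345) %% M
}

reverse_complement <- function(seq) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

# Restore-on-exit seeded evaluation so package randomness never disturbs the
# caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
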