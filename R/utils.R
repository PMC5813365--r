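# Shared low-level helpers. Sequences are plain uppercase character strings
# over {A,C,G,T,N}; coordinates are 0-based half-open internally.

#' Reverse complement of DNA strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase + RNA->DNA normalization.
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

assert_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, substr(x[bad][1L], 1L, 40L)), call. = FALSE)
  }
  invisible(x)
}

# Hamming distance on integer (utf8) vectors; N (78) never matches anything,
# including another N.
.N_INT <- 78L

hamming_int <- function(a, b) {
  sum(a != b | (a == .N_INT & b == .N_INT))
}

# Deterministic sub-seed derivation; keeps results within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

# Run `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# All k-length substrings of one string (n - k + 1 of them, in order).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
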