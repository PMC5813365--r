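# Pre-processing: 3' adapter trimming, symmetric barcode clipping, and read
# length filtering. Runs before the alignment cascade; quality strings are
# carried through the trims but never used for filtering.

#' Trimming / filtering specification
#'
#' @param adapter3 3' adapter sequence, or "" when the input is already
#'   adapter-trimmed.
#' @param barcode_n number of bases clipped from each end after adapter
#'   removal (default 0).
#' @param min_len,max_len retained read length band (defaults 15 and 32 nt,
#'   the two alignment length bands together).
#' @param min_adapter_overlap minimum adapter prefix length required to trim
#'   (default 6).
#' @param max_adapter_mismatch_rate maximum fraction of mismatches in the
#'   adapter match (default 0.1).
#' @return object of class `trim_spec`.
#' @export
trim_spec <- function(adapter3 = "", barcode_n = 0L, min_len = 15L,
                      max_len = 32L, min_adapter_overlap = 6L,
                      max_adapter_mismatch_rate = 0.1) {
  adapter3 <- normalize_seq(adapter3)
  if (nzchar(adapter3)) assert_dna(adapter3, "adapter")
  stopifnot(min_len <= max_len, barcode_n >= 0L, min_adapter_overlap >= 1L,
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate < 1)
  structure(list(adapter3 = adapter3, barcode_n = as.integer(barcode_n),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate),
            class = "trim_spec")
}

#' Trim the 3' adapter from one read
#'
#' The read is truncated at the leftmost position where a prefix of the
#' adapter of length >= `min_adapter_overlap` matches with mismatch rate
#' <= `max_adapter_mismatch_rate` (Hamming, no indels; N never matches).
#' With an empty adapter the read is returned unchanged; with no match the
#' read is returned unchanged and flagged untrimmed.
#'
#' @param sequence read sequence.
#' @param spec a [trim_spec()].
#' @param quality optional quality string, truncated alongside.
#' @return list(sequence, quality, trimmed).
#' @export
trim_adapter <- function(sequence, spec, quality = NULL) {
  if (!nzchar(spec$adapter3)) {
    return(list(sequence = sequence, quality = quality, trimmed = TRUE))
  }
  pos <- adapter_match_pos(sequence, spec)
  if (is.na(pos)) {
    return(list(sequence = sequence, quality = quality, trimmed = FALSE))
  }
  list(sequence = substr(sequence, 1L, pos - 1L),
       quality = if (is.null(quality)) NULL else substr(quality, 1L, pos - 1L),
       trimmed = TRUE)
}

# Leftmost 1-based start of an acceptable adapter prefix match, or NA.
adapter_match_pos <- function(sequence, spec) {
  n <- nchar(sequence)
  a <- utf8ToInt(spec$adapter3)
  s <- utf8ToInt(sequence)
  la <- length(a)
  if (n < spec$min_adapter_overlap) return(NA_integer_)
  for (start in seq_len(n - spec$min_adapter_overlap + 1L)) {
    ov <- min(la, n - start + 1L)
    seg <- s[start:(start + ov - 1L)]
    ad <- a[seq_len(ov)]
    mm <- sum(seg != ad | (seg == .N_INT & ad == .N_INT))
    if (mm <= spec$max_adapter_mismatch_rate * ov) return(start)
  }
  NA_integer_
}

#' Clip barcode bases from both ends
#'
#' Removes `barcode_n` bases from the 5' end and `barcode_n` bases from the
#' 3' end of the adapter-clipped read; reads shorter than `2 * barcode_n + 1`
#' are discarded (NULL).
#'
#' @inheritParams trim_adapter
#' @return list(sequence, quality) or NULL when discarded.
#' @export
trim_barcode <- function(sequence, spec, quality = NULL) {
  b <- spec$barcode_n
  if (b == 0L) return(list(sequence = sequence, quality = quality))
  n <- nchar(sequence)
  if (2L * b >= n) return(NULL)
  list(sequence = substr(sequence, b + 1L, n - b),
       quality = if (is.null(quality)) NULL else substr(quality, b + 1L, n - b))
}

#' Keep a read iff its length is inside the configured band
#' @inheritParams trim_adapter
#' @return TRUE (kept) or FALSE (discarded).
#' @export
length_filter <- function(sequence, spec) {
  n <- nchar(sequence)
  n >= spec$min_len & n <= spec$max_len
}

#' Preprocess one sample: adapter -> barcode -> length filter
#'
#' @param reads data.frame (read_id, sequence, quality) from [read_fastq()].
#' @param spec a [trim_spec()].
#' @return list with `reads` (kept, trimmed) and `stats`: counts in/kept/
#'   discarded by reason, plus the post-trim length histogram of kept reads.
#' @export
preprocess_sample <- function(reads, spec) {
  n_in <- nrow(reads)
  seqs <- reads$sequence
  quals <- if (is.null(reads$quality)) rep(NA_character_, n_in) else reads$quality
  untrimmed <- 0L
  if (n_in && nzchar(spec$adapter3)) {
    pos <- vapply(seqs, adapter_match_pos, 1L, spec = spec, USE.NAMES = FALSE)
    untrimmed <- sum(is.na(pos))
    cut <- ifelse(is.na(pos), nchar(seqs), pos - 1L)
    seqs <- substr(seqs, 1L, cut)
    quals <- ifelse(is.na(quals), quals, substr(quals, 1L, cut))
  }
  len <- nchar(seqs)
  b <- spec$barcode_n
  disc_barcode <- if (b > 0L) (2L * b >= len) else rep(FALSE, n_in)
  if (b > 0L) {
    seqs <- substr(seqs, b + 1L, len - b)
    quals <- ifelse(is.na(quals), quals, substr(quals, b + 1L, len - b))
    len <- pmax(len - 2L * b, 0L)
  }
  too_short <- !disc_barcode & len < spec$min_len
  too_long <- !disc_barcode & len > spec$max_len
  keep <- !(disc_barcode | too_short | too_long)
  kept <- data.frame(read_id = reads$read_id[keep], sequence = seqs[keep],
                     quality = quals[keep], stringsAsFactors = FALSE)
  disc <- c(barcode = sum(disc_barcode), too_short = sum(too_short),
            too_long = sum(too_long))
  hist_tab <- if (nrow(kept)) table(factor(nchar(kept$sequence),
                                           levels = spec$min_len:spec$max_len))
              else table(factor(integer(0), levels = spec$min_len:spec$max_len))
  stats <- list(reads_in = n_in, reads_kept = nrow(kept),
                discarded = as.list(disc), untrimmed = untrimmed,
                length_histogram = as.list(setNames(as.integer(hist_tab),
                                                    names(hist_tab))))
  list(reads = kept, stats = stats)
}
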