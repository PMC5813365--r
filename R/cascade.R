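# Four-tier alignment cascade. Every preprocessed read is consumed by exactly
# one tier: (1) target-organism transcripts, (2) target genome (feeding novel
# miRNA prediction), (3) pathogen k-mer screen, (4) cross-species miRNA
# precursors; otherwise it is UNALIGNED. Mismatches are Hamming only (no
# indels) and N never matches any base.

TIERS <- c("TIER1_TRANSCRIPT", "TIER2_GENOME", "TIER3_PATHOGEN", "TIER4_NTO",
           "UNALIGNED")

#' Alignment policy (length-banded mismatch allowances)
#'
#' Reads of 15-19 nt align with 0 mismatches, reads of 20-32 nt with at most
#' 1 mismatch; genome hits are capped at 5 loci for prediction eligibility;
#' cross-species matches are exact.
#'
#' @param short_band,long_band inclusive length ranges.
#' @param short_mm,long_mm mismatch allowance per band.
#' @param max_genome_loci multimapper cap for novel miRNA prediction.
#' @param nto_mismatches mismatch allowance against cross-species precursors.
#' @return object of class `alignment_policy`.
#' @export
alignment_policy <- function(short_band = c(15L, 19L), long_band = c(20L, 32L),
                             short_mm = 0L, long_mm = 1L, max_genome_loci = 5L,
                             nto_mismatches = 0L) {
  stopifnot(short_band[2] + 1L == long_band[1])
  structure(list(short_band = as.integer(short_band),
                 long_band = as.integer(long_band),
                 short_mm = as.integer(short_mm),
                 long_mm = as.integer(long_mm),
                 max_genome_loci = as.integer(max_genome_loci),
                 nto_mismatches = as.integer(nto_mismatches)),
            class = "alignment_policy")
}

#' Mismatch allowance for a read length under a policy
#' @param len read length(s).
#' @param policy an [alignment_policy()].
#' @return integer vector of allowances (NA outside both bands).
#' @export
band_mismatches <- function(len, policy) {
  ifelse(len >= policy$short_band[1] & len <= policy$short_band[2],
         policy$short_mm,
         ifelse(len >= policy$long_band[1] & len <= policy$long_band[2],
                policy$long_mm, NA_integer_))
}

#' Build a seeded substring index over a reference set
#'
#' Answers "all occurrences of query q with <= m mismatches (m in 0..1,
#' Hamming, no indels)" by pigeonhole seeding: the query is split in two
#' halves, each half is located exactly through a hashed k-mer table, and the
#' full-length Hamming distance is verified at every candidate start.
#'
#' @param references named character vector (id -> sequence) or data.frame
#'   with columns id, sequence.
#' @param seed_len seed k-mer length; must be <= floor(min query length / 2).
#' @return object of class `mismatch_index`.
#' @export
build_mismatch_index <- function(references, seed_len = 7L) {
  if (is.data.frame(references)) {
    references <- setNames(references$sequence, references$id)
  }
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  assert_dna(references, "reference")
  tab <- new.env(hash = TRUE, parent = emptyenv())
  ref_int <- lapply(references, utf8ToInt)
  for (r in seq_along(references)) {
    seq <- references[[r]]
    n <- nchar(seq)
    if (n < seed_len) next
    km <- kmers_of(seq, seed_len)
    keep <- !grepl("N", km, fixed = TRUE)
    pos <- which(keep)
    km <- km[keep]
    by_kmer <- split(pos, km)
    for (k in names(by_kmer)) {
      prev <- tab[[k]]
      entry <- cbind(rep.int(r, length(by_kmer[[k]])), by_kmer[[k]])
      tab[[k]] <- if (is.null(prev)) entry else rbind(prev, entry)
    }
  }
  structure(list(table = tab, seed_len = as.integer(seed_len),
                 ids = names(references), ref_int = ref_int,
                 ref_len = nchar(references)),
            class = "mismatch_index")
}

#' Query a mismatch index
#'
#' @param index a [build_mismatch_index()] result.
#' @param query query sequence (length >= 2 * seed_len).
#' @param max_mm 0 or 1 allowed mismatches.
#' @return data.frame(target_id, position (0-based), mismatches), one row per
#'   occurrence, best hits not yet filtered.
#' @export
query_index <- function(index, query, max_mm = 0L) {
  n <- nchar(query)
  k <- index$seed_len
  if (n < 2L * k) stop("query shorter than two seeds", call. = FALSE)
  h <- n %/% 2L
  # For <=1 mismatch at least one half is exact, so its leading seed is exact.
  offs <- c(0L, h)
  seeds <- substr(c(query, query), offs + 1L, offs + k)
  q <- utf8ToInt(query)
  out_ref <- integer(0); out_pos <- integer(0); out_mm <- integer(0)
  seen <- character(0)
  for (j in 1:2) {
    ent <- index$table[[seeds[j]]]
    if (is.null(ent)) next
    starts <- ent[, 2L] - offs[j]          # 1-based candidate start
    ok <- starts >= 1L & starts + n - 1L <= index$ref_len[ent[, 1L]]
    if (!any(ok)) next
    refs <- ent[ok, 1L]; starts <- starts[ok]
    key <- paste(refs, starts)
    new <- !(key %in% seen)
    seen <- c(seen, key[new])
    refs <- refs[new]; starts <- starts[new]
    for (i in seq_along(refs)) {
      seg <- index$ref_int[[refs[i]]][starts[i]:(starts[i] + n - 1L)]
      mm <- sum(seg != q | (seg == .N_INT & q == .N_INT))
      if (mm <= max_mm) {
        out_ref <- c(out_ref, refs[i]); out_pos <- c(out_pos, starts[i] - 1L)
        out_mm <- c(out_mm, mm)
      }
    }
  }
  data.frame(target_id = index$ids[out_ref], position = out_pos,
             mismatches = out_mm, stringsAsFactors = FALSE)
}

# Best-stratum (minimum mismatch) subset of a hit table.
best_stratum <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
}

#' Tier 1: align reads to target-organism transcripts
#'
#' Forward orientation only (transcripts are already oriented). A read maps
#' iff it occurs in some transcript within its length-band mismatch
#' allowance; all best-stratum hits are returned.
#'
#' @param reads data.frame (read_id, sequence).
#' @param transcripts a [transcript_set()].
#' @param policy an [alignment_policy()].
#' @param index optional prebuilt index over the transcripts.
#' @return list(hits, unmapped) where hits has read_id, target_id, target_kind,
#'   position, strand, mismatches.
#' @export
align_tier1 <- function(reads, transcripts, policy = alignment_policy(),
                        index = NULL) {
  if (nrow(transcripts) == 0L) stop("empty transcript set", call. = FALSE)
  if (is.null(index)) {
    index <- build_mismatch_index(
      setNames(transcripts$sequence, transcripts$transcript_id))
  }
  res <- align_forward(reads, index, policy)
  res$hits$target_kind <- rep("transcript", nrow(res$hits))
  res
}

align_forward <- function(reads, index, policy) {
  hit_list <- vector("list", nrow(reads))
  mapped <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    mm_allow <- band_mismatches(nchar(reads$sequence[i]), policy)
    if (is.na(mm_allow)) next
    h <- best_stratum(query_index(index, reads$sequence[i], mm_allow))
    if (nrow(h)) {
      h$read_id <- reads$read_id[i]
      h$strand <- "+"
      hit_list[[i]] <- h
      mapped[i] <- TRUE
    }
  }
  hits <- do.call(rbind, hit_list[mapped])
  if (is.null(hits)) {
    hits <- data.frame(target_id = character(0), position = integer(0),
                       mismatches = integer(0), read_id = character(0),
                       strand = character(0), stringsAsFactors = FALSE)
  }
  list(hits = hits[, c("read_id", "target_id", "position", "strand",
                       "mismatches")],
       unmapped = reads[!mapped, , drop = FALSE])
}

#' Tier 1 counting: class priority then equal split
#'
#' Each mapped read contributes total weight 1: its best-stratum hits are
#' restricted to the highest-priority sRNA class present (miRNA > piRNA >
#' snoRNA > snRNA > rRNA > novel_miRNA > family), then the weight is split
#' equally among the remaining distinct transcripts.
#'
#' @param hits hit table from [align_tier1()].
#' @param transcripts the [transcript_set()] aligned against.
#' @return named numeric vector of counts over all transcript ids.
#' @export
count_tier1 <- function(hits, transcripts) {
  counts <- setNames(numeric(nrow(transcripts)), transcripts$transcript_id)
  if (nrow(hits) == 0L) return(counts)
  cls <- setNames(transcripts$srna_class, transcripts$transcript_id)
  prio <- setNames(seq_along(SRNA_CLASSES), SRNA_CLASSES)
  for (rid in unique(hits$read_id)) {
    targets <- unique(hits$target_id[hits$read_id == rid])
    p <- prio[cls[targets]]
    targets <- targets[p == min(p)]
    counts[targets] <- counts[targets] + 1 / length(targets)
  }
  counts
}

#' Tier 2: align tier-1-unmapped reads to the target genome (both strands)
#'
#' A read with >= 1 locus within its mismatch allowance is consumed by tier 2.
#' Reads with more than `policy$max_genome_loci` best-stratum loci are flagged
#' multimappers: still tier-2-consumed, but excluded from novel miRNA
#' prediction.
#'
#' @param reads tier-1 unmapped reads.
#' @param genome named character vector (chrom -> sequence).
#' @param policy an [alignment_policy()].
#' @param index optional prebuilt genome index.
#' @return list(hits (prediction-eligible loci: read_id, chrom, start, end,
#'   strand, mismatches), multimapper_ids, mapped_ids, unmapped).
#' @export
align_tier2 <- function(reads, genome, policy = alignment_policy(),
                        index = NULL) {
  if (is.null(index)) index <- build_mismatch_index(genome)
  n <- nrow(reads)
  hit_list <- vector("list", n)
  mapped <- logical(n)
  multi <- logical(n)
  rc <- if (n) revcomp(reads$sequence) else character(0)
  for (i in seq_len(n)) {
    len <- nchar(reads$sequence[i])
    mm_allow <- band_mismatches(len, policy)
    if (is.na(mm_allow)) next
    fwd <- query_index(index, reads$sequence[i], mm_allow)
    rev <- query_index(index, rc[i], mm_allow)
    fwd$strand <- rep("+", nrow(fwd))
    rev$strand <- rep("-", nrow(rev))
    h <- best_stratum(rbind(fwd, rev))
    if (nrow(h) == 0L) next
    mapped[i] <- TRUE
    if (nrow(h) > policy$max_genome_loci) { multi[i] <- TRUE; next }
    hit_list[[i]] <- data.frame(read_id = reads$read_id[i],
                                chrom = h$target_id, start = h$position,
                                end = h$position + len, strand = h$strand,
                                mismatches = h$mismatches,
                                stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_list[mapped & !multi])
  if (is.null(hits)) {
    hits <- data.frame(read_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), mismatches = integer(0),
                       stringsAsFactors = FALSE)
  }
  list(hits = hits, multimapper_ids = reads$read_id[multi],
       mapped_ids = reads$read_id[mapped],
       unmapped = reads[!mapped, , drop = FALSE])
}

#' Tier 4: exact alignment to cross-species miRNA precursors
#'
#' Exact substring match (0 mismatches) against non-target-organism precursor
#' sequences; counts follow the tier-1 rule (all records are class miRNA).
#'
#' @param reads reads unmapped by tiers 1-3.
#' @param nto_precursors [transcript_set()] of precursors, or named vector.
#' @param index optional prebuilt index.
#' @return list(hits, counts, unmapped).
#' @export
align_tier4 <- function(reads, nto_precursors, index = NULL) {
  if (is.data.frame(nto_precursors)) {
    ref <- setNames(nto_precursors$sequence, nto_precursors$transcript_id)
  } else ref <- nto_precursors
  if (is.null(index)) index <- build_mismatch_index(ref)
  policy0 <- alignment_policy(short_mm = 0L, long_mm = 0L)
  res <- align_forward(reads, index, policy0)
  ts <- transcript_set(names(ref), "miRNA", "NTO", unname(ref))
  counts <- count_tier1(res$hits, ts)
  list(hits = res$hits, counts = counts, unmapped = res$unmapped)
}

#' Run the full alignment cascade on one sample
#'
#' In `model` mode, tiers 1 (transcripts) -> 2 (genome) -> 3 (pathogen
#' k-mers) -> 4 (cross-species precursors) are applied with strict precedence:
#' a read consumed at one tier never reaches the next. In `non_model` mode
#' only the tier-4-style exact alignment against the stored known + novel
#' miRNA/family catalog is applied.
#'
#' @param reads preprocessed reads (read_id, sequence).
#' @param refs list with elements `transcripts` ([transcript_set()]), `genome`
#'   (named vector), `kmer_db` ([build_kmer_db()]), `taxonomy`, and `nto`
#'   (transcript_set or named vector) in model mode; `catalog_transcripts`
#'   in non_model mode.
#' @param policy an [alignment_policy()].
#' @param mode "model" or "non_model".
#' @return list: assignments (read_id, tier), counts (tier-1 transcript
#'   counts), nto_counts, tier2 result (for prediction), tier3
#'   classifications, summary (per-tier totals).
#' @export
run_cascade <- function(reads, refs, policy = alignment_policy(),
                        mode = c("model", "non_model")) {
  mode <- match.arg(mode)
  tier <- setNames(rep("UNALIGNED", nrow(reads)), reads$read_id)
  if (mode == "non_model") {
    if (is.null(refs$catalog_transcripts)) {
      stop("non_model mode requires refs$catalog_transcripts", call. = FALSE)
    }
    t4 <- align_tier4(reads, refs$catalog_transcripts)
    tier[unique(t4$hits$read_id)] <- "TIER4_NTO"
    assignments <- data.frame(read_id = reads$read_id,
                              tier = unname(tier[reads$read_id]),
                              stringsAsFactors = FALSE)
    return(list(assignments = assignments, counts = NULL,
                nto_counts = t4$counts, tier2 = NULL, tier3 = NULL,
                summary = as.list(table(factor(assignments$tier,
                                               levels = TIERS)))))
  }
  for (need in c("transcripts", "genome", "kmer_db", "taxonomy", "nto")) {
    if (is.null(refs[[need]])) {
      stop("model mode requires refs$", need, call. = FALSE)
    }
  }
  t1 <- align_tier1(reads, refs$transcripts, policy)
  tier[setdiff(reads$read_id, t1$unmapped$read_id)] <- "TIER1_TRANSCRIPT"
  counts <- count_tier1(t1$hits, refs$transcripts)

  t2 <- align_tier2(t1$unmapped, refs$genome, policy)
  tier[t2$mapped_ids] <- "TIER2_GENOME"

  cl <- classify_reads(t2$unmapped, refs$kmer_db, refs$taxonomy)
  t3_ids <- cl$read_id[!is.na(cl$taxon_id)]
  tier[t3_ids] <- "TIER3_PATHOGEN"
  t3_unmapped <- t2$unmapped[!t2$unmapped$read_id %in% t3_ids, , drop = FALSE]

  t4 <- align_tier4(t3_unmapped, refs$nto)
  tier[unique(t4$hits$read_id)] <- "TIER4_NTO"

  assignments <- data.frame(read_id = reads$read_id,
                            tier = unname(tier[reads$read_id]),
                            stringsAsFactors = FALSE)
  list(assignments = assignments, counts = counts, nto_counts = t4$counts,
       tier2 = t2, tier3 = cl[!is.na(cl$taxon_id), , drop = FALSE],
       summary = as.list(table(factor(assignments$tier, levels = TIERS))))
}
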