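# Novel miRNA prediction: cluster prediction-eligible genomic reads, excise
# candidate precursor windows, fold them (Nussinov pair maximization with GU
# wobble), score them with an explicit 5-term hairpin score, test structure
# significance against a dinucleotide-preserving shuffle null, and register
# survivors of the three quality criteria (score > 10, no tRNA/rRNA decoy
# similarity, shuffle p <= 0.05) in a named catalog.

#' Quality criteria for novel miRNA registration
#'
#' @param min_score hairpin score threshold; strict `>` (default 10).
#' @param max_randfold_p shuffle p-value threshold; inclusive `<=`
#'   (default 0.05).
#' @param decoy_match_len exact shared k-mer length defining tRNA/rRNA
#'   similarity (default 20).
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_score = 10, max_randfold_p = 0.05,
                            decoy_match_len = 20L) {
  stopifnot(min_score > 0, max_randfold_p > 0, decoy_match_len > 0)
  structure(list(min_score = min_score, max_randfold_p = max_randfold_p,
                 decoy_match_len = as.integer(decoy_match_len)),
            class = "filter_criteria")
}

#' Cluster prediction-eligible genome hits
#'
#' Single-linkage clustering of read intervals per chromosome and strand with
#' a maximum gap of `gap` nt; clusters with fewer than `min_reads` reads are
#' dropped.
#'
#' @param genome_hits hit table from [align_tier2()] (read_id, chrom, start,
#'   end, strand).
#' @param gap maximum gap joining two reads (default 30).
#' @param min_reads minimum reads per cluster (default 2).
#' @return list of clusters, each a data.frame of the member hits.
#' @export
cluster_reads <- function(genome_hits, gap = 30L, min_reads = 2L) {
  if (nrow(genome_hits) == 0L) return(list())
  clusters <- list()
  for (key in unique(paste(genome_hits$chrom, genome_hits$strand))) {
    sub <- genome_hits[paste(genome_hits$chrom, genome_hits$strand) == key, ,
                       drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L
    grp[1L] <- g
    max_end <- sub$end[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] - max_end > gap) g <- g + 1L
      grp[i] <- g
      max_end <- max(max_end, sub$end[i])
    }
    clusters <- c(clusters, split(sub, grp))
  }
  clusters <- clusters[vapply(clusters, nrow, 0L) >= min_reads]
  unname(clusters)
}

# Modal (most frequent) read interval of a cluster; ties -> leftmost.
modal_interval <- function(cluster) {
  key <- paste(cluster$start, cluster$end)
  tab <- table(key)
  best <- names(tab)[tab == max(tab)]
  picks <- cluster[key %in% best, c("start", "end")]
  picks <- picks[order(picks$start, picks$end), ]
  as.integer(picks[1L, ])
}

#' Excise candidate precursor windows around a read cluster
#'
#' The modal read interval is the putative mature. Two windows are excised:
#' A = `[mature_start - 15, mature_start + 95)` (mature on the 5' arm) and
#' B = `[mature_end - 95, mature_end + 15)` (mature on the 3' arm), clipped to
#' chromosome bounds; minus-strand windows are reverse-complemented. Windows
#' shorter than mature length + 18 are dropped.
#'
#' @param cluster one cluster from [cluster_reads()].
#' @param genome named character vector of chromosome sequences.
#' @return list of candidate shells: chrom, strand, pre_start/pre_end
#'   (genomic, 0-based half-open), precursor_seq, mature offset/length in
#'   precursor orientation, read 5' starts in precursor orientation, counts.
#' @export
excise_candidates <- function(cluster, genome) {
  chrom <- cluster$chrom[1L]
  strand <- cluster$strand[1L]
  chrom_len <- nchar(genome[[chrom]])
  mat <- modal_interval(cluster)
  ms <- mat[1L]; me <- mat[2L]
  mat_len <- me - ms
  windows <- list(c(max(0L, ms - 15L), min(chrom_len, ms + 95L)),
                  c(max(0L, me - 95L), min(chrom_len, me + 15L)))
  out <- list()
  for (w in windows) {
    ws <- w[1L]; we <- w[2L]
    if (we - ws < mat_len + 18L) next
    if (ms < ws || me > we) next
    seq <- substr(genome[[chrom]], ws + 1L, we)
    win_len <- we - ws
    if (strand == "+") {
      m_off <- ms - ws
      starts <- cluster$start - ws
    } else {
      seq <- revcomp(seq)
      m_off <- we - me
      starts <- we - cluster$end
    }
    out[[length(out) + 1L]] <- list(
      chrom = chrom, strand = strand, pre_start = ws, pre_end = we,
      precursor_seq = seq, mature_offset = m_off, mature_len = mat_len,
      read_starts = starts, read_lens = cluster$end - cluster$start,
      mature_count = sum(cluster$start == ms & cluster$end == me))
  }
  out
}

#' Fold a sequence by Nussinov base-pair maximization
#'
#' Watson-Crick plus GU wobble pairs, minimum loop length 3; the traceback
#' prefers pairings over skips and scans partners outside-in, keeping stems
#' contiguous.
#'
#' @param seq DNA sequence (length >= 18 for hairpin candidates; any length
#'   >= 1 folds).
#' @return list(structure (dot-bracket), n_pairs, pairs (0-based partner or
#'   -1 per position)).
#' @export
fold_hairpin <- function(seq) {
  .nussinov(seq)
}

#' Score a hairpin candidate
#'
#' `score = 2*log2(1 + mature_count) + 3*[valid star read present] +
#' 8*pairedness(mature) + 5*precision - 10*[mature overlaps the loop]`, where
#' pairedness is the fraction of mature bases paired in the stem, precision
#' the fraction of mature-arm reads sharing the modal 5' start, and a star
#' read is a non-mature-overlapping cluster read whose 3' end lies 0-4 nt
#' beyond the pairing partner of the mature 5' end (the 3'-overhang of a
#' Dicer duplex).
#'
#' @param cand candidate shell from [excise_candidates()], with `fold`
#'   attached (a [fold_hairpin()] result).
#' @return the candidate with fields `score`, `star_count`, `star_interval`
#'   (precursor coordinates, or NULL), `pairedness`, `precision` added.
#' @export
score_candidate <- function(cand) {
  fold <- cand$fold
  pt <- fold$pairs
  ms <- cand$mature_offset            # 0-based in precursor orientation
  me <- ms + cand$mature_len
  mat_idx <- (ms + 1L):me             # 1-based indices into pt
  paired <- pt[mat_idx] >= 0L
  pairedness <- mean(paired)

  # loop = innermost unpaired gap: positions between a pair (i, pt[i]) with no
  # pairs inside
  in_loop <- function(lo, hi) any(mat_idx - 1L > lo & mat_idx - 1L < hi)
  loop_overlap <- FALSE
  for (i in which(pt >= 0L & pt > seq_along(pt) - 1L)) {
    lo <- i - 1L; hi <- pt[i]
    if (hi - lo >= 2L && all(pt[(lo + 2L):hi] < 0L)) {
      if (in_loop(lo, hi)) loop_overlap <- TRUE
    }
  }

  # reads on the mature arm: 5' start within 3 nt of the mature start
  on_mature <- abs(cand$read_starts - ms) <= 3L
  precision <- if (any(on_mature)) {
    starts <- cand$read_starts[on_mature]
    max(table(starts)) / length(starts)
  } else 0

  star_ok <- FALSE
  star_count <- 0L
  star_interval <- NULL
  if (any(paired)) {
    partners <- pt[mat_idx][paired]
    star_lo <- min(partners); star_hi <- max(partners)  # 0-based
    expected_end <- pt[mat_idx[which(paired)[1L]]] + 1L + 2L  # 2-nt 3' overhang
    ends <- cand$read_starts + cand$read_lens
    overlaps_mature <- cand$read_starts < me & ends > ms
    is_star <- !overlaps_mature & (ends - (expected_end - 2L)) >= 0L &
      (ends - (expected_end - 2L)) <= 4L
    star_count <- sum(is_star)
    star_ok <- star_count >= 1L
    star_interval <- c(star_lo, star_hi + 1L)
  }

  cand$pairedness <- pairedness
  cand$precision <- precision
  cand$star_count <- star_count
  cand$star_interval <- star_interval
  cand$score <- 2 * log2(1 + cand$mature_count) + 3 * star_ok +
    8 * pairedness + 5 * precision - 10 * loop_overlap
  cand
}

#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Uniformly samples a sequence with the identical dinucleotide multiset and
#' identical first and last nucleotide, via random Euler paths on the
#' dinucleotide multigraph (random last-edge arborescence with rejection).
#'
#' @param seq sequence (length >= 3 for a non-trivial shuffle).
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return shuffled sequence.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  with_seed(seed, dinucleotide_shuffle_impl(seq))
}

dinucleotide_shuffle_impl <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (n < 3L || length(unique(ch)) == 1L) return(seq)
  last <- ch[n]
  verts <- unique(ch)
  # outgoing edge lists
  out <- split(ch[-1L], factor(ch[-n], levels = verts))
  repeat {
    last_edge <- vapply(verts, function(v) {
      e <- out[[v]]
      if (v == last || length(e) == 0L) NA_character_
      else e[[sample.int(length(e), 1L)]]
    }, "")
    # arborescence check: from every vertex with a last edge, following last
    # edges must reach `last`
    ok <- TRUE
    for (v in verts) {
      if (is.na(last_edge[[v]])) next
      cur <- v
      steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- lapply(setNames(verts, verts), function(v) {
    e <- out[[v]]
    if (is.na(last_edge[[v]])) {
      if (length(e)) e[sample.int(length(e))] else character(0)
    } else {
      idx <- which(e == last_edge[[v]])[1L]
      rest <- e[-idx]
      c(if (length(rest)) rest[sample.int(length(rest))] else character(0),
        e[idx])
    }
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1L] <- ch[1L]
  cur <- ch[1L]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Empirical structure p-value against the dinucleotide-shuffle null
#'
#' `p = (1 + #{shuffles folding with >= as many pairs as the original}) /
#' (n_shuffles + 1)`; the attainable floor with the default 99 shuffles is
#' 0.01.
#'
#' @param seq precursor sequence (length >= 18).
#' @param n_shuffles number of shuffles (default 99).
#' @param seed integer seed.
#' @return p-value in `[1/(n_shuffles+1), 1]`.
#' @export
randfold_p <- function(seq, n_shuffles = 99L, seed = 1L) {
  obs <- fold_hairpin(seq)$n_pairs
  ge <- 0L
  for (i in seq_len(n_shuffles)) {
    s <- dinucleotide_shuffle(seq, derive_seed(seed, i))
    if (fold_hairpin(s)$n_pairs >= obs) ge <- ge + 1L
  }
  (1 + ge) / (n_shuffles + 1)
}

#' Flag sequence similarity to tRNA/rRNA decoys
#'
#' A precursor is decoy-similar iff it shares at least one exact `k`-mer
#' (default 20) with any decoy sequence, on either strand.
#'
#' @param precursor_seq character vector of precursor sequences.
#' @param decoys named character vector of tRNA/rRNA sequences.
#' @param k shared k-mer length.
#' @return logical vector.
#' @export
decoy_similarity <- function(precursor_seq, decoys, k = 20L) {
  if (length(decoys) == 0L) {
    warning("empty decoy set; no similarity flagged", call. = FALSE)
    return(rep(FALSE, length(precursor_seq)))
  }
  decoy_kmers <- unique(unlist(lapply(c(decoys, revcomp(decoys)), kmers_of,
                                      k = k), use.names = FALSE))
  vapply(precursor_seq, function(p) {
    any(kmers_of(p, k) %in% decoy_kmers)
  }, TRUE, USE.NAMES = FALSE)
}

#' Create an empty novel miRNA catalog
#' @param organism organism prefix used in catalog names.
#' @return empty catalog data.frame with attribute `organism`.
#' @export
new_catalog <- function(organism = "syn") {
  cat <- data.frame(name = character(0), organism = character(0),
                    chrom = character(0), strand = character(0),
                    pre_start = integer(0), pre_end = integer(0),
                    mature_start = integer(0), mature_end = integer(0),
                    star_start = integer(0), star_end = integer(0),
                    mature_arm = character(0), precursor_seq = character(0),
                    structure = character(0), score = numeric(0),
                    randfold_p = numeric(0), mature_count = numeric(0),
                    star_count = numeric(0), software_version = character(0),
                    stringsAsFactors = FALSE)
  attr(cat, "organism") <- organism
  cat
}

#' Apply the three quality criteria and register survivors
#'
#' Accept iff score > `min_score` (strict), not decoy-similar, and shuffle
#' p <= `max_randfold_p` (inclusive). Accepted candidates are deduplicated
#' against the catalog by precursor sequence (counts merged), serial numbers
#' are assigned in genomic order (chromosome, then start), and the mature arm
#' is named -5p/-3p.
#'
#' @param cands list of fully scored candidates (with `fold`, `score`,
#'   `randfold_p`, `decoy_similar` fields).
#' @param criteria a [filter_criteria()].
#' @param catalog an existing catalog ([new_catalog()]).
#' @return list(catalog, accepted (names), rejected (data.frame candidate,
#'   reason)).
#' @export
filter_and_register <- function(cands, criteria = filter_criteria(),
                                catalog = new_catalog()) {
  reasons <- character(length(cands))
  pass <- logical(length(cands))
  for (i in seq_along(cands)) {
    cand <- cands[[i]]
    r <- character(0)
    if (!(cand$score > criteria$min_score)) r <- c(r, "score")
    if (isTRUE(cand$decoy_similar)) r <- c(r, "decoy_similarity")
    if (!(cand$randfold_p <= criteria$max_randfold_p)) r <- c(r, "randfold_p")
    if (length(r)) reasons[i] <- paste(r, collapse = "+") else pass[i] <- TRUE
  }
  accepted_cands <- cands[pass]
  rejected <- data.frame(
    chrom = vapply(cands[!pass], `[[`, "", "chrom"),
    pre_start = vapply(cands[!pass], function(cand) as.numeric(cand$pre_start), 0),
    reason = reasons[!pass], stringsAsFactors = FALSE)

  organism <- attr(catalog, "organism")
  if (is.null(organism)) organism <- "syn"
  accepted_names <- character(0)
  if (length(accepted_cands)) {
    ord <- order(vapply(accepted_cands, `[[`, "", "chrom"),
                 vapply(accepted_cands,
                        function(cand) as.numeric(cand$pre_start), 0))
    for (cand in accepted_cands[ord]) {
      dup <- which(catalog$precursor_seq == cand$precursor_seq)
      if (length(dup)) {
        catalog$mature_count[dup[1L]] <-
          catalog$mature_count[dup[1L]] + cand$mature_count
        catalog$star_count[dup[1L]] <-
          catalog$star_count[dup[1L]] + cand$star_count
        next
      }
      serial <- nrow(catalog) + 1L
      name <- sprintf("%s-oasis-mir-%d", organism, serial)
      arm <- if (cand$mature_offset + cand$mature_len / 2 <=
                 nchar(cand$precursor_seq) / 2) "5p" else "3p"
      gen <- precursor_to_genomic(cand)
      entry <- data.frame(
        name = name, organism = organism, chrom = cand$chrom,
        strand = cand$strand, pre_start = cand$pre_start,
        pre_end = cand$pre_end, mature_start = gen$mature[1L],
        mature_end = gen$mature[2L], star_start = gen$star[1L],
        star_end = gen$star[2L],
        mature_arm = arm,
        precursor_seq = cand$precursor_seq,
        structure = cand$fold$structure, score = cand$score,
        randfold_p = cand$randfold_p, mature_count = cand$mature_count,
        star_count = cand$star_count,
        software_version = as.character(utils::packageVersion("srnacascade")),
        stringsAsFactors = FALSE)
      org <- attr(catalog, "organism")
      catalog <- rbind(catalog, entry)
      attr(catalog, "organism") <- org
      accepted_names <- c(accepted_names, name)
    }
  }
  list(catalog = catalog, accepted = accepted_names, rejected = rejected)
}

# Convert precursor-orientation mature/star intervals to genomic 0-based
# half-open coordinates.
precursor_to_genomic <- function(cand) {
  conv <- function(lo, hi) {
    if (cand$strand == "+") c(cand$pre_start + lo, cand$pre_start + hi)
    else c(cand$pre_end - hi, cand$pre_end - lo)
  }
  mature <- conv(cand$mature_offset, cand$mature_offset + cand$mature_len)
  star <- if (is.null(cand$star_interval)) mature
          else conv(cand$star_interval[1L], cand$star_interval[2L])
  list(mature = mature, star = star)
}

#' Predict novel miRNAs from tier-2 genome hits
#'
#' Full prediction path: cluster eligible hits, excise candidate windows,
#' fold, score, shuffle-test, decoy-screen, and register survivors. At most
#' one candidate (the best-scoring passing window) is registered per read
#' cluster.
#'
#' @param genome_hits prediction-eligible hits from [align_tier2()].
#' @param genome named chromosome sequences.
#' @param decoys tRNA/rRNA decoy sequences.
#' @param criteria a [filter_criteria()].
#' @param catalog existing catalog.
#' @param n_shuffles shuffles for the structure p-value.
#' @param seed integer seed.
#' @return as [filter_and_register()], plus `candidates` (all scored shells).
#' @export
predict_novel_mirnas <- function(genome_hits, genome, decoys,
                                 criteria = filter_criteria(),
                                 catalog = new_catalog(), n_shuffles = 99L,
                                 seed = 1L) {
  clusters <- cluster_reads(genome_hits)
  all_cands <- list()
  selected <- list()
  for (ci in seq_along(clusters)) {
    shells <- excise_candidates(clusters[[ci]], genome)
    scored <- list()
    for (si in seq_along(shells)) {
      cand <- shells[[si]]
      cand$fold <- fold_hairpin(cand$precursor_seq)
      cand <- score_candidate(cand)
      cand$randfold_p <- randfold_p(cand$precursor_seq, n_shuffles,
                                    derive_seed(seed, ci * 17L + si))
      cand$decoy_similar <- decoy_similarity(cand$precursor_seq, decoys,
                                             criteria$decoy_match_len)
      scored[[si]] <- cand
    }
    all_cands <- c(all_cands, scored)
    passing <- Filter(function(cand) {
      cand$score > criteria$min_score && !cand$decoy_similar &&
        cand$randfold_p <= criteria$max_randfold_p
    }, scored)
    pick <- if (length(passing)) {
      passing[[which.max(vapply(passing, `[[`, 0, "score"))]]
    } else if (length(scored)) {
      scored[[which.max(vapply(scored, `[[`, 0, "score"))]]
    } else NULL
    if (!is.null(pick)) selected[[length(selected) + 1L]] <- pick
  }
  res <- filter_and_register(selected, criteria, catalog)
  res$candidates <- all_cands
  res
}
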