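# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Hamming scan: all occurrences of `query` in `subject` with
# <= max_mm mismatches (N never matches, including N vs N). Returns 0-based
# start positions.
bf_hamming_scan <- function(query, subject, max_mm) {
  q <- utf8ToInt(query)
  s <- utf8ToInt(subject)
  n <- length(q)
  if (length(s) < n) return(integer(0))
  hits <- integer(0)
  for (start in 0:(length(s) - n)) {
    seg <- s[(start + 1):(start + n)]
    mm <- sum(seg != q | (seg == 78L & q == 78L))
    if (mm <= max_mm) hits <- c(hits, start)
  }
  hits
}

# Exhaustive enumeration of nested secondary structures (Watson-Crick + GU,
# min loop 3): maximum number of base pairs. Pure recursion, no memoization,
# independent of the package's DP.
bf_max_pairs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)
    for (k in (i + 4):j) {
      if (!ok(ch[i], ch[k])) next
      v <- 1 + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0
      if (v > best) best <- v
    }
    best
  }
  if (length(ch) < 5) return(0)
  rec(1, length(ch))
}

# AUC as the fraction of concordant (positive, negative) score pairs, ties
# counting one half.
bf_auc_pairs <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive Kraken path scoring on a small taxonomy: enumerate every
# root-to-leaf path, sum hit counts along it, take deepest counted node on
# the arg-max path(s), LCA on ties.
bf_kraken <- function(counts, nodes) {
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  path_up <- function(t) {
    p <- character(0)
    while (!is.na(t)) { p <- c(p, t); t <- parent[[t]] }
    p
  }
  leaves <- setdiff(nodes$taxon_id, nodes$parent_id[!is.na(nodes$parent_id)])
  paths <- lapply(leaves, path_up)
  sc <- vapply(paths, function(p) sum(counts[intersect(p, names(counts))]), 0)
  cand <- unique(vapply(paths[sc == max(sc)], function(p) {
    hit <- p[p %in% names(counts)]
    hit[1]
  }, ""))
  if (length(cand) == 1) return(cand)
  common <- path_up(cand[1])
  for (t in cand[-1]) common <- intersect(common, path_up(t))
  common[1]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Dinucleotide count vector of a sequence, as a named table keyed "XY".
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
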