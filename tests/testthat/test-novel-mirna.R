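test_that("read clusters form by single linkage with a 30-nt gap", {
  hits <- function(starts, len = 22) {
    data.frame(read_id = paste0("r", seq_along(starts)), chrom = "chr1",
               start = starts, end = starts + len, strand = "+",
               mismatches = 0L, stringsAsFactors = FALSE)
  }
  # two reads 10 nt apart: one cluster
  expect_length(cluster_reads(hits(c(100, 132))), 1L)
  # two reads 31 nt apart: two clusters, both dropped as singletons
  expect_length(cluster_reads(hits(c(100, 153))), 0L)
  # exactly 30 nt gap still joins
  expect_length(cluster_reads(hits(c(100, 152))), 1L)
  # mature + star reads on both arms form a single cluster
  cl <- cluster_reads(hits(c(rep(100, 50), rep(140, 5))))
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 55L)
})

test_that("candidate excision follows the window/clipping conventions", {
  genome <- c(chr1 = random_seq(400))
  cl <- data.frame(read_id = c("a", "b"), chrom = "chr1",
                   start = c(150, 150), end = c(172, 172), strand = "+",
                   mismatches = 0L, stringsAsFactors = FALSE)
  cands <- excise_candidates(cl, genome)
  expect_length(cands, 2L)
  expect_equal(cands[[1]]$pre_start, 135)   # mature_start - 15
  expect_equal(cands[[1]]$pre_end, 245)     # mature_start + 95
  expect_equal(cands[[2]]$pre_start, 77)    # mature_end - 95
  expect_equal(cands[[2]]$pre_end, 187)     # mature_end + 15
  expect_equal(cands[[1]]$precursor_seq,
               substr(genome[["chr1"]], 136, 245))

  # cluster near the chromosome start: window clipped at 0
  cl0 <- transform(cl, start = c(3, 3), end = c(25, 25))
  c0 <- excise_candidates(cl0, genome)
  expect_equal(c0[[1]]$pre_start, 0)

  # minus-strand cluster: precursor is the reverse complement of the slice
  clm <- transform(cl, strand = "-")
  cm <- excise_candidates(clm, genome)
  expect_equal(cm[[1]]$precursor_seq,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(
                 substr(genome[["chr1"]], 136, 245)))))
  # mature offset measured from the window's 3' genomic end on minus strand
  expect_equal(cm[[1]]$mature_offset, 245 - 172)
})

test_that("Nussinov fold matches exhaustive enumeration on short sequences", {
  expect_equal(fold_hairpin("GGGAAACCC")$structure, "(((...)))")
  expect_equal(fold_hairpin("GGGAAACCC")$n_pairs, 3L)
  expect_equal(fold_hairpin("AAAAAAAAA")$n_pairs, 0L)
  expect_equal(fold_hairpin("AAAAAAAAA")$structure, ".........")

  set.seed(53)
  # sampled 9-mers plus random sequences up to 12 nt
  for (i in 1:120) {
    s <- random_seq(sample(5:12, 1))
    f <- fold_hairpin(s)
    expect_equal(f$n_pairs, bf_max_pairs(s), info = s)
    # structure is consistent: balanced and pairs only legal partners
    pt <- f$pairs
    paired <- which(pt >= 0)
    expect_equal(sum(pt >= 0), 2L * f$n_pairs)
    for (j in paired) {
      expect_equal(pt[pt[j] + 1] , j - 1L)     # involution
      expect_gte(abs(pt[j] - (j - 1L)), 4L)    # min loop 3
    }
  }
})

test_that("dinucleotide shuffle preserves composition, ends, and seed", {
  expect_equal(dinucleotide_shuffle("AAAAAA", 3), "AAAAAA")
  set.seed(61)
  for (i in 1:40) {
    s <- random_seq(sample(10:90, 1))
    sh <- dinucleotide_shuffle(s, i)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(s), nchar(s)),
                 substr(s, nchar(s), nchar(s)))
    expect_equal(dinucleotide_shuffle(s, i), sh)  # same seed, same output
  }
  # different seeds explore different shuffles
  s <- random_seq(60)
  expect_false(all(vapply(1:10, function(k)
    dinucleotide_shuffle(s, k) == dinucleotide_shuffle(s, k + 100), TRUE)))
})

test_that("shuffle p-value behaves at its extremes and floor", {
  expect_equal(randfold_p(strrep("A", 30), 99, 1), 1)
  # strong hairpin: 26-bp perfect stem, 6-nt loop
  left <- random_seq(26)
  hp <- paste0(left, "AACAAC",
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(left))))
  p <- randfold_p(hp, 99, 5)
  expect_lte(p, 0.05)
  expect_gte(p, 1 / 100)   # formula floor at 99 shuffles

  # structure p is non-increasing as the stem grows, at fixed shuffle count
  set.seed(71)
  stems <- c(6, 14, 26)
  ps <- vapply(stems, function(k) {
    l <- random_seq(k)
    seq <- paste0(l, "AACAAC",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(l))), random_seq(52 - 2 * k))
    mean(vapply(1:5, function(r) randfold_p(seq, 49, r), 0))
  }, 0)
  expect_true(ps[1] >= ps[2] && ps[2] >= ps[3])
})

test_that("decoy similarity is an exact shared 20-mer on either strand", {
  decoy <- random_seq(300)
  shared20 <- substr(decoy, 50, 69)
  pre_hit <- paste0(random_seq(30), shared20, random_seq(30))
  pre_rc <- paste0(random_seq(30),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(shared20))), random_seq(30))
  pre_19 <- paste0(random_seq(30), substr(shared20, 1, 19), random_seq(31))
  pre_rand <- random_seq(100)
  got <- decoy_similarity(c(pre_hit, pre_rc, pre_19, pre_rand),
                          c(trna1 = decoy))
  expect_equal(got, c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(decoy_similarity(pre_hit, character(0)), "empty decoy")
})

test_that("hairpin score follows its five-term arithmetic", {
  # ideal candidate: 31 identical mature reads, one star read with a 2-nt
  # 3' overhang, fully paired mature -> 2*log2(32) + 3 + 8 + 5 = 26
  left <- random_seq(26)
  hp <- paste0(left, "AACAAC",
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(left))))
  win <- paste0(random_seq(15), hp, random_seq(110 - 15 - nchar(hp)))
  fold <- fold_hairpin(win)
  ms <- 18L  # mature 3 nt into the stem (window offset 15 + 3)
  pt <- fold$pairs
  star_end <- pt[ms + 1] + 1 + 2
  cand <- list(chrom = "chr1", strand = "+", pre_start = 0, pre_end = 110,
               precursor_seq = win, mature_offset = ms, mature_len = 22,
               read_starts = c(rep(ms, 31), star_end - 22),
               read_lens = rep(22, 32), mature_count = 31, fold = fold)
  sc <- score_candidate(cand)
  expect_equal(sc$pairedness, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$star_count, 1L)
  expect_equal(sc$score, 2 * log2(32) + 3 + 8 + 5)

  # single read, no star: score drops below the acceptance threshold
  weak <- cand
  weak$read_starts <- ms; weak$read_lens <- 22; weak$mature_count <- 1
  expect_lt(score_candidate(weak)$score, 26)
  expect_equal(score_candidate(weak)$score, 2 * log2(2) + 8 + 5)
})

test_that("three-criteria filter honors strict and inclusive thresholds", {
  base <- list(chrom = "chr1", strand = "+", pre_start = 100, pre_end = 210,
               precursor_seq = random_seq(110), mature_offset = 18,
               mature_len = 22, mature_count = 10, star_count = 1,
               star_interval = c(60, 82),
               fold = fold_hairpin(random_seq(110)),
               decoy_similar = FALSE, randfold_p = 0.01, score = 15)
  crit <- filter_criteria()
  # score exactly 10 is rejected (strict >)
  c10 <- base; c10$score <- 10
  expect_equal(filter_and_register(list(c10), crit)$rejected$reason, "score")
  # randfold p exactly 0.05 passes that criterion (inclusive <=)
  c05 <- base; c05$randfold_p <- 0.05
  expect_equal(length(filter_and_register(list(c05), crit)$accepted), 1L)
  # decoy similarity alone rejects
  cd <- base; cd$decoy_similar <- TRUE
  expect_match(filter_and_register(list(cd), crit)$rejected$reason, "decoy")

  # duplicate precursor: not re-added, read counts merged
  res1 <- filter_and_register(list(base), crit)
  res2 <- filter_and_register(list(base), crit, res1$catalog)
  expect_equal(nrow(res2$catalog), 1L)
  expect_equal(res2$catalog$mature_count, 20)
  expect_length(res2$accepted, 0L)

  # serials assigned in genomic order
  b2 <- base; b2$pre_start <- 50; b2$pre_end <- 160
  b2$precursor_seq <- random_seq(110); b2$fold <- fold_hairpin(b2$precursor_seq)
  multi <- filter_and_register(list(base, b2), crit)
  expect_equal(multi$catalog$pre_start, c(50, 100))
  expect_equal(multi$catalog$name, c("syn-oasis-mir-1", "syn-oasis-mir-2"))
})

test_that("planted hairpins are recovered and decoy clusters rejected", {
  for (sd in c(101, 202)) {
    spec <- fixture_spec(seed = sd, read_error_rate = 0)
    host <- make_host(spec)
    sim <- simulate_sample(host, NULL, spec)
    pp <- preprocess_sample(sim$reads,
                            trim_spec(adapter3 = spec$sample$adapter3))
    t2 <- align_tier2(align_tier1(pp$reads, host$transcripts)$unmapped,
                      host$genome)
    pred <- predict_novel_mirnas(t2$hits, host$genome, host$decoys, seed = sd)
    found <- vapply(seq_len(nrow(host$hairpins)), function(i) {
      h <- host$hairpins[i, ]
      any(pred$catalog$pre_start < h$hp_end &
            pred$catalog$pre_end > h$hp_start)
    }, TRUE)
    expect_true(all(found), info = paste("seed", sd))
    expect_equal(nrow(pred$catalog), sum(found))  # no extra acceptances
    # filter decision is a pure function of candidate + criteria
    again <- filter_and_register(pred$candidates[1], filter_criteria())
    expect_equal(again$rejected$reason,
                 filter_and_register(pred$candidates[1],
                                     filter_criteria())$rejected$reason)
  }
})
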