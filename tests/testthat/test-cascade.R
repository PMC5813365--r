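test_that("mismatch index finds exact and 1-mismatch occurrences", {
  idx <- build_mismatch_index(c(r1 = "ACGTACGTAGGCTTAGGCATCGATTACGGA"))
  h0 <- query_index(idx, "ACGTACGTAGGCTTAG", 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$position, 0L)
  expect_equal(h0$mismatches, 0L)
  h1 <- query_index(idx, "ACGAACGTAGGCTTAG", 1)
  expect_equal(h1$mismatches, 1L)
  expect_equal(nrow(query_index(idx, "ACGAACGTAGGCTTAG", 0)), 0L)
  expect_error(build_mismatch_index(character(0)), "empty")
})

test_that("seeded index equals a brute-force Hamming scan on random queries", {
  set.seed(23)
  ref <- random_seq(10000)
  idx <- build_mismatch_index(c(chr = ref))
  for (mm in 0:1) {
    for (i in 1:100) {
      # half planted (with mm mutations), half random
      if (i %% 2 == 0) {
        at <- sample(1:(10000 - 24), 1)
        q <- substr(ref, at, at + 23)
        if (mm == 1) {
          p <- sample(1:24, 1)
          substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(q, p, p)), 1)
        }
      } else q <- random_seq(24)
      got <- sort(query_index(idx, q, mm)$position)
      expect_equal(got, sort(bf_hamming_scan(q, ref, mm)))
    }
  }
})

test_that("tier-1 mismatch allowance switches at the 19/20 nt boundary", {
  tx <- transcript_set("t1", "miRNA", "syn",
                       "ACGTACGTAGGCTTAGGCATCGATTACGGATTCCAG")
  mk <- function(seq) data.frame(read_id = "r", sequence = seq,
                                 stringsAsFactors = FALSE)
  # 16-nt exact substring: mapped at 0 mm
  r16 <- substr(tx$sequence, 3, 18)
  expect_equal(nrow(align_tier1(mk(r16), tx)$unmapped), 0L)
  # 16-nt with one mismatch: short band allows none -> unmapped
  r16m <- r16; substr(r16m, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                             substr(r16m, 8, 8))[1]
  expect_equal(nrow(align_tier1(mk(r16m), tx)$unmapped), 1L)
  # 24-nt with 1 mismatch mapped, with 2 unmapped
  r24 <- substr(tx$sequence, 5, 28)
  r24m1 <- r24; substr(r24m1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(r24m1, 10, 10))[1]
  expect_equal(nrow(align_tier1(mk(r24m1), tx)$unmapped), 0L)
  r24m2 <- r24m1; substr(r24m2, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                                   substr(r24m2, 15, 15))[1]
  expect_equal(nrow(align_tier1(mk(r24m2), tx)$unmapped), 1L)
})

test_that("tier-1 counting applies class priority then equal split", {
  seqA <- random_seq(40)
  read <- substr(seqA, 5, 26)
  tx <- transcript_set(c("mirA", "mirB", "rrnaC"),
                       c("miRNA", "miRNA", "rRNA"), "syn",
                       c(seqA, paste0(random_seq(6), read, random_seq(6)),
                         paste0(read, random_seq(30))))
  reads <- data.frame(read_id = "r1", sequence = read,
                      stringsAsFactors = FALSE)
  res <- align_tier1(reads, tx)
  counts <- count_tier1(res$hits, tx)
  # read hits two miRNAs and one rRNA at 0 mm: rRNA outranked, miRNAs split
  expect_equal(unname(counts["mirA"]), 0.5)
  expect_equal(unname(counts["mirB"]), 0.5)
  expect_equal(unname(counts["rrnaC"]), 0)
  expect_equal(sum(counts), 1)

  # single-target read contributes exactly 1
  tx1 <- tx[1, ]
  res1 <- align_tier1(reads, tx1)
  expect_equal(unname(count_tier1(res1$hits, tx1)["mirA"]), 1)
})

test_that("tier-2 maps both strands and enforces the 5-locus cap", {
  set.seed(31)
  core <- random_seq(24)
  # plant once, plus a 6x multi-mapper elsewhere
  multi <- random_seq(24)
  genome <- c(chr1 = paste0(random_seq(200), core, random_seq(200),
                            paste(rep(multi, 6), collapse = random_seq(30)),
                            random_seq(100)))
  reads <- data.frame(
    read_id = c("unique", "minus", "multi6", "nohit"),
    sequence = c(core,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(core))),
                 multi, random_seq(24)),
    stringsAsFactors = FALSE)
  res <- align_tier2(reads, genome)
  expect_setequal(res$mapped_ids, c("unique", "minus", "multi6"))
  expect_equal(res$multimapper_ids, "multi6")
  expect_setequal(unique(res$hits$read_id), c("unique", "minus"))
  expect_equal(res$hits$strand[res$hits$read_id == "minus"], "-")
  expect_equal(res$unmapped$read_id, "nohit")

  # relaxing the cap only ever grows the prediction-eligible set
  res10 <- align_tier2(reads, genome, alignment_policy(max_genome_loci = 10))
  expect_true(all(unique(res$hits$read_id) %in% unique(res10$hits$read_id)))
  expect_true("multi6" %in% unique(res10$hits$read_id))
})

test_that("tier-4 is exact-only and splits counts across precursors", {
  pre <- random_seq(70)
  read <- substr(pre, 10, 31)
  nto <- c("mmu-mir-1" = pre, "rno-mir-2" = paste0(random_seq(10), read,
                                                   random_seq(10)))
  reads <- data.frame(read_id = c("hit", "near"),
                      sequence = c(read, {
                        x <- read
                        substr(x, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                                   substr(x, 5, 5))[1]
                        x
                      }),
                      stringsAsFactors = FALSE)
  res <- align_tier4(reads, nto)
  expect_equal(res$unmapped$read_id, "near")   # 1 mismatch: no tier-4 hit
  expect_equal(unname(res$counts["mmu-mir-1"]), 0.5)
  expect_equal(unname(res$counts["rno-mir-2"]), 0.5)
})

test_that("cascade enforces precedence and partitions every read", {
  spec <- fixture_spec(seed = 17, read_error_rate = 0, genome_length = 8000,
                       n_planted_mirnas = 2, n_decoy_clusters = 1,
                       pathogen = list(n_viral = 4, n_bacterial = 2,
                                       viral_len = 2000, bacterial_len = 3000),
                       sample = list(n_tier1 = 120, n_pathogen = 80,
                                     n_nto = 60, n_random = 80))
  host <- make_host(spec)
  panel <- make_pathogen_panel(spec)
  db <- build_kmer_db(panel$genomes, panel$taxonomy)
  sim <- simulate_sample(host, panel, spec)
  pp <- preprocess_sample(sim$reads, trim_spec(adapter3 = spec$sample$adapter3))
  refs <- list(transcripts = host$transcripts, genome = host$genome,
               kmer_db = db, taxonomy = panel$taxonomy, nto = host$nto)
  casc <- run_cascade(pp$reads, refs, alignment_policy(), "model")

  # partition: every read appears exactly once
  expect_equal(sort(casc$assignments$read_id), sort(pp$reads$read_id))
  expect_equal(sum(unlist(casc$summary)), nrow(pp$reads))
  # error-free reads land on their provenance tier
  m <- merge(casc$assignments, sim$provenance, by = "read_id")
  expect_equal(m$tier, m$expected_tier)
  # no read consumed by tier 1 shows up in tier-2 hits (precedence)
  t1_ids <- m$read_id[m$tier == "TIER1_TRANSCRIPT"]
  expect_length(intersect(t1_ids, casc$tier2$hits$read_id), 0L)

  # a read present in both a transcript and a pathogen genome goes to tier 1
  shared <- substr(panel$genomes$sequence[1], 100, 121)
  refs2 <- refs
  refs2$transcripts <- rbind(refs$transcripts,
                             transcript_set("shared", "miRNA", "syn",
                                            paste0(shared, random_seq(8))))
  one <- data.frame(read_id = "x", sequence = shared, stringsAsFactors = FALSE)
  expect_equal(run_cascade(one, refs2, alignment_policy(),
                           "model")$assignments$tier, "TIER1_TRANSCRIPT")

  # missing reference set fails before any alignment
  expect_error(run_cascade(one, refs[-2], alignment_policy(), "model"),
               "genome")
})

test_that("non-model mode aligns exactly against the stored catalog only", {
  cat_tx <- transcript_set(c("mir1", "fam1"), c("miRNA", "family"), "any",
                           c(random_seq(60), random_seq(60)))
  reads <- data.frame(
    read_id = c("hit", "miss"),
    sequence = c(substr(cat_tx$sequence[1], 5, 26), random_seq(22)),
    stringsAsFactors = FALSE)
  res <- run_cascade(reads, list(catalog_transcripts = cat_tx),
                     mode = "non_model")
  tiers <- setNames(res$assignments$tier, res$assignments$read_id)
  expect_equal(unname(tiers["hit"]), "TIER4_NTO")
  expect_equal(unname(tiers["miss"]), "UNALIGNED")
  expect_error(run_cascade(reads, list(), mode = "non_model"),
               "catalog_transcripts")
})
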