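# Deterministic synthetic-data generator. Produces every input the pipeline
# consumes -- host genome with planted miRNA hairpins, transcript and decoy
# references, a pathogen genome panel with taxonomy, per-sample FASTQ with
# per-read provenance, and classification count tables -- as pure functions
# of (spec, seed), with loud self-checks on the planted ground truth.

#' Fixture generation specification
#'
#' Defaults define the study conditions used throughout the test and
#' acceptance suites: a 20 kb host genome with 5 planted hairpins (26-bp stem
#' with up to 2 single-base bulges, 6-10 nt loop, 22-nt mature) and 5
#' non-hairpin decoy clusters; a 12-genome (8 viral + 4 bacterial) pathogen
#' panel under a root/domain/genus/species taxonomy; 1% per-base read error.
#'
#' @param seed integer seed.
#' @param genome_length host genome length (nt).
#' @param n_planted_mirnas planted hairpins.
#' @param n_decoy_clusters planted non-hairpin read clusters.
#' @param read_error_rate per-base substitution rate in [0, 0.2].
#' @param pathogen list: n_viral, n_bacterial, viral_len, bacterial_len,
#'   share_frac (fraction of sequence shared between sibling species).
#' @param sample list: per-sample read composition (n_tier1, n_pathogen,
#'   n_nto, n_random, mature_mean, star_mean, decoy_mean, adapter3,
#'   sequencer_len).
#' @param classification list: n_per_class, n_features (background),
#'   n_informative, effect_size (log2 fold change), dispersion,
#'   perfect_separator.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 20000L,
                         n_planted_mirnas = 5L, n_decoy_clusters = 5L,
                         read_error_rate = 0.01,
                         pathogen = list(), sample = list(),
                         classification = list()) {
  stopifnot(read_error_rate >= 0, read_error_rate <= 0.2,
            genome_length > 0L, n_planted_mirnas >= 0L,
            n_decoy_clusters >= 0L)
  pathogen <- modifyList(list(n_viral = 8L, n_bacterial = 4L,
                              viral_len = 5000L, bacterial_len = 10000L,
                              share_frac = 0.1), pathogen)
  sample <- modifyList(list(n_tier1 = 300L, n_pathogen = 200L, n_nto = 100L,
                            n_random = 200L, mature_mean = 20, star_mean = 3,
                            decoy_mean = 10,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                            sequencer_len = 50L), sample)
  classification <- modifyList(list(n_per_class = c(6L, 6L),
                                    n_features = 300L, n_informative = 0L,
                                    effect_size = 2, dispersion = 0.2,
                                    perfect_separator = TRUE),
                               classification)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_planted_mirnas = as.integer(n_planted_mirnas),
                 n_decoy_clusters = as.integer(n_decoy_clusters),
                 read_error_rate = read_error_rate, pathogen = pathogen,
                 sample = sample, classification = classification),
            class = "fixture_spec")
}

# One synthetic hairpin: 26-bp stem with n_bulges single-base insertions in
# the 3' arm, loop of 6-10 nt. Returns the hairpin sequence plus
# hairpin-relative mature and star intervals derived from its own fold.
make_hairpin <- function(mature_arm) {
  repeat {
    left <- random_dna(26)
    loop_len <- sample(6:10, 1L)
    loop <- random_dna(loop_len)
    right <- strsplit(revcomp(left), "")[[1L]]
    # 1-2 single-base bulges near the stem centre: keeps the fold a clear
    # hairpin but breaks the palindrome, so arm reads map to one strand only
    n_bulges <- sample(1:2, 1L)
    for (b in seq_len(n_bulges)) {
      at <- sample(6:18, 1L)
      right <- append(right, sample(c("A", "C", "G", "T"), 1L), after = at)
    }
    hp <- paste0(left, loop, paste(right, collapse = ""))
    fold <- fold_hairpin(hp)
    if (fold$n_pairs < 20L) next
    H <- nchar(hp)
    # mature sits 3 nt inside the stem so the star 3' overhang stays inside
    if (mature_arm == "5p") { ms <- 3L; me <- 25L } else { ms <- H - 25L; me <- H - 3L }
    pt <- fold$pairs
    mat_idx <- (ms + 1L):me
    paired <- which(pt[mat_idx] >= 0L)
    if (length(paired) < 18L) next
    # star read end = partner of the mature 5' end + 2-nt 3' overhang
    star_end <- pt[mat_idx[paired[1L]]] + 1L + 2L
    star_start <- star_end - 22L
    if (star_start < 0L || star_end > H) next
    if (star_start < me && star_end > ms) next  # star must not overlap mature
    return(list(seq = hp, mature = c(ms, me), star = c(star_start, star_end),
                arm = mature_arm))
  }
}

#' Generate the host references with planted ground truth
#'
#' Random genome with planted miRNA hairpins, a transcript reference (known
#' miRNAs plus piRNA/snoRNA/snRNA/rRNA records), tRNA/rRNA decoys,
#' cross-species miRNA precursors, and the locations of non-hairpin decoy
#' read clusters. Self-checks: every planted hairpin folds to >= 20 pairs and
#' shares no 20-mer with the decoys; decoy cluster windows show no
#' unusually low shuffle-null structure p (internal check p >= 0.3), i.e.
#' they really are non-hairpins.
#'
#' @param spec a [fixture_spec()].
#' @return list(genome, transcripts, decoys, nto, hairpins (truth
#'   data.frame), decoy_clusters (truth data.frame)).
#' @export
make_host <- function(spec) {
  with_seed(derive_seed(spec$seed, 11L), make_host_impl(spec))
}

make_host_impl <- function(spec) {
  decoys <- setNames(vapply(seq_len(4L), function(i)
    random_dna(sample(80:150, 1L)), ""), paste0("decoy", 1:4))
  decoy_kmers <- unique(unlist(lapply(c(decoys, revcomp(decoys)), kmers_of,
                                      k = 20L), use.names = FALSE))
  genome_chars <- strsplit(random_dna(spec$genome_length), "")[[1L]]

  n_hp <- spec$n_planted_mirnas
  n_dc <- spec$n_decoy_clusters
  n_slots <- n_hp + n_dc
  slot_w <- spec$genome_length %/% max(1L, n_slots)
  if (slot_w < 400L) stop("genome too short for requested plantings",
                          call. = FALSE)
  slots <- sample(seq_len(n_slots))  # shuffle hairpin/decoy placement

  hp_truth <- list()
  dc_truth <- list()
  for (s in seq_len(n_slots)) {
    lo <- (s - 1L) * slot_w
    is_hp <- slots[s] <= n_hp
    if (is_hp) {
      repeat {
        repeat {
          hp <- make_hairpin(sample(c("5p", "3p"), 1L))
          if (!any(kmers_of(hp$seq, 20L) %in% decoy_kmers) &&
              !any(kmers_of(revcomp(hp$seq), 20L) %in% decoy_kmers)) break
        }
        H <- nchar(hp$seq)
        pos <- lo + sample(100:(slot_w - H - 100L), 1L)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") hp$seq else revcomp(hp$seq)
        genome_chars[(pos + 1L):(pos + H)] <- strsplit(ins, "")[[1L]]
        # detectability self-check: the excision window around the planted
        # mature must be clearly non-random under the shuffle null, i.e. the
        # plant really is a hairpin in its genomic context
        ms <- hp$mature[1L]; me <- hp$mature[2L]
        if (hp$arm == "5p") { wlo <- ms - 15L; whi <- ms + 95L
        } else { wlo <- me - 95L; whi <- me + 15L }
        wg <- if (strand == "+") c(pos + wlo, pos + whi)
              else c(pos + H - whi, pos + H - wlo)
        win <- paste(genome_chars[(wg[1L] + 1L):wg[2L]], collapse = "")
        if (strand == "-") win <- revcomp(win)
        if (randfold_p(win, n_shuffles = 99L,
                       seed = derive_seed(spec$seed, 800L + s)) <= 0.01) break
        # undo and replant with fresh sequence
        genome_chars[(pos + 1L):(pos + H)] <-
          strsplit(random_dna(H), "")[[1L]]
      }
      to_gen <- function(iv) {
        if (strand == "+") c(pos + iv[1L], pos + iv[2L])
        else c(pos + H - iv[2L], pos + H - iv[1L])
      }
      m <- to_gen(hp$mature); st <- to_gen(hp$star)
      hp_truth[[length(hp_truth) + 1L]] <- data.frame(
        chrom = "chr1", strand = strand, hp_start = pos, hp_end = pos + H,
        mature_start = m[1L], mature_end = m[2L], star_start = st[1L],
        star_end = st[2L], arm = hp$arm, seq = hp$seq,
        stringsAsFactors = FALSE)
    } else {
      # non-hairpin decoy cluster: neither excision window around the planted
      # read site may look structured under its own shuffle null
      start <- lo + sample(100:(slot_w - 140L), 1L)
      m <- start + 15L  # planted modal read start
      repeat {
        winA <- paste(genome_chars[(m - 15L + 1L):(m + 95L)], collapse = "")
        winB <- paste(genome_chars[(m - 73L + 1L):(m + 37L)], collapse = "")
        pA <- randfold_p(winA, n_shuffles = 49L,
                         seed = derive_seed(spec$seed, 900L + s))
        pB <- randfold_p(winB, n_shuffles = 49L,
                         seed = derive_seed(spec$seed, 950L + s))
        if (pA >= 0.3 && pB >= 0.3) break
        # re-randomize the whole span and retry
        genome_chars[(m - 73L + 1L):(m + 95L)] <-
          strsplit(random_dna(168L), "")[[1L]]
      }
      dc_truth[[length(dc_truth) + 1L]] <- data.frame(
        chrom = "chr1", strand = "+", start = m, end = m + 22L,
        stringsAsFactors = FALSE)
    }
  }
  genome <- c(chr1 = paste(genome_chars, collapse = ""))

  n_mirna <- 8L
  transcripts <- transcript_set(
    transcript_id = c(paste0("mir", seq_len(n_mirna)),
                      paste0("pir", 1:3), paste0("sno", 1:2),
                      paste0("snr", 1:2), paste0("rrna", 1:2)),
    srna_class = c(rep("miRNA", n_mirna), rep("piRNA", 3L),
                   rep("snoRNA", 2L), rep("snRNA", 2L), rep("rRNA", 2L)),
    organism = "syn",
    sequence = c(vapply(seq_len(n_mirna), function(i) random_dna(22L), ""),
                 vapply(1:3, function(i) random_dna(28L), ""),
                 vapply(1:2, function(i) random_dna(70L), ""),
                 vapply(1:2, function(i) random_dna(90L), ""),
                 vapply(1:2, function(i) random_dna(120L), "")))
  nto <- setNames(vapply(1:6, function(i) random_dna(70L), ""),
                  paste0("nto-mir-", 1:6))
  list(genome = genome, transcripts = transcripts, decoys = decoys,
       nto = nto, hairpins = do.call(rbind, hp_truth),
       decoy_clusters = do.call(rbind, dc_truth))
}

#' Generate the pathogen genome panel and its taxonomy
#'
#' Viral and bacterial species under a root/domain/genus/species taxonomy;
#' within each genus the two sibling species share a `share_frac` fraction of
#' sequence so that shared k-mers exercise the LCA rule.
#'
#' @param spec a [fixture_spec()].
#' @return list(genomes (data.frame taxon_id, chrom, sequence), taxonomy).
#' @export
make_pathogen_panel <- function(spec) {
  with_seed(derive_seed(spec$seed, 22L), make_pathogen_panel_impl(spec))
}

make_pathogen_panel_impl <- function(spec) {
  cfg <- spec$pathogen
  n_sp <- cfg$n_viral + cfg$n_bacterial
  n_genus <- ceiling(n_sp / 2)
  domains <- c(rep("viruses", ceiling(cfg$n_viral / 2)),
               rep("bacteria", ceiling(cfg$n_bacterial / 2)))
  nodes <- data.frame(
    taxon_id = c("root", "d_vir", "d_bac", paste0("g", seq_len(n_genus)),
                 paste0("s", seq_len(n_sp))),
    parent_id = c(NA, "root", "root",
                  ifelse(domains == "viruses", "d_vir", "d_bac"),
                  paste0("g", rep(seq_len(n_genus), each = 2L)[seq_len(n_sp)])),
    rank = c("root", "domain", "domain", rep("genus", n_genus),
             rep("species", n_sp)),
    name = c("root", "Viruses", "Bacteria",
             paste0("genus_", seq_len(n_genus)),
             paste0("species_", sprintf("%02d", seq_len(n_sp)))),
    stringsAsFactors = FALSE)
  taxonomy <- taxonomy_tree(nodes)
  lens <- c(rep(cfg$viral_len, cfg$n_viral),
            rep(cfg$bacterial_len, cfg$n_bacterial))
  seqs <- vapply(lens, random_dna, "")
  # sibling sharing: copy a block from the first sibling into the second
  if (cfg$share_frac > 0) {
    for (g in seq_len(n_genus)) {
      a <- 2L * g - 1L; b <- 2L * g
      if (b > n_sp) next
      blk <- max(0L, as.integer(cfg$share_frac * min(lens[a], lens[b])))
      if (blk < 18L) next
      from <- sample.int(lens[a] - blk + 1L, 1L)
      at <- sample.int(lens[b] - blk + 1L, 1L)
      substr(seqs[b], at, at + blk - 1L) <- substr(seqs[a], from,
                                                   from + blk - 1L)
    }
  }
  genomes <- data.frame(taxon_id = paste0("s", seq_len(n_sp)),
                        chrom = paste0("s", seq_len(n_sp), "_chr"),
                        sequence = seqs, stringsAsFactors = FALSE)
  list(genomes = genomes, taxonomy = taxonomy)
}

# Per-base substitution errors at a fixed rate.
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate one sRNA-seq sample with known read provenance
#'
#' Draws reads from known transcripts (tier-1 truth), planted hairpin arms
#' (tier-2 truth, ~Poisson(mature_mean) mature + ~Poisson(star_mean) star
#' reads per hairpin) and decoy clusters, one designated pathogen genome
#' (tier-3 truth), cross-species precursors (tier-4 truth), and uniform
#' random sequence (unaligned truth; lengths 20-32 so chance alignments are
#' negligible). Per-base errors at the configured rate; the 3' adapter is
#' appended and the read clipped to the sequencer length, so preprocessing
#' is exercised.
#'
#' @param host [make_host()] output.
#' @param panel [make_pathogen_panel()] output (NULL to skip pathogen reads).
#' @param spec a [fixture_spec()].
#' @param sample_seed per-sample seed (default: spec seed).
#' @param infecting_taxon taxon id of the designated pathogen (default: drawn
#'   from the panel).
#' @return list(reads (raw, adapter-bearing), provenance (read_id, source,
#'   expected_tier), infecting_taxon).
#' @export
simulate_sample <- function(host, panel, spec, sample_seed = spec$seed,
                            infecting_taxon = NULL) {
  with_seed(derive_seed(sample_seed, 33L),
            simulate_sample_impl(host, panel, spec, infecting_taxon))
}

simulate_sample_impl <- function(host, panel, spec, infecting_taxon) {
  cfg <- spec$sample
  src_seq <- character(0); src_lab <- character(0); src_tier <- character(0)
  add <- function(seqs, label, tier) {
    src_seq <<- c(src_seq, seqs)
    src_lab <<- c(src_lab, rep_len(label, length(seqs)))
    src_tier <<- c(src_tier, rep_len(tier, length(seqs)))
  }
  # tier 1: substrings of transcript records
  if (cfg$n_tier1 > 0L) {
    tx <- host$transcripts
    pick <- sample.int(nrow(tx), cfg$n_tier1, replace = TRUE)
    seqs <- vapply(pick, function(i) {
      full <- tx$sequence[i]
      L <- nchar(full)
      len <- min(L, sample(15:32, 1L))
      at <- sample.int(L - len + 1L, 1L)
      substr(full, at, at + len - 1L)
    }, "")
    add(seqs, paste0("transcript:", tx$transcript_id[pick]),
        "TIER1_TRANSCRIPT")
  }
  # tier 2: planted hairpin mature/star reads + decoy cluster reads
  if (!is.null(host$hairpins) && nrow(host$hairpins)) {
    for (i in seq_len(nrow(host$hairpins))) {
      h <- host$hairpins[i, ]
      n_mat <- max(2L, rpois(1L, cfg$mature_mean))
      n_star <- rpois(1L, cfg$star_mean)
      ms <- h$mature_start - h$hp_start; me <- h$mature_end - h$hp_start
      ss <- h$star_start - h$hp_start; se <- h$star_end - h$hp_start
      # truth coordinates are genomic; recover oriented arm sequences
      hp_len <- nchar(h$seq)
      if (h$strand == "+") {
        mat_seq <- substr(h$seq, ms + 1L, me)
        star_seq <- substr(h$seq, ss + 1L, se)
      } else {
        mat_seq <- substr(h$seq, hp_len - me + 1L, hp_len - ms)
        star_seq <- substr(h$seq, hp_len - se + 1L, hp_len - ss)
      }
      add(rep(mat_seq, n_mat), paste0("hairpin:", i, ":mature"),
          "TIER2_GENOME")
      if (n_star > 0L) add(rep(star_seq, n_star),
                           paste0("hairpin:", i, ":star"), "TIER2_GENOME")
    }
  }
  if (!is.null(host$decoy_clusters) && nrow(host$decoy_clusters)) {
    for (i in seq_len(nrow(host$decoy_clusters))) {
      d <- host$decoy_clusters[i, ]
      n_r <- max(2L, rpois(1L, cfg$decoy_mean))
      starts <- d$start + sample(-8:8, n_r, replace = TRUE)
      lens <- sample(20:24, n_r, replace = TRUE)
      seqs <- substr(rep(host$genome[["chr1"]], n_r), starts + 1L,
                     starts + lens)
      add(seqs, paste0("decoy_cluster:", i), "TIER2_GENOME")
    }
  }
  # tier 3: reads from the designated pathogen genome, both strands
  if (!is.null(panel) && cfg$n_pathogen > 0L) {
    if (is.null(infecting_taxon)) {
      infecting_taxon <- sample(panel$genomes$taxon_id, 1L)
    }
    g <- panel$genomes$sequence[panel$genomes$taxon_id == infecting_taxon]
    L <- nchar(g)
    seqs <- vapply(seq_len(cfg$n_pathogen), function(i) {
      len <- sample(22:32, 1L)
      at <- sample.int(L - len + 1L, 1L)
      s <- substr(g, at, at + len - 1L)
      if (runif(1L) < 0.5) revcomp(s) else s
    }, "")
    add(seqs, paste0("pathogen:", infecting_taxon), "TIER3_PATHOGEN")
  } else infecting_taxon <- NA_character_
  # tier 4: substrings of cross-species precursors
  if (cfg$n_nto > 0L) {
    pick <- sample(names(host$nto), cfg$n_nto, replace = TRUE)
    seqs <- vapply(pick, function(id) {
      full <- host$nto[[id]]
      len <- sample(18:26, 1L)
      at <- sample.int(nchar(full) - len + 1L, 1L)
      substr(full, at, at + len - 1L)
    }, "", USE.NAMES = FALSE)
    add(seqs, paste0("nto:", pick), "TIER4_NTO")
  }
  # unaligned: uniform random, lengths 20-32
  if (cfg$n_random > 0L) {
    seqs <- vapply(seq_len(cfg$n_random), function(i)
      random_dna(sample(20:32, 1L)), "")
    add(seqs, "random", "UNALIGNED")
  }

  inserts <- apply_errors(src_seq, spec$read_error_rate)
  pad <- cfg$sequencer_len
  raw <- vapply(inserts, function(s) {
    full <- paste0(s, cfg$adapter3, random_dna(pad))
    substr(full, 1L, pad)
  }, "", USE.NAMES = FALSE)
  ids <- sprintf("r%05d", seq_along(raw))
  reads <- data.frame(read_id = ids, sequence = raw,
                      quality = strrep("I", nchar(raw)),
                      stringsAsFactors = FALSE)
  provenance <- data.frame(read_id = ids, source = src_lab,
                           expected_tier = src_tier, stringsAsFactors = FALSE)
  stopifnot(nrow(provenance) == nrow(reads))  # conservation self-check
  list(reads = reads, provenance = provenance,
       infecting_taxon = infecting_taxon)
}

#' Simulate a classification count table
#'
#' Negative-binomial background counts (fixed dispersion); informative
#' features are shifted by `effect_size` log2 fold change in the second
#' group; the perfect-separator option adds one feature whose per-group count
#' ranges are disjoint.
#'
#' @param spec a [fixture_spec()] (fields under `classification`).
#' @param seed dataset seed (default: spec seed).
#' @return list(counts (features x samples), sheet (sample_id, group), truth
#'   (informative feature names)).
#' @export
make_classification_dataset <- function(spec, seed = spec$seed) {
  with_seed(derive_seed(seed, 44L), {
    cfg <- spec$classification
    n1 <- cfg$n_per_class[1L]; n2 <- cfg$n_per_class[2L]
    n <- n1 + n2
    p <- cfg$n_features
    group <- rep(c("control", "case"), c(n1, n2))
    base_mu <- exp(rnorm(p, log(100), 1))
    size <- 1 / cfg$dispersion
    counts <- matrix(0, nrow = p, ncol = n,
                     dimnames = list(sprintf("feat%03d", seq_len(p)),
                                     sprintf("s%02d", seq_len(n))))
    informative <- character(0)
    if (cfg$n_informative > 0L) {
      informative <- rownames(counts)[seq_len(cfg$n_informative)]
    }
    for (j in seq_len(n)) {
      mu <- base_mu
      if (group[j] == "case" && cfg$n_informative > 0L) {
        mu[seq_len(cfg$n_informative)] <-
          mu[seq_len(cfg$n_informative)] * 2^cfg$effect_size
      }
      counts[, j] <- rnbinom(p, mu = mu, size = size)
    }
    truth <- informative
    if (isTRUE(cfg$perfect_separator)) {
      sep <- ifelse(group == "control", sample(0:10, n, replace = TRUE),
                    sample(100:200, n, replace = TRUE))
      counts <- rbind(counts, separator = sep)
      truth <- c(truth, "separator")
      stopifnot(max(sep[group == "control"]) < min(sep[group == "case"]))
    }
    sheet <- data.frame(sample_id = colnames(counts), group = group,
                        stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet, truth = truth)
  })
}
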