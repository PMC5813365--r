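# Pathogen screen: canonical 18-mer database over a pathogen genome panel
# with LCA collapsing of shared k-mers, Kraken-style maximal root-to-leaf
# path classification of reads, a ranked top-N species report, and the
# precision/recall/F evaluation harness.

#' Build and validate a taxonomy tree
#'
#' @param nodes data.frame with taxon_id, parent_id (NA for the root), rank
#'   (root, domain, ..., genus, species, strain), name.
#' @return object of class `taxonomy` (the validated node table).
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon_id", call. = FALSE)
  roots <- which(is.na(nodes$parent_id) | nodes$parent_id == nodes$taxon_id)
  if (length(roots) != 1L) stop("taxonomy must have a single root", call. = FALSE)
  nodes$parent_id[roots] <- NA
  # every node must reach the root without cycles
  for (i in seq_len(nrow(nodes))) {
    seen <- character(0)
    cur <- nodes$taxon_id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) stop("taxonomy contains a cycle", call. = FALSE)
      seen <- c(seen, cur)
      j <- match(cur, nodes$taxon_id)
      if (is.na(j)) stop("unknown parent_id: ", cur, call. = FALSE)
      cur <- nodes$parent_id[j]
    }
  }
  structure(nodes, class = c("taxonomy", "data.frame"))
}

#' Read a taxonomy TSV (taxon_id, parent_id, rank, name)
#' @param path TSV path.
#' @return a [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(taxon_id = "character",
                                  parent_id = "character"))
  df$parent_id[df$parent_id == ""] <- NA
  taxonomy_tree(df)
}

# Path from a node up to the root (inclusive), node first.
tax_path <- function(taxonomy, taxon_id) {
  path <- character(0)
  cur <- taxon_id
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- taxonomy$parent_id[match(cur, taxonomy$taxon_id)]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#' @param taxonomy a [taxonomy_tree()].
#' @param taxa character vector of taxon ids.
#' @return the LCA taxon id.
#' @export
tax_lca <- function(taxonomy, taxa) {
  taxa <- unique(taxa)
  common <- tax_path(taxonomy, taxa[1L])
  for (t in taxa[-1L]) common <- intersect(common, tax_path(taxonomy, t))
  common[1L]  # paths are node-first, so the first common entry is deepest
}

canonical_kmers <- function(seq, k) {
  km <- kmers_of(seq, k)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character(0))
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

#' Build the canonical k-mer database over a pathogen genome panel
#'
#' Canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement; k-mers containing N are skipped; a k-mer present in multiple
#' taxa is stored under the LCA of those taxa.
#'
#' @param genomes data.frame with taxon_id, chrom, sequence (one or more rows
#'   per taxon).
#' @param taxonomy a [taxonomy_tree()].
#' @param k k-mer length (default 18).
#' @return object of class `kmer_db`: sorted k-mer vector plus parallel taxon
#'   vector.
#' @export
build_kmer_db <- function(genomes, taxonomy, k = 18L) {
  unknown <- setdiff(unique(genomes$taxon_id), taxonomy$taxon_id)
  if (length(unknown)) {
    stop("genome taxon_id not in taxonomy: ", unknown[1L], call. = FALSE)
  }
  per_tax <- split(genomes$sequence, genomes$taxon_id)
  km_list <- lapply(per_tax, function(seqs) {
    unique(unlist(lapply(seqs, canonical_kmers, k = k), use.names = FALSE))
  })
  kmer <- unlist(km_list, use.names = FALSE)
  taxon <- rep(names(km_list), lengths(km_list))
  dup_mask <- duplicated(kmer) | duplicated(kmer, fromLast = TRUE)
  uk <- kmer[!dup_mask]; ut <- taxon[!dup_mask]
  if (any(dup_mask)) {
    shared <- split(taxon[dup_mask], kmer[dup_mask])
    lca <- vapply(shared, function(ts) tax_lca(taxonomy, ts), "")
    uk <- c(uk, names(lca)); ut <- c(ut, unname(lca))
  }
  ord <- order(uk)
  structure(list(k = as.integer(k), kmers = uk[ord], taxa = ut[ord]),
            class = "kmer_db")
}

# Classify one read's canonical k-mer hit-count profile with Kraken's rule:
# score each root-to-leaf path by the summed counts of its nodes; classify to
# the deepest counted node on the maximal path; path ties -> LCA of the tied
# deepest nodes.
classify_hit_counts <- function(counts, taxonomy, paths = NULL) {
  if (length(counts) == 0L) return(NA_character_)
  if (is.null(paths)) paths <- leaf_paths(taxonomy)
  scores <- vapply(paths, function(p) sum(counts[intersect(p, names(counts))]), 0)
  best <- which(scores == max(scores))
  deepest <- vapply(paths[best], function(p) {
    hit <- p[p %in% names(counts)]
    hit[1L]  # node-first path: first hit node is the deepest counted
  }, "")
  deepest <- unique(deepest)
  if (length(deepest) == 1L) deepest else tax_lca(taxonomy, deepest)
}

#' Classify reads against a k-mer database
#'
#' @param reads data.frame (read_id, sequence).
#' @param db a [build_kmer_db()].
#' @param taxonomy the matching [taxonomy_tree()].
#' @return data.frame(read_id, taxon_id) with NA taxon for unclassified reads
#'   (no k-mer hit, or shorter than k).
#' @export
classify_reads <- function(reads, db, taxonomy) {
  n <- nrow(reads)
  taxon <- rep(NA_character_, n)
  if (n) {
    km_list <- lapply(reads$sequence, function(s) {
      if (nchar(s) < db$k) return(character(0))
      km <- kmers_of(s, db$k)
      km[!grepl("N", km, fixed = TRUE)]
    })
    all_km <- unlist(km_list, use.names = FALSE)
    if (length(all_km)) {
      rc <- revcomp(all_km)
      canon <- ifelse(all_km <= rc, all_km, rc)
      hit <- db$taxa[match(canon, db$kmers)]
      idx <- rep(seq_len(n), lengths(km_list))
      paths <- leaf_paths(taxonomy)
      keep <- !is.na(hit)
      per_read <- split(hit[keep], idx[keep])
      for (key in names(per_read)) {
        taxon[as.integer(key)] <-
          classify_hit_counts(table(per_read[[key]]), taxonomy, paths)
      }
    }
  }
  data.frame(read_id = reads$read_id, taxon_id = taxon,
             stringsAsFactors = FALSE)
}

leaf_paths <- function(taxonomy) {
  leaves <- setdiff(taxonomy$taxon_id,
                    taxonomy$parent_id[!is.na(taxonomy$parent_id)])
  lapply(leaves, tax_path, taxonomy = taxonomy)
}

# Species-rank ancestor of a taxon, or NA if the taxon sits above species.
species_of <- function(taxonomy, taxon_id) {
  path <- tax_path(taxonomy, taxon_id)
  ranks <- taxonomy$rank[match(path, taxonomy$taxon_id)]
  sp <- path[ranks == "species"]
  if (length(sp)) sp[1L] else NA_character_
}

#' Ranked top-N pathogen species report
#'
#' Reads classified at species rank or below are attributed to their species;
#' reads classified above species are tallied separately. Species are ranked
#' by read count descending (count ties broken by name ascending) and the
#' list truncated to `top_n`.
#'
#' @param classifications data.frame from [classify_reads()].
#' @param taxonomy a [taxonomy_tree()].
#' @param top_n report length (default 5).
#' @return list(ranked data.frame(taxon_id, name, read_count), above_species,
#'   unclassified, top_n) of class `pathogen_report`.
#' @export
make_report <- function(classifications, taxonomy, top_n = 5L) {
  cl <- classifications$taxon_id
  unclassified <- sum(is.na(cl))
  cl <- cl[!is.na(cl)]
  sp <- vapply(cl, species_of, "", taxonomy = taxonomy, USE.NAMES = FALSE)
  above <- sum(is.na(sp))
  sp <- sp[!is.na(sp)]
  ranked <- data.frame(taxon_id = character(0), name = character(0),
                       read_count = integer(0), stringsAsFactors = FALSE)
  if (length(sp)) {
    tab <- table(sp)
    name <- taxonomy$name[match(names(tab), taxonomy$taxon_id)]
    ranked <- data.frame(taxon_id = names(tab), name = name,
                         read_count = as.integer(tab),
                         stringsAsFactors = FALSE)
    ranked <- ranked[order(-ranked$read_count, ranked$name), , drop = FALSE]
    ranked <- head(ranked, top_n)
    rownames(ranked) <- NULL
  }
  structure(list(ranked = ranked, above_species = above,
                 unclassified = unclassified, top_n = as.integer(top_n)),
            class = "pathogen_report")
}

#' @export
print.pathogen_report <- function(x, ...) {
  cat(sprintf("Top-%d pathogen species report\n", x$top_n))
  if (nrow(x$ranked)) print(x$ranked) else cat("  (no species-level reads)\n")
  cat(sprintf("above-species: %d, unclassified: %d\n",
              x$above_species, x$unclassified))
  invisible(x)
}

#' Top-N precision / recall / F-score over evaluation datasets
#'
#' Per dataset, with R the first `min(n, report length)` reported species and
#' T the truth set: TP = |R intersect T|, precision = TP/|R| (0 if R empty),
#' recall = TP/|T|, F = harmonic mean (0 when both are 0). Returned metrics
#' are unweighted means over datasets.
#'
#' @param reports list of [make_report()] results.
#' @param truths list of character vectors (true species taxon ids), parallel
#'   to `reports`.
#' @param n evaluation depth, 1..10.
#' @return list(n, precision, recall, f_score, per_dataset).
#' @export
evaluate_topn <- function(reports, truths, n = 5L) {
  stopifnot(length(reports) == length(truths), n >= 1L, n <= 10L)
  if (any(lengths(truths) == 0L)) stop("empty truth set", call. = FALSE)
  per <- t(vapply(seq_along(reports), function(i) {
    R <- head(reports[[i]]$ranked$taxon_id, n)
    T_ <- unique(truths[[i]])
    tp <- length(intersect(R, T_))
    p <- if (length(R)) tp / length(R) else 0
    r <- tp / length(T_)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f_score = f)
  }, c(precision = 0, recall = 0, f_score = 0)))
  list(n = as.integer(n), precision = mean(per[, "precision"]),
       recall = mean(per[, "recall"]), f_score = mean(per[, "f_score"]),
       per_dataset = as.data.frame(per))
}
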