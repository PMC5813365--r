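# Pipeline orchestration: configuration handling, the end-to-end per-sample
# run (preprocess -> cascade -> novel miRNA prediction -> pathogen report),
# and the per-sample QC summary. All outputs are machine-readable TSV/JSON.

#' Default pipeline configuration
#'
#' Houses every numeric parameter of the pipeline at its default: length
#' bands 15-19 nt (0 mismatches) and 20-32 nt (1 mismatch), at most 5 genomic
#' loci for prediction eligibility, k-mer length 18, top-5 pathogen report,
#' hairpin score > 10, shuffle p <= 0.05, barcode_n = 0.
#'
#' @param ... overrides (named).
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "model",
    adapter3 = "",
    barcode_n = 0L,
    min_len = 15L, max_len = 32L,
    max_genome_loci = 5L,
    kmer_len = 18L,
    top_n = 5L,
    n_shuffles = 99L,
    n_trees = 1000L,
    seed = 1L,
    organism = "syn",
    paths = list())
  modifyList(cfg, list(...))
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#' @param path file path (.yaml/.yml or .json).
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Run the pipeline on one sample
#'
#' preprocess -> alignment cascade -> novel miRNA prediction (within tier 2)
#' -> pathogen report. When `out_dir` is given, writes counts.tsv,
#' nto_counts.tsv, tiers.tsv, catalog.gff3 (+ .tsv sidecar), pathogens.json,
#' summary.json and qc.json.
#'
#' @param config configuration list (see [default_config()]); referenced
#'   reference files under `config$paths` (fastq, transcripts, genome, nto,
#'   decoys, pathogen_genomes, taxonomy) or in-memory references under
#'   `config$refs`.
#' @param out_dir optional output directory.
#' @return list with preprocessing stats, cascade result, novel miRNA
#'   prediction, pathogen report and QC summary.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- modifyList(default_config(), config)
  refs <- cfg$refs
  if (is.null(refs)) refs <- list()
  p <- cfg$paths
  load_if <- function(slot, loader, path_key) {
    if (!is.null(refs[[slot]])) return(refs[[slot]])
    if (!is.null(p[[path_key]])) return(loader(p[[path_key]]))
    NULL
  }
  reads <- load_if("reads", read_fastq, "fastq")
  refs$genome <- load_if("genome", read_fasta, "genome")
  refs$nto <- load_if("nto", read_fasta, "nto")
  decoys <- load_if("decoys", read_fasta, "decoys")
  refs$taxonomy <- load_if("taxonomy", read_taxonomy, "taxonomy")
  if (is.null(refs$transcripts) && !is.null(p$transcripts)) {
    fa <- read_fasta(p$transcripts)
    cls <- sub(".*\\|", "", names(fa))
    ok <- cls %in% SRNA_CLASSES
    refs$transcripts <- transcript_set(sub("\\|.*", "", names(fa)),
                                       ifelse(ok, cls, "miRNA"),
                                       cfg$organism, unname(fa))
  }
  if (is.null(refs$kmer_db) && !is.null(p$pathogen_genomes)) {
    fa <- read_fasta(p$pathogen_genomes)
    genomes <- data.frame(taxon_id = sub("\\|.*", "", names(fa)),
                          chrom = names(fa), sequence = unname(fa),
                          stringsAsFactors = FALSE)
    refs$kmer_db <- build_kmer_db(genomes, refs$taxonomy, cfg$kmer_len)
  }
  if (is.null(reads)) stop("run_pipeline: no reads supplied", call. = FALSE)
  mode <- cfg$mode
  if (mode == "model") {
    for (need in c("transcripts", "genome", "kmer_db", "taxonomy", "nto")) {
      if (is.null(refs[[need]])) {
        stop("missing reference for model mode: ", need, call. = FALSE)
      }
    }
  }

  spec <- trim_spec(adapter3 = cfg$adapter3, barcode_n = cfg$barcode_n,
                    min_len = cfg$min_len, max_len = cfg$max_len)
  pp <- preprocess_sample(reads, spec)
  policy <- alignment_policy(max_genome_loci = cfg$max_genome_loci)
  cascade <- run_cascade(pp$reads, refs, policy, mode)

  prediction <- NULL
  report <- NULL
  if (mode == "model") {
    catalog <- new_catalog(cfg$organism)
    prediction <- predict_novel_mirnas(cascade$tier2$hits, refs$genome,
                                       if (is.null(decoys)) character(0) else decoys,
                                       filter_criteria(), catalog,
                                       cfg$n_shuffles, cfg$seed)
    report <- make_report(cascade$tier3, refs$taxonomy, cfg$top_n)
  }
  qc <- qc_summary(cascade$assignments, pp$stats)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cascade$counts)) {
      write_counts(matrix(cascade$counts, ncol = 1,
                          dimnames = list(names(cascade$counts), "sample")),
                   file.path(out_dir, "counts.tsv"))
    }
    if (!is.null(cascade$nto_counts) && length(cascade$nto_counts)) {
      write_counts(matrix(cascade$nto_counts, ncol = 1,
                          dimnames = list(names(cascade$nto_counts), "sample")),
                   file.path(out_dir, "nto_counts.tsv"))
    }
    write.table(cascade$assignments, file.path(out_dir, "tiers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(prediction)) {
      write_catalog(prediction$catalog, file.path(out_dir, "catalog.gff3"),
                    setNames(nchar(refs$genome), names(refs$genome)))
    }
    if (!is.null(report)) {
      jsonlite::write_json(list(ranked = report$ranked,
                                above_species = report$above_species,
                                unclassified = report$unclassified),
                           file.path(out_dir, "pathogens.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(cascade$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(preprocess = pp$stats, cascade = cascade, prediction = prediction,
       pathogen_report = report, qc = qc)
}

#' Per-sample QC summary
#'
#' @param assignments tier assignment table from [run_cascade()].
#' @param preprocess_stats stats from [preprocess_sample()].
#' @return list: input reads, kept reads, per-tier fractions (sum to 1 over
#'   kept reads), length histogram.
#' @export
qc_summary <- function(assignments, preprocess_stats) {
  n_kept <- nrow(assignments)
  tier_counts <- table(factor(assignments$tier, levels = TIERS))
  fractions <- if (n_kept > 0) as.numeric(tier_counts) / n_kept
               else rep(0, length(TIERS))
  list(reads_in = preprocess_stats$reads_in,
       reads_kept = preprocess_stats$reads_kept,
       discarded = preprocess_stats$discarded,
       tier_counts = as.list(setNames(as.integer(tier_counts), TIERS)),
       tier_fractions = as.list(setNames(fractions, TIERS)),
       length_histogram = preprocess_stats$length_histogram)
}
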