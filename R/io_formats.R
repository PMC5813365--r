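# On-disk formats. Everything downstream consumes the plain containers
# produced here: reads as a data.frame (read_id, sequence, quality),
# references as data.frames or named character vectors, counts as a numeric
# matrix (features x samples).

SRNA_CLASSES <- c("miRNA", "piRNA", "snoRNA", "snRNA", "rRNA",
                  "novel_miRNA", "family")

#' Read a (optionally gzipped) 4-line FASTQ file
#'
#' Bases are uppercased and U is converted to T so RNA-space reads and DNA
#' references interoperate. Reads with more than 10% N bases are dropped with
#' a warning. Malformed records (sequence/quality length mismatch, truncated
#' record) raise an error naming the offending line.
#'
#' @param path path to a FASTQ file; gzip detected from content.
#' @param gz force gzip interpretation (optional; auto-detected by default).
#' @return data.frame with columns read_id, sequence, quality.
#' @export
read_fastq <- function(path, gz = NA) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")  # gzfile reads plain text transparently
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record at line %d in %s",
                 length(lines) + 1L, path), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad_hdr)) {
    stop(sprintf("FASTQ header missing '@' at line %d", (bad_hdr[1L] - 1L) * 4L + 1L),
         call. = FALSE)
  }
  bad_len <- which(nchar(seqs) != nchar(quals) | nchar(seqs) == 0L)
  if (length(bad_len)) {
    stop(sprintf("sequence/quality length mismatch at line %d",
                 (bad_len[1L] - 1L) * 4L + 2L), call. = FALSE)
  }
  ids <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[[`, "", 1L))
  seqs <- normalize_seq(seqs)
  assert_dna(seqs, sprintf("FASTQ %s", path))
  n_frac <- vapply(gregexpr("N", seqs, fixed = TRUE), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, 0L) / nchar(seqs)
  drop <- n_frac > 0.10
  if (any(drop)) {
    warning(sprintf("dropping %d read(s) with >10%% N bases", sum(drop)),
            call. = FALSE)
  }
  data.frame(read_id = ids[!drop], sequence = seqs[!drop],
             quality = quals[!drop], stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with read_id, sequence and optional quality
#'   (defaults to "I" per base).
#' @param path output path; names ending in .gz are gzip-compressed.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' The id is the header token before the first whitespace; duplicate ids are
#' an error. Multi-line sequences are concatenated, uppercased, and U
#' converted to T.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- normalize_seq(as.character(ss))
  assert_dna(seqs, sprintf("FASTA %s", path))
  setNames(seqs, ids)
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Build a validated transcript reference set
#'
#' @param transcript_id unique ids.
#' @param srna_class one of miRNA, piRNA, snoRNA, snRNA, rRNA, novel_miRNA,
#'   family.
#' @param organism organism tag.
#' @param sequence DNA sequences.
#' @return data.frame of class records.
#' @export
transcript_set <- function(transcript_id, srna_class, organism, sequence) {
  if (anyDuplicated(transcript_id)) {
    stop("duplicate transcript_id", call. = FALSE)
  }
  if (!all(srna_class %in% SRNA_CLASSES)) {
    stop("unknown srna_class: ",
         paste(setdiff(unique(srna_class), SRNA_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  sequence <- normalize_seq(sequence)
  assert_dna(sequence, "transcript")
  data.frame(transcript_id = transcript_id, srna_class = srna_class,
             organism = organism, sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Read a sample sheet (TSV: sample_id, group, further covariate columns)
#' @param path TSV path with header.
#' @return data.frame; sample_id unique.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs sample_id and group columns", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  sheet
}

#' Write a count matrix as TSV
#'
#' Tab-separated, header = sample ids, first column = feature id, rows in
#' ascending feature order, counts rendered in plain (non-scientific)
#' notation at full double precision.
#'
#' @param matrix numeric matrix, rownames = features, colnames = samples.
#' @param path output TSV.
#' @export
write_counts <- function(matrix, path) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("count matrix is empty", call. = FALSE)
  }
  matrix <- matrix[order(rownames(matrix)), , drop = FALSE]
  txt <- apply(matrix, 2L, function(col) {
    format(col, scientific = FALSE, trim = TRUE, digits = 17)
  })
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(matrix))
  out <- cbind(feature = rownames(matrix), txt)
  colnames(out) <- c("feature", colnames(matrix))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV path.
#' @return numeric matrix (features x samples).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write the novel miRNA catalog as GFF3 plus a sidecar TSV
#'
#' One `pre_miRNA` feature with two `miRNA` children (mature/star arms) per
#' entry. Internal 0-based half-open coordinates are converted to GFF3
#' 1-based inclusive. The sidecar TSV (same path with `.tsv` appended)
#' carries precursor sequence, dot-bracket structure, score, shuffle p-value
#' and software version.
#'
#' @param catalog catalog data.frame from [new_catalog()] /
#'   [filter_and_register()].
#' @param path output GFF3 path.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   bounds checking.
#' @export
write_catalog <- function(catalog, path, chrom_lengths = NULL) {
  lines <- "##gff-version 3"
  if (nrow(catalog)) {
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[catalog$chrom]
      if (any(is.na(len)) || any(catalog$pre_end > len) ||
          any(catalog$pre_start < 0L)) {
        stop("catalog coordinate outside chromosome bounds", call. = FALSE)
      }
    }
    for (i in seq_len(nrow(catalog))) {
      e <- catalog[i, ]
      pre_id <- e$name
      attr_pre <- sprintf("ID=%s;Name=%s", gff3_escape(pre_id),
                          gff3_escape(pre_id))
      lines <- c(lines, paste(e$chrom, "srnacascade", "pre_miRNA",
                              e$pre_start + 1L, e$pre_end, ".", e$strand, ".",
                              attr_pre, sep = "\t"))
      arms <- data.frame(
        suffix = c(e$mature_arm, if (e$mature_arm == "5p") "3p" else "5p"),
        start = c(e$mature_start, e$star_start),
        end = c(e$mature_end, e$star_end))
      for (j in 1:2) {
        cid <- sprintf("%s-%s", pre_id, arms$suffix[j])
        lines <- c(lines, paste(e$chrom, "srnacascade", "miRNA",
                                arms$start[j] + 1L, arms$end[j], ".",
                                e$strand, ".",
                                sprintf("ID=%s;Parent=%s", gff3_escape(cid),
                                        gff3_escape(pre_id)),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  side <- catalog[, c("name", "organism", "chrom", "strand", "pre_start",
                      "pre_end", "precursor_seq", "structure", "score",
                      "randfold_p", "mature_count", "star_count",
                      "software_version")]
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
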