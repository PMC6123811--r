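# Plain-text I/O: FASTQ (Phred+33) via Biostrings, simple TSV tables.

#' Write reads to FASTQ
#'
#' @param ids read identifiers (written as-is, including any comment).
#' @param seqs DNA sequences.
#' @param quals Phred+33 quality strings (same lengths as `seqs`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a paired read set to R1/R2 FASTQ files
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param path1,path2 output paths for R1 and R2.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq(pairs$id, pairs$seq1, pairs$qual1, path1)
  write_fastq(pairs$id, pairs$seq2, pairs$qual2, path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files into a pair table
#'
#' Mates are paired by record order (standard R1/R2 convention); identifiers
#' are taken from R1.
#'
#' @param path1,path2 R1 and R2 FASTQ paths.
#' @return data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("R1 and R2 have different record counts", call. = FALSE)
  }
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Plain TSV read/write
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` (write) or a data.frame (read), invisibly for write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
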