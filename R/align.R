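# Semi-global affine-gap alignment and alignment-derived variant calls.
#
# This is the package's in-repo replacement for an external mapper + variant
# caller: reads are amplicon substrings, so the query is aligned end-to-end
# while reference end gaps are free ("fitting" alignment), under affine gap
# costs (gap of length L costs gap_open + L * gap_extend).

#' Semi-global alignment of a query against a reference
#'
#' Optimal-score semi-global alignment (free end gaps on the reference, query
#' fully aligned) under affine gap costs, with deterministic tie-breaking:
#' match/mismatch preferred over gaps, deletions over insertions, and the
#' smallest reference end point (hence leftmost placement of exact repeats).
#'
#' @param query,reference ACGTN strings (query non-empty).
#' @param scoring a [scoring()] scheme.
#' @return an object of class `alignment`: list with `score`, `ops`
#'   (character vector over M/I/D; M covers both match and mismatch),
#'   `lengths`, `ref_start`, `ref_end` (0-based, half-open span on the
#'   reference), and `query` length bookkeeping.
#' @export
align_semi_global <- function(query, reference, scoring = ampliclone::scoring()) {
  stopifnot(is.character(query), length(query) == 1, nchar(query) > 0,
            is.character(reference), length(reference) == 1,
            nchar(reference) > 0)
  check_dna(query, "query"); check_dna(reference, "reference")
  res <- align_sg_cpp(query, reference, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  res$query_length <- nchar(query)
  class(res) <- "alignment"
  res
}

# Construct the trivial all-match alignment of query placed at ref_start
# (used on the exact-substring fast path; provably optimal since score ==
# query_length * match is the global maximum).
perfect_alignment <- function(query, ref_start, scoring) {
  n <- nchar(query)
  structure(list(score = n * scoring$match, ops = "M", lengths = n,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_start + n), query_length = n),
            class = "alignment")
}

#' CIGAR string of an alignment
#'
#' @param aln an `alignment`.
#' @return character scalar, e.g. `"96M2D104M"`.
#' @export
cigar_string <- function(aln) {
  paste0(paste0(aln$lengths, aln$ops), collapse = "")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %d, ref [%d, %d), cigar %s\n",
              x$score, x$ref_start, x$ref_end, cigar_string(x)))
  invisible(x)
}

#' Brute-force reference score for small alignments
#'
#' Exhaustively enumerates every semi-global alignment path (no dynamic
#' programming) and returns the best affine-gap score.  Exponential in
#' sequence length; restricted to sequences of at most 10 nt.  Serves as the
#' independent oracle that [align_semi_global()] is validated against.
#'
#' @inheritParams align_semi_global
#' @return integer best score.
#' @export
align_score_enumerate <- function(query, reference,
                                  scoring = ampliclone::scoring()) {
  align_score_enum_cpp(query, reference, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
}

#' Extract variants from an alignment
#'
#' One variant per non-match run: consecutive mismatching columns become one
#' multi-base SUB, each gap run one INS/DEL.  Indels are left-normalized.
#' Variant quality is the mean Phred quality of the query bases involved
#' (for DEL: the mean of the two flanking query bases).
#'
#' @param aln an `alignment` of `query` against `reference`.
#' @param reference reference sequence string.
#' @param query query sequence string.
#' @param quals integer vector of per-base Phred qualities of the query
#'   (or a Phred+33 string).
#' @return variant data.frame (see [signature_string()] for the columns).
#' @export
extract_variants <- function(aln, reference, query, quals) {
  if (is.character(quals)) quals <- qual_to_int(quals)
  stopifnot(length(quals) == nchar(query))
  qch <- utf8ToInt(query)
  rch <- utf8ToInt(reference)
  out <- list()
  qpos <- 0L; rpos <- aln$ref_start  # 0-based cursors
  for (k in seq_along(aln$ops)) {
    len <- aln$lengths[k]
    op <- aln$ops[k]
    if (op == "M") {
      qs <- qch[(qpos + 1):(qpos + len)]
      rs <- rch[(rpos + 1):(rpos + len)]
      mism <- which(qs != rs)
      if (length(mism) > 0) {
        # group consecutive mismatches into single SUB records
        brk <- c(0L, which(diff(mism) > 1L), length(mism))
        for (g in seq_len(length(brk) - 1L)) {
          idx <- mism[(brk[g] + 1L):brk[g + 1L]]
          out[[length(out) + 1L]] <- data.frame(
            ref_pos = rpos + idx[1] - 1L, kind = "SUB",
            ref = intToUtf8(rs[idx]), alt = intToUtf8(qs[idx]),
            qual = mean(quals[qpos + idx]), stringsAsFactors = FALSE)
        }
      }
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op == "I") {
      ins <- substr(query, qpos + 1L, qpos + len)
      norm <- left_normalize(reference, rpos, ins)
      out[[length(out) + 1L]] <- data.frame(
        ref_pos = norm$pos, kind = "INS", ref = "", alt = norm$seq,
        qual = mean(quals[(qpos + 1):(qpos + len)]), stringsAsFactors = FALSE)
      qpos <- qpos + len
    } else if (op == "D") {
      del <- substr(reference, rpos + 1L, rpos + len)
      norm <- left_normalize(reference, rpos, del)
      flank <- c(if (qpos >= 1L) quals[qpos], if (qpos < length(quals)) quals[qpos + 1L])
      out[[length(out) + 1L]] <- data.frame(
        ref_pos = norm$pos, kind = "DEL", ref = norm$seq, alt = "",
        qual = mean(flank), stringsAsFactors = FALSE)
      rpos <- rpos + len
    }
  }
  if (length(out) == 0) return(empty_variants())
  v <- do.call(rbind, out)
  v[order(v$ref_pos, v$kind), , drop = FALSE]
}

# Union of two mates' variant sets: identical variants are merged (keeping the
# higher quality); conflicting calls at the same position and kind with a
# different allele drop the lower-quality one.
merge_pair_variants <- function(v1, v2) {
  v <- rbind(v1, v2)
  if (nrow(v) <= 1) return(v)
  key_full <- paste(v$ref_pos, v$kind, v$ref, v$alt)
  v <- v[order(key_full, -v$qual), , drop = FALSE]
  v <- v[!duplicated(paste(v$ref_pos, v$kind, v$ref, v$alt)), , drop = FALSE]
  key_site <- paste(v$ref_pos, v$kind)
  v <- v[order(key_site, -v$qual), , drop = FALSE]
  v <- v[!duplicated(paste(v$ref_pos, v$kind)), , drop = FALSE]
  v[order(v$ref_pos, v$kind), , drop = FALSE]
}

#' Write alignments as SAM records
#'
#' Minimal single-reference SAM output for external inspection.
#'
#' @param alignments list of `alignment` objects.
#' @param names,seqs,quals read names, sequences and Phred+33 quality strings.
#' @param ref_name,ref_length reference name and length for the header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, names, seqs, quals, ref_name, ref_length,
                      path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_length)), con)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       names[i], ref_name, a$ref_start + 1L, cigar_string(a),
                       seqs[i], quals[i]), con)
  }
  invisible(path)
}
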