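# Per-read WT / HDR / NHEJ classification and per-clone allele tallies.
#
# A read (pair) is aligned to both the wild-type and the HDR-edited
# reference.  It is called WT if its WT alignment shows no variant with
# quality >= qual_threshold inside the edit window, HDR if its HDR alignment
# shows none, and NHEJ otherwise, with the WT-relative window variant set as
# its allele signature.  Reads that cover the window on neither mate, or that
# are consistent with both references (possible only when every diagnostic
# position is missing or low-quality), are UNINFORMATIVE.

# Align one mate to one reference, with a provably-optimal fast path when the
# read is an exact substring (score = length * match is the global maximum;
# leftmost placement matches the DP tie-break).
analyze_mate <- function(seq, quals, ref, scoring) {
  hit <- regexpr(seq, ref, fixed = TRUE)
  if (hit > 0L) {
    aln <- perfect_alignment(seq, hit - 1L, scoring)
    return(list(aln = aln, variants = empty_variants()))
  }
  aln <- align_semi_global(seq, ref, scoring)
  list(aln = aln, variants = extract_variants(aln, ref, seq, quals))
}

covers_window <- function(aln, ws, we) {
  aln$ref_start <= ws && aln$ref_end >= we
}

# Highest quality among aligned query bases that sit on `positions` (0-based
# ref coords) and match the reference base there; -Inf if none aligned.
best_matching_qual_at <- function(aln, positions, seq, quals, ref) {
  best <- -Inf
  qpos <- 0L; rpos <- aln$ref_start
  for (k in seq_along(aln$ops)) {
    len <- aln$lengths[k]; op <- aln$ops[k]
    if (op == "M") {
      inrun <- positions[positions >= rpos & positions < rpos + len]
      for (p in inrun) {
        qi <- qpos + (p - rpos) + 1L
        if (substr(seq, qi, qi) == substr(ref, p + 1L, p + 1L)) {
          best <- max(best, quals[qi])
        }
      }
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op == "I") {
      qpos <- qpos + len
    } else {
      rpos <- rpos + len
    }
  }
  best
}

# Analyse a pair against one reference: union of mate variant sets
# (conflicts keep the higher-quality call), window coverage, and the
# qualifying (in-window, quality >= threshold) variant subset.
analyze_pair_vs_ref <- function(m1, m2, ref, window, scoring, qual_threshold) {
  a1 <- analyze_mate(m1$seq, m1$quals, ref, scoring)
  a2 <- analyze_mate(m2$seq, m2$quals, ref, scoring)
  v <- merge_pair_variants(a1$variants, a2$variants)
  ws <- window[1]; we <- window[2]
  inw <- variant_in_window(v, ws, we)
  qualifying <- v[inw & v$qual >= qual_threshold, , drop = FALSE]
  list(a1 = a1, a2 = a2,
       covered = covers_window(a1$aln, ws, we) || covers_window(a2$aln, ws, we),
       qualifying = qualifying,
       flank_n = sum(!inw & v$qual >= qual_threshold))
}

#' Classify a read pair as WT, HDR, NHEJ or UNINFORMATIVE
#'
#' @param seq1,qual1 R1 sequence (barcode already stripped) and Phred+33
#'   qualities.
#' @param seq2,qual2 R2 sequence and qualities (as sequenced; R2 is
#'   reverse-complemented internally).
#' @param refs a [reference_pair()].
#' @param scoring a [scoring()] scheme.
#' @param qual_threshold minimum variant quality for a variant to count
#'   against a reference (default 30).
#' @return list with `class` (`"WT"`, `"HDR"`, `"NHEJ"`,
#'   `"UNINFORMATIVE"`), `signature` (canonical WT-relative window variant
#'   string; empty except for NHEJ) and `flank_variants` (count of
#'   quality-passing variants outside the window, logged but ignored).
#' @export
classify_read <- function(seq1, qual1, seq2, qual2, refs,
                          scoring = ampliclone::scoring(),
                          qual_threshold = 30) {
  if (identical(refs$wt_seq, refs$hdr_seq)) {
    stop("reference pair has identical sequences", call. = FALSE)
  }
  m1 <- list(seq = seq1, quals = qual_to_int(qual1))
  m2 <- list(seq = revcomp(seq2), quals = rev(qual_to_int(qual2)))
  ws <- refs$edit_window[1]; we <- refs$edit_window[2]
  hdr_window <- c(ws, we + nchar(refs$hdr_seq) - nchar(refs$wt_seq))
  diag_pos <- diagnostic_positions(refs)

  wt <- analyze_pair_vs_ref(m1, m2, refs$wt_seq, c(ws, we), scoring,
                            qual_threshold)
  if (!wt$covered) {
    return(list(class = "UNINFORMATIVE", signature = "",
                flank_variants = wt$flank_n))
  }
  wt_clean <- nrow(wt$qualifying) == 0
  if (wt_clean && length(diag_pos) > 0) {
    # a confident WT base on any diagnostic position rules the HDR reference
    # out without aligning to it
    q1 <- best_matching_qual_at(wt$a1$aln, diag_pos, m1$seq, m1$quals,
                                refs$wt_seq)
    q2 <- best_matching_qual_at(wt$a2$aln, diag_pos, m2$seq, m2$quals,
                                refs$wt_seq)
    if (max(q1, q2) >= qual_threshold) {
      return(list(class = "WT", signature = "", flank_variants = wt$flank_n))
    }
  }
  hdr <- analyze_pair_vs_ref(m1, m2, refs$hdr_seq, hdr_window, scoring,
                             qual_threshold)
  hdr_clean <- hdr$covered && nrow(hdr$qualifying) == 0
  if (wt_clean && hdr_clean) {
    return(list(class = "UNINFORMATIVE", signature = "",
                flank_variants = wt$flank_n))
  }
  if (wt_clean) {
    return(list(class = "WT", signature = "", flank_variants = wt$flank_n))
  }
  if (hdr_clean) {
    return(list(class = "HDR", signature = "", flank_variants = hdr$flank_n))
  }
  list(class = "NHEJ", signature = signature_string(wt$qualifying),
       flank_variants = wt$flank_n)
}

#' Classify every read pair of a sample
#'
#' @param pairs barcode-stripped read-pair table (`id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`).
#' @inheritParams classify_read
#' @return data.frame with `id`, `class`, `signature`, `flank_variants`.
#' @export
classify_reads <- function(pairs, refs, scoring = ampliclone::scoring(),
                           qual_threshold = 30) {
  n <- nrow(pairs)
  class <- character(n); signature <- character(n); flank <- integer(n)
  for (i in seq_len(n)) {
    r <- classify_read(pairs$seq1[i], pairs$qual1[i], pairs$seq2[i],
                       pairs$qual2[i], refs, scoring, qual_threshold)
    class[i] <- r$class; signature[i] <- r$signature
    flank[i] <- r$flank_variants
  }
  data.frame(id = pairs$id, class = class, signature = signature,
             flank_variants = flank, stringsAsFactors = FALSE)
}

#' Tally distinct alleles from a clone's read classifications
#'
#' Groups informative calls by (class, signature); frequencies are computed
#' over informative reads only, UNINFORMATIVE reads are counted separately.
#'
#' @param calls data.frame from [classify_reads()].
#' @param clone_id clone identifier stored in the table.
#' @return an object of class `allele_table`: list with `clone_id`,
#'   `alleles` (data.frame `class`, `signature`, `reads`, `frequency`,
#'   sorted by decreasing read count), `informative`, `uninformative` and
#'   `total` read counts.
#' @export
tally_alleles <- function(calls, clone_id = "clone") {
  inf <- calls[calls$class != "UNINFORMATIVE", , drop = FALSE]
  if (nrow(inf) > 0) {
    agg <- stats::aggregate(list(reads = rep(1L, nrow(inf))),
                            by = list(class = inf$class,
                                      signature = inf$signature),
                            FUN = sum)
    agg$frequency <- agg$reads / nrow(inf)
    agg <- agg[order(-agg$reads, agg$class, agg$signature), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(class = character(0), signature = character(0),
                      reads = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE)
  }
  structure(list(clone_id = clone_id, alleles = agg,
                 informative = nrow(inf),
                 uninformative = nrow(calls) - nrow(inf),
                 total = nrow(calls)),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %s: %d informative / %d total reads\n",
              x$clone_id, x$informative, x$total))
  print(x$alleles)
  invisible(x)
}
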