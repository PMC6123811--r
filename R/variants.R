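# Variant records and canonical allele signatures.
#
# A variant set is a data.frame with columns:
#   ref_pos (0-based int), kind ("SUB"|"INS"|"DEL"), ref (chr), alt (chr),
#   qual (numeric, Phred-scaled)
# SUB has equal-length ref/alt; INS has ref == ""; DEL has alt == "".
# Indels are left-normalized: shifted to the smallest ref_pos that preserves
# the alternate haplotype (VCF-style left alignment).

empty_variants <- function() {
  data.frame(ref_pos = integer(0), kind = character(0), ref = character(0),
             alt = character(0), qual = numeric(0), stringsAsFactors = FALSE)
}

#' Left-normalize an indel
#'
#' Shifts a deletion/insertion to the smallest reference position that yields
#' the same alternate haplotype.  Idempotent.
#'
#' @param ref reference sequence (character scalar).
#' @param pos 0-based position of the first deleted base (DEL) or of the base
#'   the insertion precedes (INS).
#' @param seq deleted (DEL) or inserted (INS) bases.
#' @return list with normalized `pos` and `seq`.
#' @export
left_normalize <- function(ref, pos, seq) {
  rch <- strsplit(ref, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  if (L == 0) return(list(pos = pos, seq = seq))
  while (pos > 0 && rch[pos] == s[L]) {
    s <- c(rch[pos], s[-L])
    pos <- pos - 1L
  }
  list(pos = as.integer(pos), seq = paste(s, collapse = ""))
}

# TRUE for variants whose reference footprint overlaps [ws, we).
variant_in_window <- function(v, ws, we) {
  if (nrow(v) == 0) return(logical(0))
  len <- ifelse(v$kind == "INS", 1L, nchar(v$ref))
  v$ref_pos < we & (v$ref_pos + pmax(len, 1L)) > ws
}

#' Canonical signature string of a variant set
#'
#' Variants sorted by position and kind, formatted as
#' `SUB:<pos>:<ref>><alt>`, `DEL:<pos>:<deleted>`, `INS:<pos>:<inserted>`,
#' joined by `;`.  The empty set gives `""`.
#'
#' @param v variant data.frame.
#' @return character scalar.
#' @export
signature_string <- function(v) {
  if (nrow(v) == 0) return("")
  v <- v[order(v$ref_pos, v$kind), , drop = FALSE]
  # canonical form: adjacent substitutions collapse into one multi-base SUB
  # (alignment-derived calls report mismatch runs that way)
  if (nrow(v) > 1) {
    keep <- rep(TRUE, nrow(v))
    for (i in 2:nrow(v)) {
      j <- max(which(keep[1:(i - 1)]))
      if (v$kind[i] == "SUB" && v$kind[j] == "SUB" &&
          v$ref_pos[i] == v$ref_pos[j] + nchar(v$ref[j])) {
        v$ref[j] <- paste0(v$ref[j], v$ref[i])
        v$alt[j] <- paste0(v$alt[j], v$alt[i])
        keep[i] <- FALSE
      }
    }
    v <- v[keep, , drop = FALSE]
  }
  parts <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    parts[i] <- switch(v$kind[i],
      SUB = sprintf("SUB:%d:%s>%s", v$ref_pos[i], v$ref[i], v$alt[i]),
      DEL = sprintf("DEL:%d:%s", v$ref_pos[i], v$ref[i]),
      INS = sprintf("INS:%d:%s", v$ref_pos[i], v$alt[i]),
      stop("unknown variant kind: ", v$kind[i]))
  }
  paste(parts, collapse = ";")
}

#' Parse a canonical signature string back into a variant set
#'
#' @param sig signature string as produced by [signature_string()].
#' @return variant data.frame (quals set to NA).
#' @export
parse_signature <- function(sig) {
  if (is.na(sig) || sig == "") return(empty_variants())
  parts <- strsplit(sig, ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    kind <- f[1]; pos <- as.integer(f[2])
    if (kind == "SUB") {
      ra <- strsplit(f[3], ">", fixed = TRUE)[[1]]
      data.frame(ref_pos = pos, kind = "SUB", ref = ra[1], alt = ra[2],
                 qual = NA_real_, stringsAsFactors = FALSE)
    } else if (kind == "DEL") {
      data.frame(ref_pos = pos, kind = "DEL", ref = f[3], alt = "",
                 qual = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(ref_pos = pos, kind = "INS", ref = "", alt = f[3],
                 qual = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Apply a variant set to a reference sequence
#'
#' Builds the alternate haplotype by applying variants right-to-left.
#'
#' @param ref reference sequence (character scalar).
#' @param v variant data.frame (or a signature string).
#' @return the edited sequence.
#' @export
apply_variants <- function(ref, v) {
  if (is.character(v)) v <- parse_signature(v)
  if (nrow(v) == 0) return(ref)
  v <- v[order(-v$ref_pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$ref_pos[i]
    ref <- switch(v$kind[i],
      SUB = paste0(substr(ref, 1, p), v$alt[i],
                   substr(ref, p + 1 + nchar(v$alt[i]), nchar(ref))),
      DEL = paste0(substr(ref, 1, p),
                   substr(ref, p + 1 + nchar(v$ref[i]), nchar(ref))),
      INS = paste0(substr(ref, 1, p), v$alt[i],
                   substr(ref, p + 1, nchar(ref))))
  }
  ref
}

#' Write variants as minimal VCF records
#'
#' CHROM = reference name, 1-based POS, REF/ALT with the VCF anchor-base
#' convention for indels, QUAL = the variant quality.
#'
#' @param v variant data.frame.
#' @param refs a [reference_pair()] (supplies CHROM and anchor bases).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", refs$name,
                       nchar(refs$wt_seq)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v) > 0) {
    v <- v[order(v$ref_pos), , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      p <- v$ref_pos[i]
      if (v$kind[i] == "SUB") {
        pos1 <- p + 1L; ref <- v$ref[i]; alt <- v$alt[i]
      } else {
        # anchor on the preceding base (VCF convention)
        anchor <- substr(refs$wt_seq, p, p)
        if (p == 0) anchor <- ""  # degenerate: indel at position 0
        pos1 <- max(p, 1L)
        if (v$kind[i] == "DEL") {
          ref <- paste0(anchor, v$ref[i]); alt <- anchor
        } else {
          ref <- anchor; alt <- paste0(anchor, v$alt[i])
        }
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\t.",
                         refs$name, pos1, ref, alt, v$qual[i]), con)
    }
  }
  invisible(path)
}
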