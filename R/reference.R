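#' Wild-type / HDR reference pair
#'
#' The coordinate frame for every variant and classification in the package:
#' the wild-type amplicon, the HDR-edited amplicon (the sequence expected when
#' the donor template is integrated), the Cas9 cut site, and the *edit window*
#' - the half-open interval `[start, end)` on wild-type coordinates covering
#' the replaced block plus flanking bases.  Only variants inside the edit
#' window count towards read classification.
#'
#' All coordinates are 0-based, half-open; conversion to 1-based happens only
#' at VCF/SAM export boundaries.
#'
#' @param name reference name (used as CHROM in VCF export).
#' @param wt_seq wild-type amplicon sequence (uppercase ACGT).
#' @param hdr_seq HDR-edited amplicon sequence; must differ from `wt_seq`
#'   only inside `edit_window`.
#' @param cut_site 0-based offset of the Cas9 cut site into `wt_seq`; must lie
#'   inside `edit_window`.
#' @param edit_window integer length-2 vector `c(start, end)`, half-open, on
#'   `wt_seq` coordinates.
#' @return an object of class `reference_pair`.
#' @seealso [default_reference()] for the packaged synthetic fixture.
#' @export
reference_pair <- function(name, wt_seq, hdr_seq, cut_site, edit_window) {
  wt_seq <- toupper(wt_seq); hdr_seq <- toupper(hdr_seq)
  check_dna(wt_seq, "wt_seq"); check_dna(hdr_seq, "hdr_seq")
  if (nchar(wt_seq) == 0 || nchar(hdr_seq) == 0) {
    stop("reference sequences must be non-empty", call. = FALSE)
  }
  stopifnot(length(edit_window) == 2, edit_window[1] < edit_window[2])
  edit_window <- as.integer(edit_window)
  cut_site <- as.integer(cut_site)
  if (cut_site < edit_window[1] || cut_site >= edit_window[2]) {
    stop("cut_site must lie inside edit_window", call. = FALSE)
  }
  if (identical(wt_seq, hdr_seq)) {
    stop("wt_seq and hdr_seq are identical: no diagnostic positions",
         call. = FALSE)
  }
  # hdr may differ only inside the window (equal flanks; hdr can change length
  # only by the window block changing length)
  nw <- nchar(wt_seq); nh <- nchar(hdr_seq)
  ws <- edit_window[1]; we <- edit_window[2]
  if (we > nw) stop("edit_window exceeds wt_seq length", call. = FALSE)
  left_ok <- substr(wt_seq, 1, ws) == substr(hdr_seq, 1, ws)
  right_ok <- substr(wt_seq, we + 1, nw) ==
    substr(hdr_seq, we + 1 + (nh - nw), nh)
  if (!left_ok || !right_ok) {
    stop("hdr_seq differs from wt_seq outside edit_window", call. = FALSE)
  }
  structure(
    list(name = name, wt_seq = wt_seq, hdr_seq = hdr_seq,
         cut_site = cut_site, edit_window = edit_window),
    class = "reference_pair"
  )
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf(
    "<reference_pair> %s: wt %d nt, hdr %d nt, cut site %d, edit window [%d, %d)\n",
    x$name, nchar(x$wt_seq), nchar(x$hdr_seq), x$cut_site,
    x$edit_window[1], x$edit_window[2]))
  invisible(x)
}

#' Packaged synthetic reference fixture
#'
#' A deterministic 400-nt synthetic amplicon with a 12-nt block replaced in the
#' HDR version, emulating a knock-in that substitutes 12 bp at the target
#' locus.  The cut site (offset 150) is placed off-centre, as amplicon primers
#' rarely straddle the cut symmetrically; with the default 200-bp reads this
#' keeps the edit window fully inside read 1 while the amplicon stays at least
#' twice the read length.  The HDR block differs from wild type at all 12
#' positions, so any read covering the window is diagnostic.
#'
#' The sequence is generated from a fixed internal seed and is identical on
#' every call; no real locus sequence is used or required.
#'
#' @return a [reference_pair()].
#' @export
default_reference <- function() {
  wt <- with_seed(664001L, random_dna(400))
  ws <- 144L; we <- 156L
  block <- substr(wt, ws + 1, we)
  # every base shifted (A->C->G->T->A): differs at all 12 positions
  hdr_block <- chartr("ACGT", "CGTA", block)
  hdr <- paste0(substr(wt, 1, ws), hdr_block, substr(wt, we + 1, nchar(wt)))
  reference_pair("synthetic_amplicon", wt, hdr,
                 cut_site = 150L, edit_window = c(139L, 161L))
}

# Positions (0-based) where wt and hdr differ, within the edit window.
# Assumes equal-length replacement inside the window (the supported case for
# diagnostic-position shortcuts; unequal lengths fall back to full alignment).
diagnostic_positions <- function(refs) {
  if (nchar(refs$wt_seq) != nchar(refs$hdr_seq)) return(integer(0))
  w <- utf8ToInt(refs$wt_seq); h <- utf8ToInt(refs$hdr_seq)
  which(w != h) - 1L
}

#' Read a reference pair from FASTA
#'
#' Expects a FASTA file with two records named `wt` and `hdr` (or uses the
#' first two records in that order).
#'
#' @param path FASTA file path.
#' @param cut_site,edit_window see [reference_pair()].
#' @param name optional reference name; defaults to the file stem.
#' @return a [reference_pair()].
#' @export
read_reference_pair <- function(path, cut_site, edit_window, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2) stop("FASTA must contain wt and hdr records", call. = FALSE)
  nms <- tolower(names(seqs))
  wt_i <- if ("wt" %in% nms) match("wt", nms) else 1L
  hdr_i <- if ("hdr" %in% nms) match("hdr", nms) else 2L
  reference_pair(name %||% sub("\\.[^.]*$", "", basename(path)),
                 as.character(seqs[[wt_i]]), as.character(seqs[[hdr_i]]),
                 cut_site, edit_window)
}

#' Write a reference pair to FASTA
#'
#' @param refs a [reference_pair()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_pair <- function(refs, path) {
  x <- Biostrings::DNAStringSet(c(wt = refs$wt_seq, hdr = refs$hdr_seq))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
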