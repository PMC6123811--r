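#' Editing-outcome model
#'
#' Per-allele probabilities of the three repair outcomes at the cut site.
#' Defaults reflect a locus where HDR runs at roughly 20% of alleles in bulk
#' and NHEJ dominates the remainder, with occasional editing that resolves
#' only after the first cell division (producing clones with more than two
#' alleles) and rare cross-contamination of a clone's read pool.
#'
#' @param p_hdr probability an allele is HDR-repaired.
#' @param p_nhej probability an allele carries an NHEJ outcome
#'   (`p_hdr + p_nhej <= 1`; the remainder stays wild type).
#' @param indel_length_dist named numeric vector of probabilities over signed
#'   indel lengths (negative = deletion); no mass at 0; must sum to 1.
#' @param p_nhej_sub fraction of NHEJ outcomes that are substitution-only
#'   (1-3 point mutations inside the edit window) instead of an indel.
#' @param p_late_edit probability editing resolves only after the first
#'   division: the clone then has four allele lineages at fraction 0.25.
#' @param contamination_rate probability a clone's read pool includes reads
#'   from a random other clone.
#' @param contaminant_fraction per-read probability of coming from the
#'   contaminant when contamination occurs.
#' @return an object of class `edit_model`.
#' @export
edit_model <- function(p_hdr = 0.2, p_nhej = 0.6,
                       indel_length_dist = default_indel_dist(),
                       p_nhej_sub = 0.1,
                       p_late_edit = 0.1,
                       contamination_rate = 0.02,
                       contaminant_fraction = 0.15) {
  check_prob(p_hdr, "p_hdr"); check_prob(p_nhej, "p_nhej")
  check_prob(p_nhej_sub, "p_nhej_sub"); check_prob(p_late_edit, "p_late_edit")
  check_prob(contamination_rate, "contamination_rate")
  check_prob(contaminant_fraction, "contaminant_fraction")
  if (p_hdr + p_nhej > 1 + 1e-12) {
    stop("p_hdr + p_nhej must be <= 1", call. = FALSE)
  }
  lens <- as.integer(names(indel_length_dist))
  if (length(lens) != length(indel_length_dist) || length(lens) == 0 ||
      anyNA(lens) || any(lens == 0L)) {
    stop("indel_length_dist must be named by non-zero signed lengths",
         call. = FALSE)
  }
  if (any(indel_length_dist < 0) ||
      abs(sum(indel_length_dist) - 1) > 1e-8) {
    stop("indel_length_dist must be a probability distribution", call. = FALSE)
  }
  structure(
    list(p_hdr = p_hdr, p_nhej = p_nhej,
         indel_length_dist = indel_length_dist, p_nhej_sub = p_nhej_sub,
         p_late_edit = p_late_edit, contamination_rate = contamination_rate,
         contaminant_fraction = contaminant_fraction),
    class = "edit_model")
}

#' Default NHEJ indel length distribution
#'
#' Geometric-like decay over lengths 1-10 with deletions weighted 1.5x over
#' insertions, the usual shape of Cas9 NHEJ spectra (short deletions dominate).
#'
#' @return named numeric vector over -10..-1, 1..10 summing to 1.
#' @export
default_indel_dist <- function() {
  lens <- c(-10:-1, 1:10)
  w <- 0.65^(abs(lens) - 1) * ifelse(lens < 0, 1.5, 1)
  setNames(w / sum(w), lens)
}

#' Sequencing error model
#'
#' @param sub_rate per-base substitution probability.
#' @param seq_indel_rate per-base sequencing indel probability (half
#'   insertions, half deletions).
#' @param read_length sequenced read length (read 1 includes the inline
#'   barcode within this length).
#' @param depth read pairs per clone.
#' @param q_correct Phred quality assigned to correct bases.
#' @param q_error Phred quality assigned to substituted/inserted bases; the
#'   default 12 vs 37 gives the downstream quality-30 filter discriminating
#'   power.
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.003, seq_indel_rate = 1e-4,
                        read_length = 200L, depth = 100L,
                        q_correct = 37L, q_error = 12L) {
  check_prob(sub_rate, "sub_rate"); check_prob(seq_indel_rate, "seq_indel_rate")
  if (sub_rate >= 1 || seq_indel_rate >= 1) {
    stop("error rates must be < 1", call. = FALSE)
  }
  stopifnot(read_length > 0, depth > 0, q_correct >= 0, q_error >= 0)
  structure(
    list(sub_rate = sub_rate, seq_indel_rate = seq_indel_rate,
         read_length = as.integer(read_length), depth = as.integer(depth),
         q_correct = as.integer(q_correct), q_error = as.integer(q_error)),
    class = "error_model")
}

#' On-chip growth model
#'
#' Defaults describe cells penned four days after electroporation: doubling
#' time around 18 h, roughly 40% of penned single cells forming a colony, and
#' under 2% of initially empty pens acquiring cells during culture.
#'
#' @param doubling_time_h colony doubling time in hours.
#' @param p_no_growth probability a penned single cell fails to form a colony.
#' @param p_contam_pen probability an initially empty pen acquires cells.
#' @param timepoints_h observation times in hours (must include 0).
#' @param count_cv optional multiplicative coefficient of variation applied to
#'   counts after growth (0 = the exact `round(2^(t/doubling))` law).
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(doubling_time_h = 18, p_no_growth = 0.6,
                         p_contam_pen = 0.02,
                         timepoints_h = c(0, 24, 48, 72),
                         count_cv = 0) {
  stopifnot(doubling_time_h > 0, count_cv >= 0, 0 %in% timepoints_h)
  check_prob(p_no_growth, "p_no_growth")
  check_prob(p_contam_pen, "p_contam_pen")
  structure(
    list(doubling_time_h = doubling_time_h, p_no_growth = p_no_growth,
         p_contam_pen = p_contam_pen,
         timepoints_h = sort(unique(as.numeric(timepoints_h))),
         count_cv = count_cv),
    class = "growth_model")
}

#' Alignment scoring scheme
#'
#' Affine gap costs: a gap of length L costs `gap_open + L * gap_extend`.
#' Defaults use bwa-like magnitudes (match 2, mismatch 4, open 6, extend 1);
#' exact parity with any external aligner is not claimed.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (>= 0, applied as negative).
#' @param gap_open gap opening penalty (>= gap_extend).
#' @param gap_extend per-base gap extension penalty (>= 0).
#' @return an object of class `scoring`.
#' @export
scoring <- function(match = 2L, mismatch = 4L, gap_open = 6L, gap_extend = 1L) {
  stopifnot(match > 0, mismatch >= 0, gap_extend >= 0, gap_open >= gap_extend)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
    class = "scoring")
}
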