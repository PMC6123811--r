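# Shared fixtures built in code.

REFS <- default_reference()
SC <- scoring()

# Error-free quality string of length n (Q37).
q37 <- function(n) paste(rep(rawToChar(as.raw(37 + 33)), n), collapse = "")

# Build an error-free read pair from a full allele sequence using the same
# primer-anchored geometry as the simulator (no barcode).
perfect_pair <- function(allele_seq, read_length = 192L, r2_length = 200L) {
  n <- nchar(allele_seq)
  seq1 <- substr(allele_seq, 1, read_length)
  seq2 <- revcomp(substr(allele_seq, max(1, n - r2_length + 1), n))
  list(seq1 = seq1, qual1 = q37(nchar(seq1)),
       seq2 = seq2, qual2 = q37(nchar(seq2)))
}

classify_pair <- function(p, refs = REFS, ...) {
  classify_read(p$seq1, p$qual1, p$seq2, p$qual2, refs, ...)
}

# Phred+33 conversions (test-local).
qual_to_ints <- function(q) utf8ToInt(q) - 33L
ints_to_qual <- function(x) intToUtf8(x + 33L)

# Hamming distance between equal-length strings (test-local oracle helper).
hamming_str <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Random DNA string of length n (test-local; uses the session RNG).
random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random scoring scheme for property-style alignment tests.
random_scoring <- function() {
  ge <- sample(0:3, 1)
  scoring(match = sample(1:5, 1), mismatch = sample(0:6, 1),
          gap_open = ge + sample(0:5, 1), gap_extend = ge)
}

# Calls table with `n` reads of a given (class, signature).
call_rows <- function(class, signature, n) {
  data.frame(id = sprintf("r%03d", seq_len(n)), class = class,
             signature = signature, flank_variants = 0L,
             stringsAsFactors = FALSE)
}

# Allele table assembled from (class, signature, reads) triplets.
make_table <- function(..., clone_id = "cl", uninformative = 0L) {
  rows <- list(...)
  calls <- do.call(rbind, lapply(rows, function(r) {
    call_rows(r[[1]], r[[2]], r[[3]])
  }))
  if (uninformative > 0) {
    calls <- rbind(calls, call_rows("UNINFORMATIVE", "", uninformative))
  }
  calls$id <- sprintf("r%04d", seq_len(nrow(calls)))
  tally_alleles(calls, clone_id)
}
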