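# Inline-barcode demultiplexing.  The barcode is read from the R1 prefix
# only; R2 is paired by record order.

#' Barcode map
#'
#' @param sample_ids sample (clone) identifiers.
#' @param barcodes DNA barcodes, one per sample; all the same length,
#'   pairwise distinct.  A named character vector can be passed as
#'   `barcodes` alone.
#' @return an object of class `barcode_map`.
#' @export
barcode_map <- function(barcodes, sample_ids = names(barcodes)) {
  force(sample_ids)
  barcodes <- toupper(as.character(barcodes))
  if (is.null(sample_ids)) stop("sample_ids are required", call. = FALSE)
  check_dna(barcodes, "barcodes")
  if (length(unique(nchar(barcodes))) != 1) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be distinct", call. = FALSE)
  }
  structure(list(entries = setNames(barcodes, sample_ids),
                 barcode_length = nchar(barcodes[1])),
            class = "barcode_map")
}

#' Read/write a barcode map as TSV
#'
#' Two columns: `sample_id`, `barcode`.
#'
#' @param map a [barcode_map()] (for writing).
#' @param path TSV path.
#' @return a `barcode_map` (read) or `path` invisibly (write).
#' @export
read_barcode_map <- function(path) {
  x <- read_tsv(path)
  barcode_map(x$barcode, x$sample_id)
}

#' @rdname read_barcode_map
#' @export
write_barcode_map <- function(map, path) {
  write_tsv(data.frame(sample_id = names(map$entries),
                       barcode = unname(map$entries)), path)
}

#' Demultiplex read pairs by inline barcode
#'
#' Each pair is assigned to the unique sample whose barcode lies within
#' `max_mismatch` Hamming distance of the R1 prefix; pairs matching no
#' barcode, or more than one, go to the unassigned set.  Assigned pairs are
#' emitted with the barcode prefix stripped from R1 (sequence and qualities).
#' Reads are partitioned: every input pair appears in exactly one output set,
#' in input order.
#'
#' @param pairs read-pair table (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param map a [barcode_map()].
#' @param max_mismatch maximum Hamming distance allowed (default 0: exact).
#' @return list with `samples` (named list of pair tables), `unassigned`
#'   (pair table) and `summary` (data.frame `sample_id`, `assigned`,
#'   `fraction`).
#' @export
demultiplex <- function(pairs, map, max_mismatch = 0L) {
  stopifnot(inherits(map, "barcode_map"), max_mismatch >= 0)
  bl <- map$barcode_length
  if (any(nchar(pairs$seq1) < bl)) {
    stop("reads shorter than the barcode length", call. = FALSE)
  }
  codes <- map$entries
  # unavoidable ambiguity: a prefix could sit within max_mismatch of two codes
  if (length(codes) > 1) {
    dmin <- min(utils::combn(codes, 2, function(p) hamming(p[1], p[2])))
    if (dmin <= 2L * max_mismatch) {
      stop(sprintf(paste0("barcode set has minimum pairwise distance %d; ",
                          "ambiguity is unavoidable with max_mismatch = %d"),
                   dmin, max_mismatch), call. = FALSE)
    }
  }
  n <- nrow(pairs)
  prefix <- substr(pairs$seq1, 1L, bl)
  if (n > 0) {
    pm <- matrix(utf8ToInt(paste(prefix, collapse = "")), nrow = bl)
    dist <- vapply(codes, function(b) {
      colSums(pm != utf8ToInt(b))
    }, numeric(n))
    dist <- matrix(dist, nrow = n)
    ok <- dist <= max_mismatch
    nhit <- rowSums(ok)
    assigned <- ifelse(nhit == 1L, max.col(ok, ties.method = "first"), NA_integer_)
  } else {
    assigned <- integer(0)
  }
  strip <- function(df) {
    df$seq1 <- substr(df$seq1, bl + 1L, nchar(df$seq1))
    df$qual1 <- substr(df$qual1, bl + 1L, nchar(df$qual1))
    df
  }
  samples <- lapply(seq_along(codes), function(k) {
    strip(pairs[!is.na(assigned) & assigned == k, , drop = FALSE])
  })
  names(samples) <- names(codes)
  unassigned <- pairs[is.na(assigned), , drop = FALSE]
  counts <- vapply(samples, nrow, 1L)
  list(samples = samples, unassigned = unassigned,
       summary = data.frame(sample_id = names(codes),
                            assigned = unname(counts),
                            fraction = if (n > 0) unname(counts) / n else 0,
                            stringsAsFactors = FALSE))
}
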