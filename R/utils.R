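#' @useDynLib ampliclone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom rbinom rnorm runif setNames coef lm cor
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  # per-string base-R implementation: orders of magnitude faster than round
  # tripping single reads through XStringSet containers
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x),
         function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Derive a reproducible child seed from a master seed and an identifier
#'
#' Stable polynomial string hash (independent of R's RNG) so that every
#' clone/pen/stage gets its own deterministic stream from one master seed.
#'
#' @param master integer master seed.
#' @param id character or integer identifier.
#' @return a single integer in `[0, 2147483628]`.
#' @export
child_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- as.double(abs(master) %% 2147483629)
  for (c in utf8ToInt(as.character(id))) {
    h <- (h * 31 + c) %% 2147483629
  }
  as.integer(h)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Phred+33 helpers.
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(x) intToUtf8(x + 33L)

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside ACGTN", what), call. = FALSE)
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
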