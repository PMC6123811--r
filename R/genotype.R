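# Clone-level diploid genotype calls from allele tables.

#' Genotype label levels
#'
#' All labels [call_genotype()] can produce, in reporting order.
#' @export
GENOTYPE_LABELS <- c("WT/WT", "HDR/WT", "HDR/NHEJ", "NHEJ/WT",
                     "NHEJ/NHEJ_same", "NHEJ/NHEJ_diff", "HDR/HDR",
                     "MULTI_ALLELIC", "LOW_COVERAGE")

# Shared labelling rule: `alleles` has columns class, signature and is
# already filtered to the retained set.
label_from_retained <- function(alleles) {
  n <- nrow(alleles)
  if (n == 0) return("LOW_COVERAGE")
  if (n > 2) return("MULTI_ALLELIC")
  if (n == 1) {
    return(switch(alleles$class, WT = "WT/WT", HDR = "HDR/HDR",
                  NHEJ = "NHEJ/NHEJ_same"))
  }
  cl <- sort(alleles$class)
  if (identical(cl, c("HDR", "WT"))) return("HDR/WT")
  if (identical(cl, c("HDR", "NHEJ"))) return("HDR/NHEJ")
  if (identical(cl, c("NHEJ", "WT"))) return("NHEJ/WT")
  if (identical(cl, c("NHEJ", "NHEJ"))) return("NHEJ/NHEJ_diff")
  # two identical classes with distinct signatures can only be NHEJ; WT/WT
  # and HDR/HDR pairs collapse to one allele row upstream
  "MULTI_ALLELIC"
}

#' Call a diploid genotype from an allele table
#'
#' Alleles with frequency >= `min_allele_frac` and at least `min_reads`
#' supporting reads are retained; one retained allele gives a homozygous
#' label, two a heterozygous label, more than two MULTI_ALLELIC (flagged as
#' possible cross-contamination or post-division editing).  Clones with fewer
#' than `min_reads` informative reads are LOW_COVERAGE.
#'
#' @param table an [tally_alleles()] result.
#' @param min_reads minimum informative reads per clone, and minimum
#'   supporting reads per retained allele (default 10).
#' @param min_allele_frac minimum allele frequency to retain (default 0.20,
#'   between sequencing noise and the 0.25 late-edit lineage fraction).
#' @return an object of class `clone_genotype`: list with `clone_id`,
#'   `label`, `alleles` (retained rows), `flags` (character vector) and the
#'   read counts carried over from the table.
#' @export
call_genotype <- function(table, min_reads = 10L, min_allele_frac = 0.20) {
  stopifnot(inherits(table, "allele_table"))
  flags <- character(0)
  if (table$informative < min_reads) {
    label <- "LOW_COVERAGE"
    kept <- table$alleles[0, , drop = FALSE]
    flags <- "low_coverage"
  } else {
    keep <- table$alleles$frequency >= min_allele_frac &
      table$alleles$reads >= min_reads
    kept <- table$alleles[keep, , drop = FALSE]
    label <- label_from_retained(kept)
    if (label == "MULTI_ALLELIC") {
      flags <- "possible_contamination_or_late_editing"
    } else if (label == "LOW_COVERAGE") {
      flags <- "no_allele_above_thresholds"
    }
    dropped <- sum(!keep)
    if (dropped > 0) flags <- c(flags, sprintf("minor_alleles_filtered:%d", dropped))
  }
  structure(list(clone_id = table$clone_id, label = label, alleles = kept,
                 flags = flags, informative = table$informative,
                 uninformative = table$uninformative, total = table$total),
            class = "clone_genotype")
}

#' @export
print.clone_genotype <- function(x, ...) {
  cat(sprintf("<clone_genotype> %s: %s (%d informative reads%s)\n",
              x$clone_id, x$label, x$informative,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' True genotype label of a simulated clone
#'
#' Applies the same retention/labelling rule as [call_genotype()] to the
#' simulator's ground-truth lineage fractions, giving the label a perfect
#' pipeline should recover.
#'
#' @param truth a [simulate_clone()] result.
#' @param min_allele_frac retention threshold on lineage fraction.
#' @return a genotype label string.
#' @export
truth_genotype <- function(truth, min_allele_frac = 0.20) {
  kept <- truth$alleles[truth$alleles$fraction >= min_allele_frac, ,
                        drop = FALSE]
  label_from_retained(kept)
}

#' Summarize the genotype calls of a run
#'
#' Counts and proportions per genotype label, plus HDR- and NHEJ-allele rates
#' computed over bi-allelically called clones (each contributing two allele
#' slots; MULTI_ALLELIC and LOW_COVERAGE clones are reported as their own
#' classes and excluded from allele-rate denominators).
#'
#' @param genotypes list of `clone_genotype` objects (or a character vector
#'   of labels).
#' @param groups optional grouping factor (e.g. day 1 vs day 4), one value
#'   per clone; groups with no clones are simply absent from the result.
#' @return for ungrouped input, a list with `n`, `counts`, `proportions`,
#'   `hdr_allele_rate`, `nhej_allele_rate`; for grouped input, a named list
#'   of such summaries.
#' @export
summarize_run <- function(genotypes, groups = NULL) {
  labels <- if (is.character(genotypes)) genotypes
            else vapply(genotypes, `[[`, "", "label")
  if (length(labels) == 0) stop("no genotypes to summarize", call. = FALSE)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(labels))
    return(lapply(split(labels, groups), summarize_run))
  }
  counts <- table(factor(labels, levels = GENOTYPE_LABELS))
  n <- length(labels)
  slots <- c("WT/WT" = 2, "HDR/WT" = 1, "HDR/NHEJ" = 1, "NHEJ/WT" = 1,
             "NHEJ/NHEJ_same" = 2, "NHEJ/NHEJ_diff" = 2, "HDR/HDR" = 2)
  hdr_slots <- c("HDR/WT" = 1, "HDR/NHEJ" = 1, "HDR/HDR" = 2)
  nhej_slots <- c("HDR/NHEJ" = 1, "NHEJ/WT" = 1, "NHEJ/NHEJ_same" = 2,
                  "NHEJ/NHEJ_diff" = 2)
  called <- sum(counts[names(slots)])
  total_slots <- 2 * called
  list(n = n,
       counts = counts,
       proportions = counts / n,
       n_called_biallelic = called,
       hdr_allele_rate = if (called > 0)
         sum(counts[names(hdr_slots)] * hdr_slots) / total_slots else NA_real_,
       nhej_allele_rate = if (called > 0)
         sum(counts[names(nhej_slots)] * nhej_slots) / total_slots else NA_real_)
}

#' Flatten genotype calls to a table
#'
#' @param genotypes list of `clone_genotype` objects.
#' @return data.frame with one row per clone: `clone_id`, `label`,
#'   `informative`, `uninformative`, `alleles` (semicolon-joined
#'   `class@frequency` descriptors) and `flags`.
#' @export
genotype_table <- function(genotypes) {
  do.call(rbind, lapply(genotypes, function(g) {
    data.frame(
      clone_id = g$clone_id, label = g$label, informative = g$informative,
      uninformative = g$uninformative,
      alleles = paste(sprintf("%s[%s]@%.3f", g$alleles$class,
                              g$alleles$signature, g$alleles$frequency),
                      collapse = ";"),
      flags = paste(g$flags, collapse = ","), stringsAsFactors = FALSE)
  }))
}
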