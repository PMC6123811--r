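# Workflow statistics of nanofluidic chip runs: clonal expansion, pen
# cross-contamination, growth, export, staining and screening-size planning.
#
# Pen tables are data.frames with columns pen_id, condition, initial_count,
# fluorescence and one count column per timepoint named t<hours> (t0, t24,
# t48, t72, ...), as produced by simulate_pens() / read by read_tsv().

pen_timepoints <- function(pens) {
  tc <- grep("^t[0-9.]+$", names(pens), value = TRUE)
  if (length(tc) == 0) stop("pen table has no t<hours> count columns",
                            call. = FALSE)
  setNames(as.numeric(sub("^t", "", tc)), tc)
}

#' On-chip clonal expansion efficiency (OCCE)
#'
#' Fraction of pens loaded with a single cell whose colony reaches at least
#' `min_cells` cells at the 72 h timepoint.  Pens loaded with 0 or >1 cells
#' are excluded from numerator and denominator (clonality rule).
#'
#' @param pens pen table.
#' @param at_hour assessment timepoint in hours (default 72).
#' @param min_cells colony-size threshold (default 6).
#' @return fraction in `[0, 1]`.
#' @export
occe <- function(pens, at_hour = 72, min_cells = 6L) {
  tp <- pen_timepoints(pens)
  col <- names(tp)[tp == at_hour]
  if (length(col) != 1) {
    stop(sprintf("pen table has no %g h timepoint", at_hour), call. = FALSE)
  }
  single <- pens$initial_count == 1L
  if (!any(single)) stop("no single-cell pens: OCCE undefined", call. = FALSE)
  mean(pens[[col]][single] >= min_cells)
}

#' Pen cross-contamination rate
#'
#' Fraction of initially empty pens that acquired any cells at a later
#' timepoint.
#'
#' @param pens pen table.
#' @return fraction in `[0, 1]`.
#' @export
contamination_rate <- function(pens) {
  tp <- pen_timepoints(pens)
  later <- names(tp)[tp > 0]
  empty <- pens$initial_count == 0L
  if (!any(empty)) stop("no initially empty pens: rate undefined",
                        call. = FALSE)
  gained <- rowSums(as.matrix(pens[empty, later, drop = FALSE]) > 0) > 0
  mean(gained)
}

#' Doubling time from a cell-count time series
#'
#' Least-squares slope of `log2(count)` against hours; the doubling time is
#' the reciprocal slope.  Zero counts are excluded from the fit; with fewer
#' than two usable points, or a non-increasing series (slope <= 0), the value
#' is undefined and `NA` is returned with a warning.  An exact
#' `2^(t/D)` series returns `D` to machine precision.
#'
#' @param counts cell counts.
#' @param hours observation times; defaults to `names(counts)` parsed as
#'   numbers (accepting the `t<hours>` convention).
#' @param method `"regression"` (default) or `"endpoint"` (log2 ratio of the
#'   last to first positive counts over the elapsed time).
#' @return doubling time in hours, or `NA`.
#' @export
doubling_time <- function(counts, hours = NULL,
                          method = c("regression", "endpoint")) {
  method <- match.arg(method)
  if (is.null(hours)) hours <- as.numeric(sub("^t", "", names(counts)))
  stopifnot(length(counts) == length(hours), !anyNA(hours))
  keep <- counts > 0
  counts <- counts[keep]; hours <- hours[keep]
  if (length(counts) < 2) {
    warning("fewer than two positive counts: doubling time undefined")
    return(NA_real_)
  }
  slope <- if (method == "regression") {
    unname(coef(lm(log2(counts) ~ hours))[2])
  } else {
    (log2(counts[length(counts)]) - log2(counts[1])) /
      (hours[length(hours)] - hours[1])
  }
  if (!is.finite(slope) || slope <= 0) {
    warning("non-increasing series: doubling time undefined")
    return(NA_real_)
  }
  1 / slope
}

#' Export efficiency
#'
#' Fraction of export records where more than one cell was transferred to the
#' channel (`exported_ok`).
#'
#' @param records export table with logical `exported_ok`.
#' @return fraction in `[0, 1]`.
#' @export
export_efficiency <- function(records) {
  if (nrow(records) == 0) stop("no export records", call. = FALSE)
  mean(records$exported_ok)
}

#' Post-export viability stratified by number of cells exported
#'
#' Among successful exports, the survival fraction of clones that had at
#' least `threshold_cells` cells exported versus fewer, plus the Spearman
#' rank correlation between cells exported and survival.  Empty strata are
#' reported as `NA` (absent), not zero.
#'
#' @param records export table (`cells_exported`, `exported_ok`, `survived`).
#' @param threshold_cells stratification threshold (default 10).
#' @return list with `high` and `low` (each `n` and `survival`),
#'   `threshold_cells` and `rank_correlation`.
#' @export
viability_by_export_size <- function(records, threshold_cells = 10L) {
  ok <- records[records$exported_ok, , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful exports", call. = FALSE)
  hi <- ok$cells_exported >= threshold_cells
  strat <- function(sel) {
    list(n = sum(sel),
         survival = if (any(sel)) mean(ok$survived[sel]) else NA_real_)
  }
  rc <- if (length(unique(ok$survived)) > 1 &&
            length(unique(ok$cells_exported)) > 1) {
    suppressWarnings(cor(ok$cells_exported, as.numeric(ok$survived),
                         method = "spearman"))
  } else NA_real_
  list(high = strat(hi), low = strat(!hi),
       threshold_cells = threshold_cells, rank_correlation = rc)
}

#' Staining positivity of colonised pens
#'
#' Fraction of colonised pens (final count >= `min_cells`, the same colony
#' criterion as [occe()]) whose fluorescence intensity reaches `threshold`,
#' grouped by condition tag.  Pens with missing intensities are excluded with
#' a message.
#'
#' @param pens pen table.
#' @param intensity_threshold positivity threshold (arbitrary units; the
#'   on-chip threshold is assay-specific and must be supplied).
#' @param min_cells colony criterion (default 6).
#' @return named numeric vector: fraction positive per condition.
#' @export
staining_positivity <- function(pens, intensity_threshold, min_cells = 6L) {
  tp <- pen_timepoints(pens)
  final <- names(tp)[which.max(tp)]
  colonised <- pens[pens[[final]] >= min_cells, , drop = FALSE]
  if (nrow(colonised) == 0) stop("no colonised pens", call. = FALSE)
  miss <- is.na(colonised$fluorescence)
  if (any(miss)) {
    message(sum(miss), " colonised pen(s) without intensity excluded")
    colonised <- colonised[!miss, , drop = FALSE]
  }
  vapply(split(colonised, colonised$condition), function(d) {
    mean(d$fluorescence >= intensity_threshold)
  }, numeric(1))
}

#' Screening-size planner
#'
#' With per-clone success probability `p_success` (e.g. the bi-allelic HDR
#' rate) and post-export viability `viability`, screening `n` clones yields
#' `n * p_success * viability` expected viable edited clones; the tail
#' probability of at least `k` comes from the binomial with success
#' probability `p_success * viability`.  In inverse mode (`n = NULL`,
#' `target_prob` given) the smallest `n` achieving
#' `P(at least k) >= target_prob` is returned.
#'
#' @param p_success probability a screened clone carries the desired edit.
#' @param viability probability an exported clone survives expansion.
#' @param n number of clones screened (forward mode).
#' @param k required number of viable edited clones (default 1).
#' @param target_prob target `P(at least k)` (inverse mode).
#' @return list with `p_joint`, and either `n`, `expected`, `p_at_least_k`
#'   (forward) or `n_required` plus the achieved tail probability (inverse).
#' @export
screening_plan <- function(p_success, viability, n = NULL, k = 1L,
                           target_prob = NULL) {
  check_prob(p_success, "p_success"); check_prob(viability, "viability")
  p <- p_success * viability
  if (!is.null(n)) {
    stopifnot(n >= 1)
    return(list(p_joint = p, n = n, expected = n * p,
                p_at_least_k = pbinom(k - 1, n, p, lower.tail = FALSE)))
  }
  if (is.null(target_prob)) stop("give either n or target_prob", call. = FALSE)
  check_prob(target_prob, "target_prob")
  if (p <= 0) stop("zero joint probability: no n can reach the target",
                   call. = FALSE)
  n_try <- max(k, 1L)
  while (pbinom(k - 1, n_try, p, lower.tail = FALSE) < target_prob) {
    n_try <- n_try + 1L
    if (n_try > 1e7) stop("target unreachable below n = 1e7", call. = FALSE)
  }
  list(p_joint = p, n_required = n_try,
       expected = n_try * p,
       p_at_least_k = pbinom(k - 1, n_try, p, lower.tail = FALSE))
}

#' Compute all chip statistics for a run
#'
#' @param pens pen table (or `NULL`).
#' @param exports export table (or `NULL`).
#' @param intensity_threshold staining threshold passed to
#'   [staining_positivity()].
#' @param viability_threshold cells-exported threshold for
#'   [viability_by_export_size()].
#' @return list of the individual statistics (absent inputs give `NULL`
#'   entries).
#' @export
chip_stats <- function(pens = NULL, exports = NULL,
                       intensity_threshold = 1000,
                       viability_threshold = 10L) {
  out <- list()
  if (!is.null(pens)) {
    tp <- pen_timepoints(pens)
    out$occe <- occe(pens)
    out$contamination_rate <- contamination_rate(pens)
    single_grown <- pens$initial_count == 1L &
      pens[[names(tp)[which.max(tp)]]] >= 6L
    dt <- vapply(which(single_grown), function(i) {
      suppressWarnings(doubling_time(unlist(pens[i, names(tp)]),
                                     unname(tp)))
    }, numeric(1))
    out$mean_doubling_time_h <- if (any(!is.na(dt))) mean(dt, na.rm = TRUE)
                                else NA_real_
    out$staining_positivity <-
      as.list(staining_positivity(pens, intensity_threshold))
  }
  if (!is.null(exports)) {
    out$export_efficiency <- export_efficiency(exports)
    out$viability <- viability_by_export_size(exports, viability_threshold)
  }
  out
}
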