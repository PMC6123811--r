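# Synthetic-data module: ground-truth edited clones, their barcoded amplicon
# reads, and chip/export tables.  Every stochastic entry point takes a seed;
# run-level generators derive per-clone/per-pen child seeds by stable hashing
# (child_seed) so outputs are reproducible and order-independent.

#' Canonical WT-relative signature of the HDR block
#'
#' The variant set distinguishing the HDR-edited reference from wild type,
#' as a canonical signature string (see [signature_string()]).
#'
#' @param refs a [reference_pair()].
#' @return character scalar.
#' @export
hdr_signature <- function(refs) {
  wt <- refs$wt_seq; hdr <- refs$hdr_seq
  if (nchar(wt) == nchar(hdr)) {
    w <- utf8ToInt(wt); h <- utf8ToInt(hdr)
    mism <- which(w != h)
    brk <- c(0L, which(diff(mism) > 1L), length(mism))
    out <- lapply(seq_len(length(brk) - 1L), function(g) {
      idx <- mism[(brk[g] + 1L):brk[g + 1L]]
      data.frame(ref_pos = idx[1] - 1L, kind = "SUB",
                 ref = intToUtf8(w[idx]), alt = intToUtf8(h[idx]),
                 qual = NA_real_, stringsAsFactors = FALSE)
    })
    signature_string(do.call(rbind, out))
  } else {
    # unequal-length replacement: encode as block deletion + insertion
    ws <- refs$edit_window[1]; we <- refs$edit_window[2]
    nh <- nchar(hdr) - nchar(wt) + we - ws
    del <- left_normalize(wt, ws, substr(wt, ws + 1, we))
    v <- rbind(
      data.frame(ref_pos = del$pos, kind = "DEL", ref = del$seq, alt = "",
                 qual = NA_real_, stringsAsFactors = FALSE),
      data.frame(ref_pos = ws, kind = "INS", ref = "",
                 alt = substr(hdr, ws + 1, ws + nh), qual = NA_real_,
                 stringsAsFactors = FALSE))
    signature_string(v)
  }
}

# One editing-outcome draw using the current RNG stream.
.draw_outcome <- function(model, refs) {
  r <- runif(1)
  if (r < model$p_hdr) {
    return(list(class = "HDR",
                signature = if (is.null(refs)) "HDR" else hdr_signature(refs)))
  }
  if (r < model$p_hdr + model$p_nhej) {
    if (is.null(refs)) stop("NHEJ outcomes require a reference pair", call. = FALSE)
    wt <- refs$wt_seq; cut <- refs$cut_site
    ws <- refs$edit_window[1]; we <- refs$edit_window[2]
    if (runif(1) < model$p_nhej_sub) {
      k <- sample.int(3L, 1L)
      pos <- sort(sample(ws:(we - 1L), k))
      v <- do.call(rbind, lapply(pos, function(p) {
        refb <- substr(wt, p + 1, p + 1)
        altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        data.frame(ref_pos = p, kind = "SUB", ref = refb, alt = altb,
                   qual = NA_real_, stringsAsFactors = FALSE)
      }))
      return(list(class = "NHEJ", signature = signature_string(v)))
    }
    len <- as.integer(sample(names(model$indel_length_dist), 1L,
                             prob = model$indel_length_dist))
    if (len < 0) {
      L <- min(-len, nchar(wt) - cut)
      norm <- left_normalize(wt, cut, substr(wt, cut + 1, cut + L))
      v <- data.frame(ref_pos = norm$pos, kind = "DEL", ref = norm$seq,
                      alt = "", qual = NA_real_, stringsAsFactors = FALSE)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      norm <- left_normalize(wt, cut, ins)
      v <- data.frame(ref_pos = norm$pos, kind = "INS", ref = "",
                      alt = norm$seq, qual = NA_real_, stringsAsFactors = FALSE)
    }
    return(list(class = "NHEJ", signature = signature_string(v)))
  }
  list(class = "WT", signature = "")
}

#' Draw a single allele editing outcome
#'
#' Returns WT with an empty signature, HDR with the canonical HDR signature,
#' or NHEJ with an indel placed at the cut site (left-normalized) or, with
#' probability `p_nhej_sub`, 1-3 point mutations inside the edit window.
#'
#' @param model an [edit_model()].
#' @param refs a [reference_pair()] (required for NHEJ outcomes; with
#'   `refs = NULL` an HDR outcome carries the placeholder signature `"HDR"`).
#' @param seed optional integer seed (draws from the current RNG stream when
#'   `NULL`).
#' @return list with `class` (`"WT"`, `"HDR"` or `"NHEJ"`) and `signature`.
#' @export
draw_allele_outcome <- function(model, refs = default_reference(),
                                seed = NULL) {
  stopifnot(inherits(model, "edit_model"))
  if (is.null(seed)) .draw_outcome(model, refs)
  else with_seed(seed, .draw_outcome(model, refs))
}

#' Simulate the true allele composition of one clone
#'
#' A diploid clone resolves editing either before its first division (two
#' allele lineages at fraction 0.5) or, with probability `p_late_edit`, after
#' it (four lineages at 0.25: two independent outcome draws per parental
#' allele).  Lineages with identical (class, signature) are merged, so a
#' late-editing clone can present 2-4 distinct alleles.
#'
#' @inheritParams draw_allele_outcome
#' @param clone_id clone identifier.
#' @return an object of class `clone_truth`: list with `clone_id`, `alleles`
#'   (data.frame `class`, `signature`, `fraction`), `late_edit` and
#'   `contaminated` flags.
#' @export
simulate_clone <- function(model, refs = default_reference(),
                           clone_id = "clone", seed = NULL) {
  stopifnot(inherits(model, "edit_model"))
  run <- function() {
    late <- runif(1) < model$p_late_edit
    n <- if (late) 4L else 2L
    draws <- lapply(seq_len(n), function(i) .draw_outcome(model, refs))
    df <- data.frame(
      class = vapply(draws, `[[`, "", "class"),
      signature = vapply(draws, `[[`, "", "signature"),
      fraction = rep(1 / n, n), stringsAsFactors = FALSE)
    agg <- stats::aggregate(fraction ~ class + signature, df, sum)
    agg <- agg[order(-agg$fraction, agg$class, agg$signature), , drop = FALSE]
    rownames(agg) <- NULL
    structure(list(clone_id = clone_id,
                   alleles = agg[, c("class", "signature", "fraction")],
                   late_edit = late, contaminated = FALSE),
              class = "clone_truth")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.clone_truth <- function(x, ...) {
  cat(sprintf("<clone_truth> %s (%d allele%s%s)\n", x$clone_id,
              nrow(x$alleles), if (nrow(x$alleles) > 1) "s" else "",
              if (x$late_edit) ", late edit" else ""))
  print(x$alleles)
  invisible(x)
}

# Full amplicon sequence of one allele.
allele_sequence <- function(refs, class, signature) {
  switch(class,
         WT = refs$wt_seq,
         HDR = refs$hdr_seq,
         NHEJ = apply_variants(refs$wt_seq, signature),
         stop("unknown allele class: ", class))
}

# Apply the per-base sequencing error model to one read.
apply_read_errors <- function(seq, err) {
  b <- utf8ToInt(seq)
  n <- length(b)
  q <- rep.int(err$q_correct, n)
  acgt <- utf8ToInt("ACGT")
  if (err$sub_rate > 0) {
    hit <- which(runif(n) < err$sub_rate)
    for (i in hit) b[i] <- sample(acgt[acgt != b[i]], 1L)
    q[hit] <- err$q_error
  }
  if (err$seq_indel_rate > 0) {
    hit <- which(runif(n) < err$seq_indel_rate)
    for (i in rev(hit)) {
      if (runif(1) < 0.5) {
        b <- b[-i]; q <- q[-i]
      } else {
        b <- append(b, sample(acgt, 1L), after = i - 1L)
        q <- append(q, err$q_error, after = i - 1L)
      }
    }
  }
  list(seq = intToUtf8(b), qual = intToUtf8(q + 33L))
}

#' Simulate the amplicon read pairs of one clone
#'
#' Primer-anchored amplicon geometry: read 1 is the inline barcode followed by
#' the start of the allele sequence (total length `read_length`); read 2 is
#' the reverse complement of the final `read_length` bases.  Each pair is
#' drawn from an allele with probability equal to its lineage fraction; when a
#' contaminant clone is supplied, each pair instead comes from the contaminant
#' with probability `contaminant_fraction`.  Every read carries a provenance
#' tag (`src=...`) in its identifier.
#'
#' @param truth a [simulate_clone()] result.
#' @param refs the [reference_pair()] the truth was simulated against.
#' @param err an [error_model()].
#' @param barcode inline sample barcode (length >= 6).
#' @param seed optional integer seed.
#' @param contaminant optional `clone_truth` contributing contaminant reads.
#' @param contaminant_fraction per-read contamination probability when
#'   `contaminant` is given.
#' @return data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   `provenance`, `true_class`, `true_signature`.
#' @export
simulate_reads <- function(truth, refs, err, barcode, seed = NULL,
                           contaminant = NULL, contaminant_fraction = 0) {
  stopifnot(inherits(truth, "clone_truth"), inherits(err, "error_model"))
  if (nchar(barcode) < 6) stop("barcode must be >= 6 nt", call. = FALSE)
  check_dna(barcode, "barcode")
  if (2L * err$read_length > nchar(refs$wt_seq)) {
    warning("reference is shorter than twice the read length; ",
            "mates overlap heavily", call. = FALSE)
  }
  run <- function() {
    al <- truth$alleles
    seqs <- vapply(seq_len(nrow(al)), function(i) {
      allele_sequence(refs, al$class[i], al$signature[i])
    }, "")
    n <- err$depth
    src <- sample.int(nrow(al), n, replace = TRUE, prob = al$fraction)
    prov <- sprintf("allele%d", src)
    src_seq <- seqs[src]
    cls <- al$class[src]; sig <- al$signature[src]
    if (!is.null(contaminant) && contaminant_fraction > 0) {
      is_cont <- runif(n) < contaminant_fraction
      if (any(is_cont)) {
        cal <- contaminant$alleles
        cseqs <- vapply(seq_len(nrow(cal)), function(i) {
          allele_sequence(refs, cal$class[i], cal$signature[i])
        }, "")
        csrc <- sample.int(nrow(cal), sum(is_cont), replace = TRUE,
                           prob = cal$fraction)
        src_seq[is_cont] <- cseqs[csrc]
        cls[is_cont] <- cal$class[csrc]
        sig[is_cont] <- cal$signature[csrc]
        prov[is_cont] <- sprintf("contam:%s", contaminant$clone_id)
      }
    }
    frag1_len <- err$read_length - nchar(barcode)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      aseq <- src_seq[i]
      raw1 <- paste0(barcode, substr(aseq, 1, frag1_len))
      raw2 <- revcomp(substr(aseq, max(1L, nchar(aseq) - err$read_length + 1L),
                             nchar(aseq)))
      r1 <- apply_read_errors(raw1, err)
      r2 <- apply_read_errors(raw2, err)
      out[[i]] <- c(r1$seq, r1$qual, r2$seq, r2$qual)
    }
    m <- do.call(rbind, out)
    data.frame(
      id = sprintf("%s:%04d src=%s", truth$clone_id, seq_len(n), prov),
      seq1 = m[, 1], qual1 = m[, 2], seq2 = m[, 3], qual2 = m[, 4],
      provenance = prov, true_class = cls, true_signature = sig,
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a set of mutually distant inline barcodes
#'
#' Random fixed-length barcodes with pairwise Hamming distance of at least
#' `min_dist` (default 3, so demultiplexing with one allowed mismatch stays
#' unambiguous).
#'
#' @param n number of barcodes.
#' @param length barcode length in nt.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed optional integer seed.
#' @return character vector of barcodes.
#' @export
generate_barcodes <- function(n, length = 8L, min_dist = 3L, seed = NULL) {
  run <- function() {
    out <- character(0)
    tries <- 0L
    while (base::length(out) < n) {
      if ((tries <- tries + 1L) > 200L * n) {
        stop("could not generate enough distant barcodes; ",
             "increase length or lower min_dist", call. = FALSE)
      }
      cand <- random_dna(length)
      if (all(vapply(out, function(b) hamming(b, cand) >= min_dist, TRUE))) {
        out <- c(out, cand)
      }
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a multiplexed sequencing run with ground truth
#'
#' Draws `n_clones` clone truths, assigns each a barcode, simulates the
#' per-clone read pairs (including cross-clone contamination per the edit
#' model) and pools them into one multiplexed pair table.
#'
#' @param n_clones number of clones.
#' @inheritParams simulate_reads
#' @param model an [edit_model()].
#' @param seed master seed; per-clone child seeds are derived by stable
#'   hashing, so each clone's reads do not depend on the others (except
#'   through contaminant identity).
#' @param clone_prefix identifier prefix for the clones.
#' @return list with `truths` (named list of `clone_truth`), `barcodes`
#'   (named character vector), `pairs` (pooled read-pair table) and
#'   `truth_table` (long-format allele truth).
#' @export
simulate_run <- function(n_clones, model = edit_model(),
                         refs = default_reference(), err = error_model(),
                         seed = 1L, clone_prefix = "clone") {
  ids <- sprintf("%s%03d", clone_prefix, seq_len(n_clones))
  truths <- lapply(ids, function(id) {
    simulate_clone(model, refs, id, seed = child_seed(seed, paste0("truth:", id)))
  })
  names(truths) <- ids
  barcodes <- generate_barcodes(n_clones, seed = child_seed(seed, "barcodes"))
  names(barcodes) <- ids
  contam <- with_seed(child_seed(seed, "contamination"), {
    flag <- runif(n_clones) < model$contamination_rate & n_clones > 1
    partner <- vapply(seq_len(n_clones), function(i) {
      if (!flag[i]) NA_integer_ else sample(setdiff(seq_len(n_clones), i), 1L)
    }, 1L)
    list(flag = flag, partner = partner)
  })
  pairs <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    truths[[i]]$contaminated <- contam$flag[i]
    pairs[[i]] <- simulate_reads(
      truths[[i]], refs, err, barcodes[i],
      seed = child_seed(seed, paste0("reads:", ids[i])),
      contaminant = if (contam$flag[i]) truths[[contam$partner[i]]],
      contaminant_fraction = if (contam$flag[i]) model$contaminant_fraction else 0)
    pairs[[i]]$clone_id <- ids[i]
  }
  truth_table <- do.call(rbind, lapply(truths, function(tr) {
    cbind(data.frame(clone_id = tr$clone_id, stringsAsFactors = FALSE),
          tr$alleles,
          data.frame(late_edit = tr$late_edit, contaminated = tr$contaminated))
  }))
  rownames(truth_table) <- NULL
  list(truths = truths, barcodes = barcodes,
       pairs = do.call(rbind, pairs), truth_table = truth_table)
}

#' Simulate pen occupancy and growth tables
#'
#' Pens are loaded with 0 or 1 cell; growing single-cell pens follow
#' `count(t) = round(2^(t / doubling_time_h))` (optionally with multiplicative
#' noise `count_cv`), non-growing pens stay at one cell, and initially empty
#' pens acquire a cell with probability `p_contam_pen` at a random later
#' timepoint and grow from there.  Colonised pens receive a fluorescence
#' intensity: positive colonies around `intensity_pos`, negative around
#' `intensity_neg`, positive with probability `p_positive`.
#'
#' @param g a [growth_model()].
#' @param n_pens number of pens.
#' @param single_cell_fraction fraction of pens loaded with a single cell.
#' @param seed optional integer seed.
#' @param condition condition tag stored per pen (e.g. "edited"/"control").
#' @param p_positive probability a colonised pen stains positive.
#' @param intensity_pos,intensity_neg mean fluorescence of positive/negative
#'   colonies (arbitrary units; SD = 15% of the mean).
#' @return data.frame with `pen_id`, `condition`, `initial_count`,
#'   `fluorescence` and one `t<hour>` count column per timepoint.
#' @export
simulate_pens <- function(g, n_pens, single_cell_fraction = 0.6, seed = NULL,
                          condition = "edited", p_positive = 0.05,
                          intensity_pos = 2000, intensity_neg = 200) {
  stopifnot(inherits(g, "growth_model"), n_pens > 0)
  run <- function() {
    tp <- g$timepoints_h
    init <- as.integer(runif(n_pens) < single_cell_fraction)
    grows <- init == 1L & runif(n_pens) >= g$p_no_growth
    acquires <- init == 0L & runif(n_pens) < g$p_contam_pen
    t_acq <- rep(NA_real_, n_pens)
    later <- tp[tp > 0]
    t_acq[acquires] <- sample(later, sum(acquires), replace = TRUE)
    counts <- matrix(0L, n_pens, length(tp),
                     dimnames = list(NULL, sprintf("t%g", tp)))
    for (k in seq_along(tp)) {
      t <- tp[k]
      c_t <- numeric(n_pens)
      c_t[init == 1L] <- 1
      c_t[grows] <- 2^(t / g$doubling_time_h)
      acq_on <- acquires & !is.na(t_acq) & t >= t_acq
      c_t[acq_on] <- 2^((t - t_acq[acq_on]) / g$doubling_time_h)
      if (g$count_cv > 0 && t > 0) {
        noisy <- c_t > 0
        c_t[noisy] <- c_t[noisy] * exp(rnorm(sum(noisy), 0, g$count_cv))
      }
      counts[, k] <- pmax(as.integer(round(c_t)), ifelse(c_t > 0, 1L, 0L))
    }
    final <- counts[, ncol(counts)]
    colonised <- final >= 6L
    pos <- colonised & runif(n_pens) < p_positive
    fluor <- rep(NA_real_, n_pens)
    fluor[colonised] <- rnorm(sum(colonised),
                              ifelse(pos[colonised], intensity_pos, intensity_neg),
                              0.15 * ifelse(pos[colonised], intensity_pos,
                                            intensity_neg))
    cbind(data.frame(pen_id = sprintf("pen%05d", seq_len(n_pens)),
                     condition = condition, initial_count = init,
                     fluorescence = round(fluor, 1),
                     stringsAsFactors = FALSE),
          as.data.frame(counts))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate clone export records
#'
#' Export succeeds (more than one cell transferred to the channel) with
#' probability `p_export_ok`; successful exports transfer `2 + Poisson(lambda)`
#' cells and survive off-chip with a logistic probability increasing in the
#' number of cells exported.  The default logistic curve passes through 60%
#' survival at 10 cells exported with slope 0.25 per cell.
#'
#' @param n number of exported clones.
#' @param seed optional integer seed.
#' @param p_export_ok probability more than one cell is transferred.
#' @param lambda Poisson mean of additional cells on successful exports.
#' @param surv_intercept,surv_slope logistic survival parameters on the
#'   cells-exported scale.
#' @return data.frame with `clone_id`, `cells_exported`, `exported_ok`,
#'   `survived` (NA when export failed).
#' @export
simulate_exports <- function(n, seed = NULL, p_export_ok = 0.85, lambda = 10,
                             surv_intercept = -2.095, surv_slope = 0.25) {
  run <- function() {
    ok <- runif(n) < p_export_ok
    cells <- integer(n)
    cells[ok] <- 2L + stats::rpois(sum(ok), lambda)
    cells[!ok] <- sample(0:1, sum(!ok), replace = TRUE)
    surv <- rep(NA, n)
    p <- stats::plogis(surv_intercept + surv_slope * cells[ok])
    surv[ok] <- runif(sum(ok)) < p
    data.frame(clone_id = sprintf("clone%03d", seq_len(n)),
               cells_exported = cells, exported_ok = ok, survived = surv,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
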