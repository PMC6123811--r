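# Ground-truth clone, read, pen and export generators.

test_that("forced outcome draws are deterministic in class", {
  m_hdr <- edit_model(p_hdr = 1, p_nhej = 0)
  m_wt <- edit_model(p_hdr = 0, p_nhej = 0)
  for (s in 1:20) {
    o <- draw_allele_outcome(m_hdr, REFS, seed = s)
    expect_equal(o$class, "HDR")
    expect_equal(o$signature, hdr_signature(REFS))
    o2 <- draw_allele_outcome(m_wt, REFS, seed = s)
    expect_equal(o2$class, "WT")
    expect_equal(o2$signature, "")
  }
})

test_that("a point-mass indel distribution gives a 2-bp deletion at the cut site", {
  m <- edit_model(p_hdr = 0, p_nhej = 1, p_nhej_sub = 0,
                  indel_length_dist = c("-2" = 1))
  for (s in 1:10) {
    o <- draw_allele_outcome(m, REFS, seed = s)
    expect_equal(o$class, "NHEJ")
    v <- parse_signature(o$signature)
    expect_equal(v$kind, "DEL")
    expect_equal(nchar(v$ref), 2)
    # placed at the cut site, then left-normalized
    expect_equal(v$ref_pos,
                 left_normalize(REFS$wt_seq, REFS$cut_site,
                                substr(REFS$wt_seq, REFS$cut_site + 1,
                                       REFS$cut_site + 2))$pos)
  }
})

test_that("clone lineage fractions sum to 1 and respect the division model", {
  m0 <- edit_model(p_late_edit = 0)
  m1 <- edit_model(p_late_edit = 1)
  for (s in 1:40) {
    tr0 <- simulate_clone(m0, REFS, "a", seed = s)
    expect_equal(sum(tr0$alleles$fraction), 1)
    expect_true(all(tr0$alleles$fraction %in% c(0.5, 1.0)))
    expect_lte(nrow(tr0$alleles), 2)
    tr1 <- simulate_clone(m1, REFS, "b", seed = s)
    expect_equal(sum(tr1$alleles$fraction), 1)
    expect_true(all(abs(tr1$alleles$fraction / 0.25 -
                          round(tr1$alleles$fraction / 0.25)) < 1e-12))
    expect_lte(nrow(tr1$alleles), 4)
  }
  tr <- simulate_clone(edit_model(p_hdr = 1, p_nhej = 0, p_late_edit = 0),
                       REFS, "c", seed = 3)
  expect_equal(nrow(tr$alleles), 1)
  expect_equal(tr$alleles$class, "HDR")
  expect_equal(tr$alleles$fraction, 1)
})

test_that("late-edit multi-allelic fraction matches exhaustive enumeration", {
  # restrict outcomes to an enumerable space: WT / HDR / 2-bp deletion
  p_hdr <- 0.3; p_nhej <- 0.4
  m <- edit_model(p_hdr = p_hdr, p_nhej = p_nhej, p_nhej_sub = 0,
                  indel_length_dist = c("-2" = 1), p_late_edit = 1)
  # oracle: enumerate the 3^4 outcome combinations of the four draws
  probs <- c(WT = 1 - p_hdr - p_nhej, HDR = p_hdr, DEL2 = p_nhej)
  combos <- expand.grid(a = names(probs), b = names(probs), c = names(probs),
                        d = names(probs), stringsAsFactors = FALSE)
  p_combo <- apply(combos, 1, function(r) prod(probs[r]))
  n_distinct <- apply(combos, 1, function(r) length(unique(r)))
  p_multi_oracle <- sum(p_combo[n_distinct > 2])
  n <- 10000
  multi <- vapply(seq_len(n), function(s) {
    nrow(simulate_clone(m, REFS, "x", seed = s)$alleles) > 2
  }, TRUE)
  se <- sqrt(p_multi_oracle * (1 - p_multi_oracle) / n)
  expect_lt(abs(mean(multi) - p_multi_oracle), 3 * se)
})

test_that("zero-error reads are exact substrings that reconstruct their allele", {
  tr <- simulate_clone(edit_model(p_hdr = 0, p_nhej = 0, p_late_edit = 0),
                       REFS, "wtclone", seed = 1)
  err0 <- error_model(sub_rate = 0, seq_indel_rate = 0, depth = 30)
  bc <- "ACGTACGT"
  rd <- simulate_reads(tr, REFS, err0, bc, seed = 2)
  expect_equal(nrow(rd), 30)
  expect_true(all(startsWith(rd$seq1, bc)))
  stripped <- substr(rd$seq1, nchar(bc) + 1, nchar(rd$seq1))
  expect_true(all(vapply(stripped, function(s) {
    grepl(s, REFS$wt_seq, fixed = TRUE)
  }, TRUE)))
  expect_true(all(vapply(revcomp(rd$seq2), function(s) {
    grepl(s, REFS$wt_seq, fixed = TRUE)
  }, TRUE)))
  # anchored geometry reconstructs the allele start and end exactly
  expect_true(all(stripped == substr(REFS$wt_seq, 1, nchar(stripped[1]))))
})

test_that("read draws follow lineage fractions (binomial check)", {
  m <- edit_model(p_hdr = 1, p_nhej = 0, p_late_edit = 0)
  tr <- simulate_clone(m, REFS, "het", seed = 1)
  tr$alleles <- data.frame(class = c("HDR", "WT"), signature = c(hdr_signature(REFS), ""),
                           fraction = c(0.5, 0.5), stringsAsFactors = FALSE)
  err0 <- error_model(sub_rate = 0, seq_indel_rate = 0, depth = 400)
  rd <- simulate_reads(tr, REFS, err0, "ACGTACGT", seed = 9)
  frac_hdr <- mean(rd$true_class == "HDR")
  # binomial 99% interval around 0.5 at n = 400
  expect_lt(abs(frac_hdr - 0.5), 2.576 * sqrt(0.25 / 400))
})

test_that("provenance tags trace contamination, and absence thereof", {
  m <- edit_model(p_hdr = 1, p_nhej = 0, p_late_edit = 0)
  tr1 <- simulate_clone(m, REFS, "own", seed = 1)
  tr2 <- simulate_clone(edit_model(p_hdr = 0, p_nhej = 0, p_late_edit = 0),
                        REFS, "other", seed = 2)
  err0 <- error_model(sub_rate = 0, seq_indel_rate = 0, depth = 200)
  clean <- simulate_reads(tr1, REFS, err0, "ACGTACGT", seed = 3)
  expect_true(all(startsWith(clean$provenance, "allele")))
  dirty <- simulate_reads(tr1, REFS, err0, "ACGTACGT", seed = 3,
                          contaminant = tr2, contaminant_fraction = 0.3)
  expect_true(any(dirty$provenance == "contam:other"))
  expect_true(all(dirty$true_class[dirty$provenance == "contam:other"] == "WT"))
})

test_that("identical seeds give byte-identical FASTQ output", {
  sim1 <- simulate_run(3, edit_model(), REFS, error_model(depth = 10), seed = 5)
  sim2 <- simulate_run(3, edit_model(), REFS, error_model(depth = 10), seed = 5)
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, c("a_R1.fq", "a_R2.fq"))
  f2 <- file.path(d, c("b_R1.fq", "b_R2.fq"))
  write_fastq_pairs(sim1$pairs, f1[1], f1[2])
  write_fastq_pairs(sim2$pairs, f2[1], f2[2])
  expect_equal(unname(tools::md5sum(f1[1])), unname(tools::md5sum(f2[1])))
  expect_equal(unname(tools::md5sum(f1[2])), unname(tools::md5sum(f2[2])))
  unlink(d, recursive = TRUE)
})

test_that("empirical per-allele HDR frequency tracks p_hdr over many draws", {
  m <- edit_model(p_hdr = 0.2, p_nhej = 0.6)
  n <- 10000
  cls <- vapply(seq_len(n), function(s) {
    draw_allele_outcome(m, REFS, seed = s)$class
  }, "")
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(cls == "HDR") - 0.2), 3 * se)
})

test_that("pen growth follows exponential doubling and the clonality knobs", {
  g <- growth_model(doubling_time_h = 24, p_no_growth = 0, p_contam_pen = 0)
  pens <- simulate_pens(g, 50, single_cell_fraction = 1, seed = 1)
  grown <- pens[pens$initial_count == 1, ]
  expect_true(all(grown$t0 == 1))
  expect_true(all(grown$t24 == 2))
  expect_true(all(grown$t48 == 4))
  expect_true(all(grown$t72 == 8))
  # no growth at all -> OCCE 0 downstream
  g0 <- growth_model(p_no_growth = 1)
  pens0 <- simulate_pens(g0, 50, single_cell_fraction = 1, seed = 2)
  expect_equal(occe(pens0), 0)
})

test_that("empty-pen contamination matches its configured rate", {
  g <- growth_model(p_contam_pen = 0.02)
  pens <- simulate_pens(g, 10000, single_cell_fraction = 0, seed = 7)
  rate <- contamination_rate(pens)
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(rate - 0.02), 2.576 * se)
})

test_that("export records couple survival to export size as configured", {
  ex <- simulate_exports(2000, seed = 4)
  expect_true(all(ex$cells_exported >= 0))
  expect_true(all(is.na(ex$survived[!ex$exported_ok])))
  ok <- ex[ex$exported_ok, ]
  expect_gt(mean(ok$survived[ok$cells_exported >= 10]),
            mean(ok$survived[ok$cells_exported < 10]))
})
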