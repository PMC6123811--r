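# Read classification and allele tallies.

test_that("error-free reads from each reference classify to their class", {
  wt_pair <- perfect_pair(REFS$wt_seq)
  hdr_pair <- perfect_pair(REFS$hdr_seq)
  r_wt <- classify_pair(wt_pair)
  r_hdr <- classify_pair(hdr_pair)
  expect_equal(r_wt$class, "WT")
  expect_equal(r_wt$signature, "")
  expect_equal(r_hdr$class, "HDR")
  expect_equal(r_hdr$signature, "")
})

test_that("a 2-bp deletion at the cut site is NHEJ with a DEL-2 signature", {
  cut <- REFS$cut_site
  allele <- paste0(substr(REFS$wt_seq, 1, cut),
                   substr(REFS$wt_seq, cut + 3, nchar(REFS$wt_seq)))
  r <- classify_pair(perfect_pair(allele))
  expect_equal(r$class, "NHEJ")
  v <- parse_signature(r$signature)
  expect_equal(v$kind, "DEL")
  expect_equal(nchar(v$ref), 2)
})

test_that("window substitutions below the quality threshold do not break a WT call", {
  # one Q12 substitution inside the edit window
  wt <- REFS$wt_seq
  p <- REFS$cut_site + 2L  # 0-based window position
  mut <- paste0(substr(wt, 1, p), chartr("ACGT", "CGTA", substr(wt, p + 1, p + 1)),
                substr(wt, p + 2, nchar(wt)))
  pair <- perfect_pair(mut)
  qv <- qual_to_ints(pair$qual1)
  qv[p + 1] <- 12L
  pair$qual1 <- ints_to_qual(qv)
  r30 <- classify_pair(pair, qual_threshold = 30)
  expect_equal(r30$class, "WT")
  # the same read with the substitution at high quality is NHEJ
  r10 <- classify_pair(pair, qual_threshold = 10)
  expect_equal(r10$class, "NHEJ")
})

test_that("reads missing the edit window are UNINFORMATIVE", {
  # fragment entirely downstream of the window
  tail_seq <- substr(REFS$wt_seq, 201, 400)
  r <- classify_read(tail_seq, q37(200), revcomp(tail_seq), q37(200), REFS)
  expect_equal(r$class, "UNINFORMATIVE")
})

test_that("an identical reference pair is a configuration error", {
  bad <- REFS
  bad$hdr_seq <- bad$wt_seq
  p <- perfect_pair(REFS$wt_seq)
  expect_error(classify_read(p$seq1, p$qual1, p$seq2, p$qual2, bad),
               "identical")
})

test_that("flank variants are logged but do not change the class", {
  wt <- REFS$wt_seq
  mut <- paste0(substr(wt, 1, 20), chartr("ACGT", "CGTA", substr(wt, 21, 21)),
                substr(wt, 22, nchar(wt)))
  r <- classify_pair(perfect_pair(mut))
  expect_equal(r$class, "WT")
  expect_equal(r$flank_variants, 1L)
})

test_that("raising the quality threshold never increases NHEJ calls", {
  set.seed(77)
  m <- edit_model()
  err <- error_model(sub_rate = 0.01, seq_indel_rate = 0, depth = 30)
  sim <- simulate_run(4, m, REFS, err, seed = 41)
  dm <- demultiplex(sim$pairs[, c("id", "seq1", "qual1", "seq2", "qual2")],
                    barcode_map(sim$barcodes), 0)
  pairs <- do.call(rbind, dm$samples)
  thresholds <- c(0, 10, 30, 40)
  nhej <- vapply(thresholds, function(th) {
    sum(classify_reads(pairs, REFS, SC, th)$class == "NHEJ")
  }, 1L)
  expect_true(all(diff(nhej) <= 0))
})

test_that("classification recovers provenance for all informative zero-error reads", {
  sim <- simulate_run(5, edit_model(contamination_rate = 0), REFS,
                      error_model(sub_rate = 0, seq_indel_rate = 0, depth = 20),
                      seed = 50)
  dm <- demultiplex(sim$pairs[, c("id", "seq1", "qual1", "seq2", "qual2")],
                    barcode_map(sim$barcodes), 0)
  for (id in names(dm$samples)) {
    calls <- classify_reads(dm$samples[[id]], REFS)
    truth <- sim$pairs[match(calls$id, sim$pairs$id), ]
    inf <- calls$class != "UNINFORMATIVE"
    expect_true(all(inf))
    expect_equal(calls$class[inf], truth$true_class[inf])
    nhej <- calls$class == "NHEJ"
    expect_equal(calls$signature[nhej], truth$true_signature[nhej])
  }
})

test_that("the allele table is invariant to read order and tallies correctly", {
  calls <- rbind(call_rows("HDR", "", 50), call_rows("WT", "", 30),
                 call_rows("NHEJ", "DEL:150:AC", 15),
                 call_rows("UNINFORMATIVE", "", 5))
  calls$id <- sprintf("r%03d", seq_len(nrow(calls)))
  tab <- tally_alleles(calls, "cl")
  expect_equal(tab$informative, 95L)
  expect_equal(tab$uninformative, 5L)
  expect_equal(tab$total, 100L)
  expect_equal(tab$alleles$reads, c(50L, 30L, 15L))
  expect_equal(tab$alleles$frequency, c(50, 30, 15) / 95)
  set.seed(3)
  tab2 <- tally_alleles(calls[sample(nrow(calls)), ], "cl")
  expect_equal(tab2$alleles, tab$alleles)
})

test_that("tally handles the spec worked examples", {
  # 100 HDR reads -> one allele at frequency 1
  t1 <- make_table(list("HDR", "", 100))
  expect_equal(nrow(t1$alleles), 1)
  expect_equal(t1$alleles$frequency, 1)
  # 50/50 -> two alleles at 0.5
  t2 <- make_table(list("WT", "", 50), list("HDR", "", 50))
  expect_equal(sort(t2$alleles$frequency), c(0.5, 0.5))
  # two NHEJ signatures plus HDR -> three rows summing to 1
  t3 <- make_table(list("NHEJ", "DEL:150:AC", 30), list("NHEJ", "INS:150:T", 30),
                   list("HDR", "", 40))
  expect_equal(nrow(t3$alleles), 3)
  expect_equal(sum(t3$alleles$frequency), 1)
})
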