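---
title: "Genotyping edited clones from barcoded amplicon reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping edited clones from barcoded amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

## Scope and model

`ampliclone` analyses targeted amplicon sequencing of clonal colonies derived
from single CRISPR-edited diploid cells. Each clone's reads carry an inline
barcode; after demultiplexing, each read pair is compared against two
references — the wild-type amplicon and the expected HDR-edited amplicon —
and the clone's diploid genotype is called from the spectrum of distinct
alleles observed. The package also computes the operational statistics of a
nanofluidic single-cell workflow (clonal expansion, pen cross-contamination,
growth rate, export efficiency and viability, staining positivity, and
screening-size planning) from tabular pen and export records; image analysis
and instrument control are out of scope, cell counts enter as numbers.

### The editing outcome model

Each allele of a diploid cell resolves the Cas9 cut independently into one of
three classes: precise template-directed repair (HDR), imprecise repair
(NHEJ: an indel at the cut site or, less often, point mutations only), or no
edit (WT). A clone therefore has two allele lineages at fraction 0.5 each —
unless editing resolves only *after* the first division, in which case four
lineages exist at fraction 0.25 (two independent outcome draws per parental
allele). Lineages with the identical outcome merge, so a late-editing clone
presents 2–4 distinct alleles; this is the simplest model that reproduces the
">2 alleles per clone" phenomenon seen in real runs, and deeper lineage trees
are deliberately not modelled.

NHEJ indels are drawn from a configurable signed-length distribution, placed
with their left edge at the cut site and then left-normalized, so simulator
truth and alignment-derived calls share one canonical coordinate. The default
length distribution decays geometrically (factor 0.65 per extra base,
deletions weighted 1.5× over insertions) — the canonical short-deletion-heavy
shape of Cas9 repair spectra. A small fraction of NHEJ outcomes
(`p_nhej_sub`, default 0.1) are substitution-only: 1–3 point mutations inside
the edit window, because imprecise repair without length change occurs and is
explicitly part of the NHEJ class definition here.

### Classification rule

All coordinates are 0-based half-open. The *edit window* `[start, end)`
covers the replaced block plus flanks; only variants inside it count for
classification, variants in the flanks (PCR or sequencing noise) are logged
but ignored. A read pair is aligned to both references; per reference, the
pair's variant set is the union of its mates' variants (conflicting calls at
one site keep the higher quality). The rule is:

* **WT** — the WT alignment has no variant with quality ≥ `qual_threshold`
  (default 30) inside the window;
* **HDR** — the HDR alignment has none;
* **NHEJ** — otherwise; its *allele signature* is the canonical WT-relative
  window variant set. Reads best explained by "HDR plus an extra indel" are
  still NHEJ — the three-way scheme has no mixed class;
* **UNINFORMATIVE** — no mate fully covers the window, or the read is
  consistent with both references (only possible when every diagnostic
  position is absent or low-quality).

The variant quality used by the filter is the mean Phred quality of the
query bases involved (for deletions, of the two flanking bases). This is a
stated approximation of a genuine caller's site quality, not an equivalence:
it gives the quality-30 threshold exactly the discriminating role it has in
the original workflow (sequencing errors are simulated at Q12, real bases at
Q37), but the numbers are not comparable to a Bayesian caller's QUAL.

### Alignment

Amplicon reads are substrings of the reference, so the aligner is
semi-global ("fitting"): the query aligns end-to-end, reference end gaps are
free. Gap costs are affine (`gap_open + L·gap_extend`); defaults
(match 2, mismatch 4, open 6, extend 1) use bwa-like magnitudes without
claiming parity with any external tool. Tie-breaking is deterministic:
match/mismatch over gaps, deletions over insertions, smallest reference end
point. The production kernel is a Gotoh dynamic program in C++; it is
validated (in the acceptance suite, over ≥ 1000 randomized
sequence/parameter combinations of length ≤ 8) against
`align_score_enumerate()`, a separate brute-force recursion that enumerates
every alignment path and therefore cannot share a bug with the DP tables.
An exact-substring fast path (provably optimal, since `length × match` is
the global score ceiling) bypasses the DP for error-free reads.

### Genotype calling

From the allele table (reads grouped by class and signature, frequencies
over informative reads), alleles with frequency ≥ `min_allele_frac` and
≥ `min_reads` supporting reads are retained. One retained allele gives a
homozygous label (WT/WT, HDR/HDR, NHEJ/NHEJ_same), two a heterozygous label
(HDR/WT, HDR/NHEJ, NHEJ/WT, NHEJ/NHEJ_diff), more than two MULTI_ALLELIC —
a terminal label flagged as possible cross-contamination or post-division
editing, deliberately not resolved into a diploid call. Clones with fewer
informative reads than `min_reads` are LOW_COVERAGE. Phenotype–genotype
discordance (e.g. a staining-negative clone called WT/WT) is reported, never
"corrected".

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `qual_threshold` | 30 | Phred | the variant-quality filter of the original workflow |
| `min_allele_frac` | 0.20 | fraction | between sequencing noise and the 0.25 late-edit lineage fraction |
| `min_reads` | 10 | reads | minimal support for an allele and for a callable clone |
| `max_mismatch` | 0 | bases | no stated barcode tolerance; exactness is the conservative default |
| `p_hdr` / `p_nhej` | 0.2 / 0.6 | per allele | a locus with ~20% bulk HDR and NHEJ-dominant repair |
| `p_late_edit` | 0.1 | per clone | occasional >2-allele clones without dominating the mix |
| `contamination_rate` / `contaminant_fraction` | 0.02 / 0.15 | per clone / per read | rare cross-well contamination, minority of the read pool |
| `sub_rate` | 0.003 | per base | Illumina-like substitution error |
| `q_correct` / `q_error` | 37 / 12 | Phred | errored bases fall below, real bases above, the Q30 filter |
| `read_length` | 200 | nt | keeps the edit window inside read 1 and the amplicon ≥ 2× read length |
| `depth` | 100 | pairs/clone | resolves a 0.25 lineage above the 0.20 threshold; not a measured value |
| `doubling_time_h` | 18 | h | colony doubling of healthy cells penned late after electroporation |
| `p_no_growth` | 0.6 | per pen | ~40% of penned single cells form a colony |
| `p_contam_pen` | 0.02 | per pen | < 2% of empty pens acquire cells |
| scoring | 2/4/6/1 | score units | bwa-like magnitudes |

The packaged reference (`default_reference()`) is a deterministic synthetic
400-nt amplicon whose HDR version replaces a 12-nt block at the cut site
(offset 150), differing at all 12 positions so any window-covering read is
diagnostic. The cut site is off-centre because with 200-nt reads and an
8-nt inline barcode, a centred cut would be coverable by neither mate while
keeping the amplicon at least twice the read length; asymmetric primer
placement is the norm in amplicon designs anyway. No real locus sequence is
used; user references are accepted from FASTA via `read_reference_pair()`.

## What the simulator does and does not emulate

It emulates: per-clone inline barcodes; primer-anchored fixed-length paired
reads; substitution and indel sequencing errors with error-state-dependent
qualities; diploid lineage structure including late-resolving edits;
cross-clone read contamination with per-read provenance tags; pen occupancy
and exponential colony growth with non-growers and empty-pen contamination;
export success and a logistic survival-vs-cells-exported relationship
(passing ~60% survival at 10 cells with slope 0.25/cell).

It does **not** emulate: PCR chimeras or jackpot amplification, flow-cell
artifacts, quality decay along the read, large deletions extending beyond
the amplicon (invisible to this assay by construction), off-target edits, or
real locus sequence context. A green test therefore establishes that the
*analysis* is correct under the stated generative model — not that the model
captures every failure mode of a wet-lab run; the control-fidelity and
recovery acceptance runs quantify exactly the failure modes that are
modelled.

## Numerical choices and degenerate inputs

* Seeding: one master seed; every clone, pen and stage derives a child seed
  by a stable polynomial string hash (`child_seed()`), so outputs are
  reproducible and independent of generation order, and FASTQ output is
  byte-identical across runs of the same config.
* Signatures are canonical: variants sorted by position, adjacent
  substitutions collapsed into one multi-base record, indels left-normalized
  (idempotent). Simulator truth and pipeline calls meet in this one form.
* `doubling_time()` excludes zero counts, returns `NA` with a warning for
  non-increasing or under-determined series, and is exact on `2^(t/D)`
  series; a log-linear fit is preferred over the endpoint ratio for
  robustness to intermediate noise (the endpoint estimator remains available).
* `occe()` and `contamination_rate()` signal explicitly (error) when their
  denominator class is absent rather than returning 0/0.
* Empty strata in `viability_by_export_size()` and empty condition groups in
  `summarize_run()` are reported as absent, not as zeros.
* The screening planner reports both the expectation `n·p·v` and the
  binomial tail `P(≥k)`; "1–2 expected clones from 100 screened" is an
  expectation statement, and the tail makes the guarantee explicit.
* N bases score as mismatches in the aligner; sequences outside ACGTN are
  rejected.

## Design decisions that were genuinely open

* **Read depth per clone** is not a measured quantity anywhere upstream
  (colonies are lysed from > 5 cells, depth depends on pooling); the default
  of 100 pairs is a package choice, justified only by threshold resolution,
  and is configurable.
* **Barcode position**: inline barcodes are read from the R1 prefix only;
  R2 pairs by record order. Dual inline indexing is not modelled.
* **Mates** are aligned independently and their variant sets merged;
  overlap-aware mate merging (consensus base calling) is not attempted.
* **Multi-allelic clones** are a terminal class in all summaries; the HDR-
  and NHEJ-allele rates are computed over bi-allelically called clones only,
  so they are rates among *resolved* allele slots, with MULTI_ALLELIC and
  LOW_COVERAGE reported separately rather than guessed into the denominator.
* **Reads partially covering the window**: full single-mate window coverage
  is required for classification. A partial overlap cannot distinguish HDR
  from WT at the uncovered diagnostic positions; such reads are
  UNINFORMATIVE rather than fractionally counted.

## Known limitations

* The mean-base-quality variant score is a proxy; a clone whose true variant
  happens to sit under systematically low-quality cycles would be
  misclassified toward the reference more often than a haplotype-aware
  caller would.
* Genotype recovery degrades gracefully but measurably below ~30× informative
  depth with `min_reads = 10`; the LOW_COVERAGE label is the guard, not a
  rescue.
* The aligner is O(query × reference) per read; it is meant for amplicons
  (hundreds of nt), not genomes, and has no seed-and-extend heuristics by
  design.
* Contamination and late editing produce the same MULTI_ALLELIC evidence;
  the package flags both hypotheses and provenance tags exist only in
  simulation, so real data cannot be disambiguated downstream of the flag.
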