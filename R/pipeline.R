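# Pipeline orchestration: simulate -> demux -> classify -> genotype ->
# report, as reproducible runs with a serialized config and an output
# manifest (config, seeds, per-stage counts, file checksums).

#' Default pipeline configuration
#'
#' @param ... overrides of the top-level fields: `seed`, `n_clones`,
#'   `n_pens`, `single_cell_fraction`, `n_exports`, `qual_threshold`,
#'   `min_reads`, `min_allele_frac`, `max_mismatch`, and the model parameter
#'   lists `edit`, `error`, `growth`, `scoring` (each a list of arguments to
#'   the corresponding constructor).
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L, n_clones = 24L, n_pens = 2000L, single_cell_fraction = 0.6,
    n_exports = 48L, qual_threshold = 30, min_reads = 10L,
    min_allele_frac = 0.20, max_mismatch = 0L,
    edit = list(), error = list(), growth = list(), scoring = list())
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

config_models <- function(cfg) {
  list(edit = do.call(edit_model, cfg$edit %||% list()),
       error = do.call(error_model, cfg$error %||% list()),
       growth = do.call(growth_model, cfg$growth %||% list()),
       scoring = do.call(scoring, cfg$scoring %||% list()))
}

#' Read / write a pipeline config as JSON
#'
#' @param cfg a [default_config()]-style list (for writing).
#' @param path JSON path.
#' @return a `run_config` (read) or `path` invisibly (write).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # named probability vectors do not survive JSON; rebuild the indel dist
  if (!is.null(cfg$edit$indel_length_dist)) {
    cfg$edit$indel_length_dist <- unlist(cfg$edit$indel_length_dist)
  }
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(serializable_config(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON-safe form: named numeric vectors must become objects, not arrays,
# or their names (e.g. signed indel lengths) are lost.
serializable_config <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$edit$indel_length_dist)) {
    cfg$edit$indel_length_dist <- as.list(cfg$edit$indel_length_dist)
  }
  cfg
}

#' Genotype one demultiplexed sample
#'
#' Classify -> tally -> call for one clone's barcode-stripped read pairs.
#'
#' @param pairs barcode-stripped read-pair table.
#' @param refs a [reference_pair()].
#' @param clone_id clone identifier.
#' @param scoring a [scoring()] scheme.
#' @param qual_threshold,min_reads,min_allele_frac thresholds (see
#'   [classify_read()] and [call_genotype()]).
#' @return list with `calls`, `table` (allele_table), `genotype`.
#' @export
genotype_sample <- function(pairs, refs, clone_id = "clone",
                            scoring = ampliclone::scoring(),
                            qual_threshold = 30, min_reads = 10L,
                            min_allele_frac = 0.20) {
  calls <- classify_reads(pairs, refs, scoring, qual_threshold)
  table <- tally_alleles(calls, clone_id)
  list(calls = calls, table = table,
       genotype = call_genotype(table, min_reads, min_allele_frac))
}

#' Run the full pipeline
#'
#' Executes simulate -> demux -> classify -> genotype -> chip statistics and
#' writes every stage output plus a self-describing manifest under
#' `out_dir`.  Deterministic for a fixed config: re-running with the same
#' config reproduces byte-identical stage files.
#'
#' @param config a [default_config()]-style list, or a path to a JSON config.
#' @param out_dir output directory (created if needed).
#' @param refs a [reference_pair()]; the packaged synthetic fixture by
#'   default.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         refs = default_reference()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- config_models(config)
  pth <- function(f) file.path(out_dir, f)

  # --- stage: simulate -------------------------------------------------
  sim <- simulate_run(config$n_clones, models$edit, refs, models$error,
                      seed = config$seed)
  write_reference_pair(refs, pth("reference.fasta"))
  write_fastq_pairs(sim$pairs, pth("reads_R1.fastq"), pth("reads_R2.fastq"))
  write_tsv(sim$truth_table, pth("truth.tsv"))
  write_barcode_map(barcode_map(sim$barcodes), pth("barcodes.tsv"))
  pens <- simulate_pens(models$growth, config$n_pens,
                        config$single_cell_fraction,
                        seed = child_seed(config$seed, "pens"))
  write_tsv(pens, pth("pens.tsv"))
  exports <- simulate_exports(config$n_exports,
                              seed = child_seed(config$seed, "exports"))
  write_tsv(exports, pth("exports.tsv"))

  # --- stage: demux ----------------------------------------------------
  dm <- demultiplex(sim$pairs[, c("id", "seq1", "qual1", "seq2", "qual2")],
                    barcode_map(sim$barcodes), config$max_mismatch)
  write_tsv(dm$summary, pth("demux_summary.tsv"))

  # --- stage: classify + genotype --------------------------------------
  results <- lapply(names(dm$samples), function(id) {
    genotype_sample(dm$samples[[id]], refs, id, models$scoring,
                    config$qual_threshold, config$min_reads,
                    config$min_allele_frac)
  })
  names(results) <- names(dm$samples)
  allele_rows <- do.call(rbind, lapply(results, function(r) {
    al <- r$table$alleles
    if (nrow(al) == 0) {
      al <- data.frame(class = "NONE", signature = "", reads = 0L,
                       frequency = NA_real_, stringsAsFactors = FALSE)
    }
    cbind(data.frame(clone_id = r$table$clone_id, stringsAsFactors = FALSE),
          al, data.frame(uninformative = r$table$uninformative))
  }))
  rownames(allele_rows) <- NULL
  write_tsv(allele_rows, pth("alleles.tsv"))
  genotypes <- lapply(results, `[[`, "genotype")
  gt <- genotype_table(genotypes)
  truth_labels <- vapply(sim$truths, truth_genotype,
                         "", min_allele_frac = config$min_allele_frac)
  gt$true_label <- truth_labels[gt$clone_id]
  write_tsv(gt, pth("genotypes.tsv"))

  # --- stage: summaries ------------------------------------------------
  summary <- summarize_run(genotypes)
  stats <- chip_stats(pens, exports)
  confusion <- table(true = gt$true_label, called = gt$label)
  recovery <- mean(gt$label == gt$true_label)
  jsonlite::write_json(
    list(genotype_summary = list(
           n = summary$n, counts = as.list(summary$counts),
           proportions = as.list(summary$proportions),
           hdr_allele_rate = summary$hdr_allele_rate,
           nhej_allele_rate = summary$nhej_allele_rate),
         chip_stats = stats,
         recovery = list(fraction_correct = recovery,
                         confusion = as.data.frame(confusion))),
    pth("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- c("reference.fasta", "reads_R1.fastq", "reads_R2.fastq",
             "truth.tsv", "barcodes.tsv", "pens.tsv", "exports.tsv",
             "demux_summary.tsv", "alleles.tsv", "genotypes.tsv",
             "summary.json")
  manifest <- list(
    package = "ampliclone",
    version = as.character(utils::packageVersion("ampliclone")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = serializable_config(config),
    seed = config$seed,
    counts = list(clones = config$n_clones, read_pairs = nrow(sim$pairs),
                  assigned = sum(dm$summary$assigned),
                  unassigned = nrow(dm$unassigned),
                  uninformative_reads = sum(gt$uninformative),
                  low_coverage_clones = sum(gt$label == "LOW_COVERAGE")),
    recovery = recovery,
    files = lapply(setNames(files, files), function(f) {
      list(path = f, md5 = unname(tools::md5sum(pth(f))))
    }))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build a small packaged fixture dataset
#'
#' Known profiles:
#' * `"bi-allelic-hdr"`: every clone truly HDR/HDR, error-free reads;
#' * `"control-scrambled"`: unedited controls (all WT/WT) at realistic error
#'   rates;
#' * `"mixed-day4"`: the default editing mix (HDR, NHEJ, late editing,
#'   contamination).
#'
#' Writes the simulated dataset plus its config under `out_dir`; analyzable
#' in well under a minute.
#'
#' @param profile one of the profile names above.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return the run manifest, invisibly.
#' @export
make_fixture <- function(profile, seed = 1L, out_dir = tempfile(profile)) {
  cfg <- switch(profile,
    "bi-allelic-hdr" = default_config(
      seed = seed, n_clones = 4L,
      edit = list(p_hdr = 1, p_nhej = 0, p_late_edit = 0,
                  contamination_rate = 0),
      error = list(sub_rate = 0, seq_indel_rate = 0, depth = 50L)),
    "control-scrambled" = default_config(
      seed = seed, n_clones = 6L,
      edit = list(p_hdr = 0, p_nhej = 0, p_late_edit = 0,
                  contamination_rate = 0),
      error = list(depth = 50L)),
    "mixed-day4" = default_config(seed = seed, n_clones = 8L,
                                  error = list(depth = 60L)),
    stop("unknown fixture profile: ", profile, call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(out_dir, "config.json"))
  run_pipeline(cfg, out_dir)
}
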