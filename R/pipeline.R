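# Full pipeline orchestration: calibrate -> quantify -> adjust -> genotype ->
# report, driven by a YAML (or list) configuration, with every parameter and
# derived seed echoed into a JSON manifest so a rerun is byte-identical.

default_config <- function() {
  list(
    seed = 1,
    outdir = "pipeline_out",
    k = 31,
    read_length = 50,
    gamma_ids = c("HBG1", "HBG2"),
    calibration = list(n_reads = 1e5, n_reps = 3,
                       gamma_levels = c(0.005, 0.02, 0.10)),
    genotyping = list(window = 20, margin_min = 2, min_reads = 20,
                      min_allele_frac = 0.2, n_reads = 400, read_length = 80,
                      error_rate = 0.005),
    compare = NULL
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("configuration error: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("configuration error: config must be a list or YAML path")
  cfg <- merge_config(default_config(), config)
  need <- c("reference", "mixture", "amplicon", "samples")
  miss <- need[!need %in% names(cfg)]
  if (length(miss))
    stop("configuration error: missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(cfg$amplicon$cutA) || is.null(cfg$amplicon$cutB))
    stop("configuration error: amplicon cut sites (cutA, cutB) are required")
  cfg
}

resolve_reference <- function(ref) {
  if (is.character(ref) && length(ref) == 1 && file.exists(ref))
    read_transcripts_fasta(ref)
  else if (isTRUE(ref$synthetic_globin))
    synthetic_globin_reference(seed = if (is.null(ref$seed)) 1003 else ref$seed)
  else if (is.list(ref) && !is.null(ref$ids))
    transcript_set(ref$ids, ref$sequences)
  else stop("configuration error: unusable reference specification")
}

resolve_amplicon <- function(amp, seed) {
  if (!is.null(amp$fasta)) {
    as.character(unclass(read_transcripts_fasta(amp$fasta))[1])
  } else if (!is.null(amp$sequence)) {
    toupper(amp$sequence)
  } else if (!is.null(amp$length)) {
    with_seed(seed, random_dna(amp$length))
  } else stop("configuration error: amplicon needs fasta, sequence or length")
}

sample_alleles <- function(sample) {
  af <- sample$allele_fractions
  if (is.null(af)) stop("configuration error: sample '", sample$name,
                        "' has no allele_fractions")
  lapply(names(af), function(lab) {
    delta <- if (!is.null(sample$allele_deltas[[lab]]))
      sample$allele_deltas[[lab]] else 0L
    allele_spec(lab, af[[lab]], delta)
  })
}

#' Run the full deletion-screen analysis pipeline
#'
#' Executes calibrate -> (per sample) simulate-or-load reads -> quantify ->
#' adjust -> genotype -> report over a configuration given as a named list or
#' a YAML file. Per-sample and calibration seeds are derived from the master
#' seed by fixed offsets, so the same configuration reproduces every output
#' byte for byte.
#'
#' The configuration must name: `reference` (FASTA path, or
#' `synthetic_globin: true`, or inline `ids`/`sequences`), `mixture` (named
#' base weights), `amplicon` (`sequence`/`fasta`/`length` plus `cutA`,
#' `cutB`), and `samples` (each with `name`, either `rna_fastq` or a
#' `gamma_level` + `n_rna_reads` synthetic spec, and either `amplicon_fastq`
#' or `allele_fractions`). Optional: `seed`, `outdir`, `k`, `read_length`,
#' `gamma_ids`, `calibration` (`n_reads`, `n_reps`, `gamma_levels`),
#' `genotyping` thresholds, and `compare` (two genotype-class vectors whose
#' samples' gamma percentages are compared by unpaired t test).
#'
#' @param config named list or path to a YAML file.
#' @param write_outputs write TSV/JSON outputs under `outdir` (default TRUE;
#'   set FALSE to only return the bundle).
#' @return list of class `pipeline_result`: `factors`, `samples` (per-sample
#'   genotype, abundances, report rows), `report` (data frame with genotype
#'   and per-transcript percentages), `comparison` (t test, if configured),
#'   `manifest`.
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
  cfg <- read_pipeline_config(config)
  transcripts <- resolve_reference(cfg$reference)
  index <- build_index(transcripts, cfg$k)
  amp_ref <- resolve_amplicon(cfg$amplicon, seed = cfg$seed + 777)
  cutA <- cfg$amplicon$cutA; cutB <- cfg$amplicon$cutB
  models <- build_allele_models(amp_ref, cutA, cutB,
                                window = cfg$genotyping$window)

  spec <- calibration_spec(
    mixture = unlist(cfg$mixture), gamma_ids = cfg$gamma_ids,
    gamma_levels = cfg$calibration$gamma_levels,
    n_reads = cfg$calibration$n_reads, n_reps = cfg$calibration$n_reps,
    read_length = cfg$read_length, seed = cfg$seed)
  factors <- compute_adjustment_factors(transcripts, spec, k = cfg$k,
                                        index = index)

  sample_results <- list()
  report_rows <- list()
  for (si in seq_along(cfg$samples)) {
    smp <- cfg$samples[[si]]
    if (is.null(smp$name)) smp$name <- paste0("sample", si)
    seed_rna <- cfg$seed + 10000L + si
    seed_amp <- cfg$seed + 20000L + si

    rna_reads <- if (!is.null(smp$rna_fastq)) read_reads_fastq(smp$rna_fastq)
      else {
        gl <- if (is.null(smp$gamma_level)) 0.02 else smp$gamma_level
        w <- level_mixture(spec, gl)
        simulate_reads(transcripts, mixture_spec(w, transcripts),
                       n_reads = if (is.null(smp$n_rna_reads)) 5e4 else smp$n_rna_reads,
                       read_length = cfg$read_length, seed = seed_rna)
      }
    ab <- quantify_reads(rna_reads, index = index,
                         read_length = cfg$read_length)
    raw <- ab$est_counts[names(factors$factor)]
    adj <- adjust_counts(raw, factors)
    row <- globin_fractions(adj$adjusted, gamma_ids = cfg$gamma_ids)

    amp_reads <- if (!is.null(smp$amplicon_fastq)) read_reads_fastq(smp$amplicon_fastq)
      else simulate_edited_amplicon_reads(
        amp_ref, cutA, cutB, sample_alleles(smp),
        n_reads = cfg$genotyping$n_reads,
        read_length = cfg$genotyping$read_length, seed = seed_amp,
        error_rate = cfg$genotyping$error_rate)
    calls <- classify_amplicon_reads(amp_reads, models,
                                     margin_min = cfg$genotyping$margin_min)
    geno <- call_genotype(calls, min_reads = cfg$genotyping$min_reads,
                          min_allele_frac = cfg$genotyping$min_allele_frac)

    sample_results[[smp$name]] <- list(
      abundance = ab, adjusted = adj, report = row, calls = calls,
      genotype = geno, seeds = c(rna = seed_rna, amplicon = seed_amp))
    report_rows[[smp$name]] <- c(
      list(sample = smp$name, genotype = geno$call,
           gamma_pct = row$gamma_pct),
      as.list(stats::setNames(row$percent, paste0("pct_", names(row$percent)))))
  }
  report <- do.call(rbind, lapply(report_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(report) <- NULL

  comparison <- NULL
  if (!is.null(cfg$compare)) {
    ga <- report$gamma_pct[report$genotype %in% cfg$compare[[1]]]
    gb <- report$gamma_pct[report$genotype %in% cfg$compare[[2]]]
    comparison <- compare_groups(ga, gb)
  }

  manifest <- list(
    seed = cfg$seed, k = cfg$k, read_length = cfg$read_length,
    gamma_ids = cfg$gamma_ids, mixture = as.list(unlist(cfg$mixture)),
    calibration = cfg$calibration,
    genotyping = cfg$genotyping,
    amplicon = list(cutA = cutA, cutB = cutB, length = nchar(amp_ref)),
    sample_seeds = lapply(sample_results, `[[`, "seeds"),
    outputs = character())

  if (write_outputs) {
    outdir <- cfg$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      factors_tsv = file.path(outdir, "adjustment_factors.tsv"),
      factors_json = file.path(outdir, "adjustment_factors.json"),
      replicate_log = file.path(outdir, "calibration_replicates.tsv"),
      report_tsv = file.path(outdir, "globin_report.tsv"),
      manifest = file.path(outdir, "manifest.json"))
    write_factors_tsv(factors, paths["factors_tsv"])
    write_factors_json(factors, paths["factors_json"])
    write_replicate_log_tsv(factors, paths["replicate_log"])
    utils::write.table(report, paths["report_tsv"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (nm in names(sample_results)) {
      p_ab <- file.path(outdir, paste0(nm, "_abundance.tsv"))
      p_gt <- file.path(outdir, paste0(nm, "_genotype.json"))
      p_rc <- file.path(outdir, paste0(nm, "_read_calls.tsv"))
      write_abundance_tsv(sample_results[[nm]]$abundance, p_ab)
      write_genotype_json(sample_results[[nm]]$genotype, p_gt)
      write_read_calls_tsv(sample_results[[nm]]$calls, p_rc)
      paths <- c(paths, p_ab, p_gt, p_rc)
    }
    if (!is.null(comparison))
      jsonlite::write_json(comparison, file.path(outdir, "group_comparison.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$outputs <- unname(paths)
    write_run_manifest(paths["manifest"], manifest)
  }

  structure(list(factors = factors, samples = sample_results, report = report,
                 comparison = comparison, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", nrow(x$report), "samples\n")
  print(x$report[, c("sample", "genotype", "gamma_pct")])
  if (!is.null(x$comparison))
    cat(sprintf("Group comparison: t = %.3f, p = %.4g\n",
                x$comparison$t, x$comparison$p_value))
  invisible(x)
}
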