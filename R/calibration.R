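# Simulation-based calibration of quantification bias among near-identical
# paralogs: reads are simulated from mixtures of known composition,
# quantified, and the mean per-transcript ratio of observed (estimated) to
# expected (truth) counts becomes an adjustment factor applied to real
# quantifications.

#' Specify a calibration experiment
#'
#' Describes the simulated mixtures used to measure quantification bias: a
#' base mixture of fixed weights plus a set of levels swept over designated
#' "gamma" transcripts (in the globin screen, HBG1 and HBG2 are swept over
#' 0.005-0.10 to emulate variable fetal-globin expression).
#'
#' @param mixture named numeric vector / [mixture_spec()] of base weights
#'   (the gamma transcripts may be included; their weights are overwritten by
#'   each level).
#' @param gamma_ids character vector of transcripts swept (may be empty, in
#'   which case `gamma_levels` must be a single placeholder level and the
#'   base mixture is used as-is).
#' @param gamma_levels numeric vector of weights, each in (0, 1), applied to
#'   all `gamma_ids` in turn.
#' @param n_reads reads per simulated replicate (default 1,000,000).
#' @param n_reps replicates per mixture (default 10).
#' @param read_length read length in nt (default 50).
#' @param seed master seed; replicate seeds are `seed + 0, 1, 2, ...` in
#'   level-major order, echoed in the output log.
#' @return Object of class `calibration_spec`.
#' @export
calibration_spec <- function(mixture, gamma_ids = character(), gamma_levels = NA,
                             n_reads = 1e6, n_reps = 10, read_length = 50,
                             seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (length(gamma_ids)) {
    if (!length(gamma_levels) || any(is.na(gamma_levels)))
      stop("gamma_levels must be supplied when gamma_ids are designated")
    if (any(gamma_levels <= 0 | gamma_levels >= 1))
      stop("gamma_levels must lie in (0, 1)")
  } else {
    gamma_levels <- NA_real_
  }
  structure(list(mixture = mixture, gamma_ids = gamma_ids,
                 gamma_levels = gamma_levels, n_reads = n_reads,
                 n_reps = n_reps, read_length = read_length, seed = seed),
            class = "calibration_spec")
}

level_mixture <- function(spec, level) {
  w <- unclass(spec$mixture)
  if (length(spec$gamma_ids) && !is.na(level)) w[spec$gamma_ids] <- level
  w
}

#' Compute per-transcript adjustment factors from simulated mixtures
#'
#' For every gamma level and replicate, reads are simulated from the known
#' mixture with truth labels, quantified with the k-mer/EM estimator, and the
#' per-transcript ratio observed/expected formed (observed = EM estimated
#' counts, expected = number of reads actually drawn from the transcript).
#' The adjustment factor of a transcript is the mean of its ratios pooled
#' over all replicates of all levels; the per-replicate log is retained.
#' Transcripts that received no simulated reads in a replicate have that
#' replicate skipped (with a warning); a transcript with zero expected counts
#' in every replicate is absent from the factor table.
#'
#' @param transcripts a [transcript_set()].
#' @param spec a [calibration_spec()].
#' @param k k-mer length for the quantifier (default 31).
#' @param length_weighting passed to [simulate_reads()].
#' @param index optional prebuilt [build_index()].
#' @param verbose print one line per replicate.
#' @return Object of class `adjustment_factors`: named `factor` (mean ratio),
#'   `sd` and `n_obs` per transcript, the replicate `log` (data frame with
#'   level, rep, seed, id, observed, expected, ratio), and the spec.
#' @export
compute_adjustment_factors <- function(transcripts, spec, k = 31,
                                       length_weighting = TRUE, index = NULL,
                                       verbose = FALSE) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (is.null(index)) index <- build_index(transcripts, k)
  levels <- spec$gamma_levels
  logs <- vector("list", length(levels) * spec$n_reps)
  li <- 0L
  for (lv in seq_along(levels)) {
    w <- level_mixture(spec, levels[lv])
    mix <- mixture_spec(w, transcripts)
    for (r in seq_len(spec$n_reps)) {
      li <- li + 1L
      rep_seed <- as.integer(spec$seed + (lv - 1L) * spec$n_reps + (r - 1L))
      reads <- simulate_reads(transcripts, mix, spec$n_reads,
                              spec$read_length, seed = rep_seed,
                              length_weighting = length_weighting)
      ab <- quantify_reads(reads, index = index,
                           read_length = spec$read_length)
      expected <- table(factor(reads$truth_source, levels = index$ids))
      expected <- stats::setNames(as.numeric(expected), index$ids)
      weighted <- names(mix)[unclass(mix) > 0]
      zero <- weighted[expected[weighted] == 0]
      if (length(zero))
        warning("replicate ", li, ": no reads sampled from ",
                paste(zero, collapse = ", "), "; ratio skipped")
      keep <- names(expected)[expected > 0]
      logs[[li]] <- data.frame(
        level = levels[lv], rep = r, seed = rep_seed, id = keep,
        observed = ab$est_counts[keep], expected = expected[keep],
        ratio = ab$est_counts[keep] / expected[keep],
        stringsAsFactors = FALSE, row.names = NULL)
      if (verbose)
        message("level ", levels[lv], " rep ", r, ": ",
                sum(expected), " reads, ", ab$iterations, " EM iterations")
    }
  }
  log <- do.call(rbind, logs)
  ids <- unique(log$id)
  fac <- vapply(ids, function(i) mean(log$ratio[log$id == i]), numeric(1))
  sdv <- vapply(ids, function(i) stats::sd(log$ratio[log$id == i]), numeric(1))
  nob <- vapply(ids, function(i) sum(log$id == i), numeric(1))
  structure(list(factor = fac, sd = sdv, n_obs = nob,
                 n_reps = spec$n_reps, log = log, spec = spec),
            class = "adjustment_factors")
}

#' @export
print.adjustment_factors <- function(x, ...) {
  cat("Adjustment factors (mean observed/expected over",
      nrow(x$log) / length(x$factor), "replicates):\n")
  print(data.frame(id = names(x$factor), factor = x$factor, sd = x$sd,
                   n = as.integer(x$n_obs), row.names = NULL))
  invisible(x)
}

#' @export
coef.adjustment_factors <- function(object, ...) object$factor

#' Apply adjustment factors to raw estimated counts
#'
#' Dividing an observed count by its mean observed/expected ratio maps it
#' back toward the expected (true) count; `mode = "multiply"` preserves the
#' opposite reading of "used as adjustment factors".
#'
#' @param raw named numeric vector of raw estimated counts; every id must
#'   have a factor.
#' @param factors an [compute_adjustment_factors()] result (or named numeric
#'   vector of factors).
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return list with `adjusted` (named counts) and `fractions` (renormalised
#'   over the adjusted counts).
#' @export
adjust_counts <- function(raw, factors, mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  f <- if (inherits(factors, "adjustment_factors")) factors$factor else factors
  miss <- setdiff(names(raw), names(f))
  if (length(miss))
    stop("adjustment error: no factor for: ", paste(miss, collapse = ", "))
  f <- f[names(raw)]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("adjustment error: missing or non-positive factor")
  adjusted <- if (mode == "divide") raw / f else raw * f
  list(adjusted = adjusted, fractions = adjusted / sum(adjusted))
}

#' Sweep gamma levels and report factor stability
#'
#' Runs [compute_adjustment_factors()] separately at each gamma level (with
#' the same per-replicate seeds the pooled run would use), plus the pooled
#' run, and reports the spread (max - min across levels) of each
#' transcript's factor.
#'
#' @inheritParams compute_adjustment_factors
#' @return list of class `gamma_sweep`: `levels`, `per_level` (named list of
#'   `adjustment_factors`), `pooled`, and `stability` (named spread vector).
#' @export
sweep_gamma_levels <- function(transcripts, spec, k = 31,
                               length_weighting = TRUE, index = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (!length(spec$gamma_levels) || all(is.na(spec$gamma_levels)))
    stop("parameter error: empty gamma level list")
  if (is.null(index)) index <- build_index(transcripts, k)
  per_level <- vector("list", length(spec$gamma_levels))
  names(per_level) <- as.character(spec$gamma_levels)
  for (lv in seq_along(spec$gamma_levels)) {
    sub <- spec
    sub$gamma_levels <- spec$gamma_levels[lv]
    sub$seed <- spec$seed + (lv - 1L) * spec$n_reps
    per_level[[lv]] <- compute_adjustment_factors(
      transcripts, sub, k = k, length_weighting = length_weighting,
      index = index, verbose = verbose)
  }
  pooled <- compute_adjustment_factors(
    transcripts, spec, k = k, length_weighting = length_weighting,
    index = index, verbose = verbose)
  ids <- names(pooled$factor)
  stability <- vapply(ids, function(i) {
    v <- vapply(per_level, function(af)
      if (i %in% names(af$factor)) af$factor[[i]] else NA_real_, numeric(1))
    v <- v[!is.na(v)]
    if (length(v)) max(v) - min(v) else NA_real_
  }, numeric(1))
  structure(list(levels = spec$gamma_levels, per_level = per_level,
                 pooled = pooled, stability = stability),
            class = "gamma_sweep")
}

#' @export
print.gamma_sweep <- function(x, ...) {
  cat("Gamma-level sweep over", length(x$levels), "levels:",
      paste(x$levels, collapse = ", "), "\n")
  tab <- sapply(x$per_level, function(af) af$factor[names(x$pooled$factor)])
  out <- data.frame(id = names(x$pooled$factor), tab,
                    pooled = x$pooled$factor, spread = x$stability,
                    row.names = NULL, check.names = FALSE)
  print(out)
  invisible(x)
}

#' Write adjustment factors as TSV / JSON
#'
#' @param factors an `adjustment_factors` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_factors_tsv <- function(factors, path) {
  utils::write.table(
    data.frame(id = names(factors$factor), factor = factors$factor,
               sd = factors$sd, n = as.integer(factors$n_obs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_factors_tsv
#' @export
write_factors_json <- function(factors, path) {
  jsonlite::write_json(
    list(factor = as.list(factors$factor), sd = as.list(factors$sd),
         n_reps = factors$n_reps,
         params = factors$spec[c("gamma_ids", "gamma_levels", "n_reads",
                                 "n_reps", "read_length", "seed")]),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factors_tsv
#' @export
write_replicate_log_tsv <- function(factors, path) {
  utils::write.table(factors$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
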