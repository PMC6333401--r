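# Automated genotyping of deep-sequenced PCR amplicons from dual-cut edited
# samples: reads are scored against candidate allele models (wild type,
# precise deletion, inversion) by semi-global alignment, indels falling in
# diagnostic junction windows are flagged, and a diploid genotype is called
# from allele fractions over junction-informative reads.

#' Build candidate allele models for a dual-cut amplicon
#'
#' Emits wild-type, precise-deletion and inversion models with diagnostic
#' junction windows of +/- `window` nt around each cut (WT, INV) or around
#' the fused junction (DEL). Only reads overlapping these windows can
#' distinguish alleles.
#'
#' @param reference wild-type amplicon sequence.
#' @param cutA,cutB 0-based between-base cut offsets, `cutA <= cutB`.
#' @param window junction half-window in nt (default 20).
#' @return Named list of class `allele_model_set`; each model has `label`,
#'   `sequence`, and `junction_windows` (named list of 0-based half-open
#'   intervals, clipped to the sequence).
#' @export
build_allele_models <- function(reference, cutA, cutB, window = 20) {
  reference <- toupper(reference)
  n <- nchar(reference)
  if (cutA < 0 || cutB > n) stop("cut offsets outside the reference")
  if (cutA > cutB) stop("coordinate error: cutA must be <= cutB")
  win <- function(center, len)
    c(max(0, center - window), min(len, center + window))
  del_seq <- build_allele_sequence(reference, cutA, cutB, "DEL")
  inv_seq <- build_allele_sequence(reference, cutA, cutB, "INV")
  models <- list(
    WT = list(label = "WT", sequence = reference,
              junction_windows = list(A = win(cutA, n), B = win(cutB, n))),
    DEL = list(label = "DEL", sequence = del_seq,
               junction_windows = list(J = win(cutA, nchar(del_seq)))),
    INV = list(label = "INV", sequence = inv_seq,
               junction_windows = list(A = win(cutA, n), B = win(cutB, n)))
  )
  structure(models, class = "allele_model_set", cutA = cutA, cutB = cutB,
            window = window)
}

# map gap runs of one pairwise alignment to model (subject) coordinates.
# Returns data.frame(kind, pos0, width): pos0 is the 0-based subject offset
# of the first deleted base (kind "del") or of the base right of the
# insertion point (kind "ins").
alignment_gaps <- function(pat, subj, subj_start1) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(subj, "", fixed = TRUE)[[1]]
  out <- list()
  sp <- subj_start1 - 1L  # 0-based offset of next subject base
  i <- 1L
  while (i <= length(p)) {
    if (s[i] == "-") {
      j <- i
      while (j < length(p) && s[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(kind = "ins", pos0 = sp,
                                            width = j - i + 1L)
      i <- j + 1L
    } else if (p[i] == "-") {
      j <- i
      while (j < length(p) && p[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(kind = "del", pos0 = sp,
                                            width = j - i + 1L)
      sp <- sp + (j - i + 1L)
      i <- j + 1L
    } else {
      sp <- sp + 1L
      i <- i + 1L
    }
  }
  if (!length(out)) data.frame(kind = character(), pos0 = integer(),
                               width = integer())
  else do.call(rbind, out)
}

overlaps_window <- function(start0, end0, windows) {
  for (w in windows) if (start0 < w[2] && end0 > w[1]) return(TRUE)
  FALSE
}

#' Classify amplicon reads against allele models
#'
#' Each read (and its reverse complement) is scored against every model by
#' semi-global alignment — the full read against a local window of the model
#' — with match +1, mismatch -1, and affine gaps costing 3 for the first base
#' and 1 per additional base. The best-scoring model wins if its score
#' exceeds the runner-up by at least `margin_min`; otherwise the read is
#' ambiguous (reads lying entirely in sequence shared by all models always
#' tie and are therefore uninformative). Reads scoring below
#' `floor_frac * read length` are unmapped. A winning read whose alignment
#' contains an indel inside a junction window of its model is re-labelled
#' `junction_indel`, with the window name and the signed net size change.
#'
#' @param reads a `read_set` or character vector of read sequences.
#' @param models an [build_allele_models()] result.
#' @param margin_min minimum best-minus-second-best score margin to assign an
#'   allele label (default 2).
#' @param floor_frac unmapped floor as a fraction of read length (default 0.5).
#' @return data.frame of class `read_calls`: `id`, `call`, `base` (the
#'   winning model), `site`, `delta`, `score`, `margin`, `informative`.
#' @export
classify_amplicon_reads <- function(reads, models, margin_min = 2,
                                    floor_frac = 0.5) {
  stopifnot(inherits(models, "allele_model_set"))
  if (!length(models)) stop("parameter error: empty model list")
  seqs <- if (is_read_set(reads)) reads$sequence else as.character(reads)
  ids <- if (is_read_set(reads)) reads$id else sprintf("read_%d", seq_along(seqs))
  nr <- length(seqs)
  L <- nchar(seqs)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pats <- list(fwd = Biostrings::DNAStringSet(seqs),
               rev = Biostrings::DNAStringSet(revcomp(seqs)))
  nm <- length(models)
  sc <- array(NA_real_, dim = c(nr, nm, 2),
              dimnames = list(NULL, names(models), c("fwd", "rev")))
  for (m in seq_len(nm)) {
    subj <- Biostrings::DNAString(models[[m]]$sequence)
    for (o in 1:2) {
      sc[, m, o] <- Biostrings::pairwiseAlignment(
        pats[[o]], subj, type = "global-local", substitutionMatrix = sm,
        gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
    }
  }
  per_model <- matrix(NA_real_, nr, nm, dimnames = list(NULL, names(models)))
  for (m in seq_len(nm)) per_model[, m] <- pmax(sc[, m, 1], sc[, m, 2])
  best_m <- max.col(per_model, ties.method = "first")
  best <- per_model[cbind(seq_len(nr), best_m)]
  second <- vapply(seq_len(nr), function(i)
    if (nm > 1) max(per_model[i, -best_m[i]]) else -Inf, numeric(1))
  margin <- best - second
  orient <- ifelse(sc[cbind(seq_len(nr), best_m, 1)] >=
                   sc[cbind(seq_len(nr), best_m, 2)], 1L, 2L)

  call <- rep("ambiguous", nr)
  base <- rep(NA_character_, nr)
  site <- rep(NA_character_, nr)
  delta <- rep(NA_integer_, nr)
  informative <- rep(FALSE, nr)

  unmapped <- best < floor_frac * L
  call[unmapped] <- "unmapped"
  win <- !unmapped & margin >= margin_min
  call[win] <- names(models)[best_m[win]]
  base[win] <- names(models)[best_m[win]]

  # resolve footprint and junction indels for winning reads, grouped by
  # (model, orientation); perfect-scoring reads are located by exact search
  for (m in seq_len(nm)) {
    model_seq <- models[[m]]$sequence
    windows <- models[[m]]$junction_windows
    for (o in 1:2) {
      idx <- which(win & best_m == m & orient == o)
      if (!length(idx)) next
      perfect <- idx[best[idx] == L[idx]]
      if (length(perfect)) {
        qs <- as.character(pats[[o]][perfect])
        pos1 <- vapply(qs, function(q)
          as.integer(regexpr(q, model_seq, fixed = TRUE)), integer(1))
        st0 <- pos1 - 1L
        en0 <- st0 + nchar(qs)
        informative[perfect] <- vapply(seq_along(perfect), function(j)
          overlaps_window(st0[j], en0[j], windows), logical(1))
      }
      rest <- setdiff(idx, perfect)
      if (length(rest)) {
        aln <- Biostrings::pairwiseAlignment(
          pats[[o]][rest], Biostrings::DNAString(model_seq),
          type = "global-local", substitutionMatrix = sm,
          gapOpening = 2, gapExtension = 1)
        st1 <- Biostrings::start(Biostrings::subject(aln))
        en1 <- Biostrings::end(Biostrings::subject(aln))
        ap <- as.character(Biostrings::alignedPattern(aln))
        as_ <- as.character(Biostrings::alignedSubject(aln))
        for (j in seq_along(rest)) {
          i <- rest[j]
          informative[i] <- overlaps_window(st1[j] - 1L, en1[j], windows)
          gaps <- alignment_gaps(ap[j], as_[j], st1[j])
          if (nrow(gaps)) {
            for (wn in names(windows)) {
              w <- windows[[wn]]
              inw <- gaps$pos0 >= w[1] & gaps$pos0 < w[2]
              if (any(inw)) {
                d <- sum(ifelse(gaps$kind[inw] == "ins", gaps$width[inw],
                                -gaps$width[inw]))
                if (d != 0) {
                  call[i] <- "junction_indel"
                  site[i] <- wn
                  delta[i] <- d
                }
              }
            }
          }
        }
      }
    }
  }
  out <- data.frame(id = ids, call = call, base = base, site = site,
                    delta = delta, score = best, margin = margin,
                    informative = informative, stringsAsFactors = FALSE)
  structure(out, class = c("read_calls", "data.frame"),
            margin_min = margin_min)
}

#' Call a diploid sample genotype from per-read allele calls
#'
#' Allele fractions are computed over junction-informative reads only (reads
#' within shared flanks cannot distinguish alleles). Alleles at fraction >=
#' `min_allele_frac` are considered present. Exactly `{WT}` is homozygous
#' wild type; `{WT, DEL}` heterozygous; a set consisting only of DEL and/or
#' DEL-with-junction-indel alleles is grouped as homozygous deletion (clones
#' whose two deletion alleles differ by a few junction bases carry two
#' distinct genotypes but one phenotype class); any inversion allele makes
#' the sample an inversion carrier; more than two present alleles, or
#' mixtures involving cut-site indels without deletion, are complex. Fewer
#' than `min_reads` informative reads yields `low_coverage`.
#'
#' @param calls a [classify_amplicon_reads()] result.
#' @param min_reads minimum informative reads (default 20).
#' @param min_allele_frac presence threshold on allele fractions (default 0.2).
#' @return Object of class `sample_genotype`: `call` (one of `hom_WT`,
#'   `het_DEL`, `hom_DEL`, `INV_carrier`, `complex`, `low_coverage`),
#'   `fractions` over distinct alleles, `present`, `n_informative`,
#'   `counts`.
#' @export
call_genotype <- function(calls, min_reads = 20, min_allele_frac = 0.2) {
  stopifnot(inherits(calls, "read_calls") || is.data.frame(calls))
  inf <- calls[calls$informative &
                 !(calls$call %in% c("ambiguous", "unmapped")), , drop = FALSE]
  n_inf <- nrow(inf)
  key <- ifelse(inf$call == "junction_indel",
                paste0(inf$base, "+indel", inf$site,
                       ifelse(inf$delta > 0, "+", ""), inf$delta),
                inf$call)
  counts <- if (n_inf) table(key) else table(character())
  fractions <- if (n_inf) as.numeric(counts) / n_inf else numeric()
  names(fractions) <- names(counts)
  present <- names(fractions)[fractions >= min_allele_frac]
  base_of <- function(k) sub("\\+indel.*$", "", k)
  has_indel <- function(k) grepl("\\+indel", k)
  typ <- vapply(present, function(k) {
    b <- base_of(k)
    if (b == "INV") "INV"
    else if (b == "DEL") "DEL"
    else if (b == "WT" && has_indel(k)) "WT_indel"
    else "WT"
  }, character(1))
  call <- if (n_inf < min_reads) "low_coverage"
    else if (!length(present)) "complex"
    else if (any(typ == "INV")) "INV_carrier"
    else if (length(present) > 2) "complex"
    else if (all(typ == "DEL")) "hom_DEL"
    else if (identical(sort(unique(typ)), "WT") && !any(has_indel(present))) "hom_WT"
    else if (setequal(unique(typ), c("WT", "DEL")) && !any(has_indel(present[typ == "WT"]))) "het_DEL"
    else "complex"
  structure(list(call = call, fractions = fractions, present = present,
                 n_informative = n_inf,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 min_reads = min_reads, min_allele_frac = min_allele_frac),
            class = "sample_genotype")
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat("Genotype call:", x$call, "(", x$n_informative, "informative reads )\n")
  if (length(x$fractions)) {
    df <- data.frame(allele = names(x$fractions),
                     reads = as.integer(x$counts),
                     fraction = round(x$fractions, 4), row.names = NULL)
    print(df)
  }
  invisible(x)
}

#' Write per-read calls / per-sample genotype
#'
#' @param calls a `read_calls` data frame.
#' @param genotype a `sample_genotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_calls_tsv
#' @export
write_genotype_json <- function(genotype, path) {
  jsonlite::write_json(
    list(call = genotype$call,
         fractions = as.list(genotype$fractions),
         counts = as.list(genotype$counts),
         n_informative = genotype$n_informative,
         min_reads = genotype$min_reads,
         min_allele_frac = genotype$min_allele_frac),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
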