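# Equivalence-class quantification of near-identical transcripts: a
# canonical k-mer index assigns each read to the set of transcripts
# compatible with all of its indexed k-mers, and an expectation-maximisation
# step distributes ambiguous classes across transcripts using effective
# lengths. This is a functional stand-in for pseudoalignment-based
# quantifiers, not a bit-exact reimplementation of any of them.

#' Build a canonical k-mer index over a transcript set
#'
#' Keys are canonical k-mers (lexicographic minimum of the k-mer and its
#' reverse complement), each mapped to the complete set of transcripts that
#' contain it on either strand, so downstream classification is
#' strand-invariant.
#'
#' @param transcripts a [transcript_set()]; every transcript must be at least
#'   `k` nt long.
#' @param k odd k-mer length >= 11 (default 31, the customary choice for
#'   short-read transcript quantification).
#' @return Object of class `kmer_index` holding the compiled index, the
#'   transcript ids and their lengths.
#' @export
build_index <- function(transcripts, k = 31) {
  stopifnot(inherits(transcripts, "transcript_set"))
  if (k < 11 || k %% 2 == 0) stop("k must be an odd integer >= 11")
  lens <- nchar(unclass(transcripts))
  short <- lens < k
  if (any(short))
    stop("transcript(s) shorter than k = ", k, ": ",
         paste(names(transcripts)[short], collapse = ", "))
  ptr <- .kmer_index_build(unclass(transcripts), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), ids = names(transcripts),
                 lengths = stats::setNames(as.integer(lens), names(transcripts))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- .kmer_index_stats(x$ptr)
  cat("k-mer index: k =", x$k, "|", length(x$ids), "transcripts |",
      format(st$n_kmers, big.mark = ","), "canonical k-mers |",
      st$n_distinct_sets, "distinct membership sets\n")
  invisible(x)
}

# transcript membership sets for each k-mer of each query (test hook)
lookup_kmers <- function(index, queries) {
  res <- .kmer_index_lookup(index$ptr, queries)
  lapply(res, function(q) lapply(q, function(v) index$ids[v]))
}

#' Classify reads into transcript equivalence classes
#'
#' A read's equivalence class is the intersection of the membership sets of
#' its k-mers that are present in the index; k-mers absent from the index are
#' skipped (so a read with a few sequencing errors still classifies by its
#' error-free k-mers). Reads whose intersection is empty, or that share no
#' k-mer with the index, are counted as unassigned. Reads shorter than `k`
#' are counted unassigned with a warning.
#'
#' @param reads a `read_set` (or character vector of read sequences).
#' @param index a [build_index()] result.
#' @return Object of class `ec_table`: list with `classes` (list of sorted
#'   transcript-id vectors), `counts`, `unassigned`, `total`.
#' @export
classify_reads <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- if (is_read_set(reads)) reads$sequence else as.character(reads)
  res <- .classify_reads_cpp(index$ptr, seqs)
  if (res$n_short > 0)
    warning(res$n_short, " read(s) shorter than k = ", index$k,
            " counted as unassigned")
  classes <- lapply(res$classes, function(v) index$ids[v])
  names(res$counts) <- vapply(classes, paste, character(1), collapse = ",")
  structure(list(classes = classes, counts = res$counts,
                 unassigned = res$unassigned, total = length(seqs)),
            class = "ec_table")
}

#' @export
print.ec_table <- function(x, ...) {
  cat("Equivalence-class table:", length(x$counts), "classes,",
      sum(x$counts), "assigned /", x$total, "reads (",
      x$unassigned, "unassigned )\n")
  o <- order(x$counts, decreasing = TRUE)
  show <- utils::head(o, 10)
  for (i in show) cat(sprintf("  %8.0f  {%s}\n", x$counts[i], names(x$counts)[i]))
  if (length(o) > 10) cat("  ...", length(o) - 10, "more classes\n")
  invisible(x)
}

#' Estimate transcript abundances from equivalence-class counts by EM
#'
#' Maximises the mixture log-likelihood
#' `sum_c n_c log( sum_{t in c} theta_t / eff_t )` over the abundance simplex
#' `theta`, where `eff_t = max(length_t - read_length + 1, 1)` is the number
#' of valid read start positions. Initialisation is uniform and the
#' iteration order fixed, so the result is bit-for-bit reproducible.
#' Estimated counts are `est_counts_t = sum_c n_c * p_tc` with
#' `p_tc = (theta_t/eff_t) / sum_{t' in c} theta_{t'}/eff_{t'}`; they sum
#' exactly to the number of assigned reads.
#'
#' @param ec an [classify_reads()] `ec_table` with at least one assigned read.
#' @param index the [build_index()] used for classification (supplies
#'   transcript ids and lengths).
#' @param read_length read length used for effective lengths.
#' @param tol convergence tolerance: maximum relative change in `theta`
#'   between iterations (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return Object of class `abundance_estimate` with `est_counts`,
#'   `fractions`, `eff_lengths`, `iterations`, `converged`, and the
#'   log-likelihood trace `loglik`.
#' @export
em_abundance <- function(ec, index, read_length, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(ec, "ec_table"), inherits(index, "kmer_index"))
  if (!length(ec$counts) || sum(ec$counts) <= 0)
    stop("estimation error: no assigned reads")
  ids <- index$ids
  eff <- pmax(index$lengths - read_length + 1, 1)
  tmap <- match(unlist(ec$classes), ids)
  if (anyNA(tmap)) stop("equivalence classes refer to transcripts not in the index")
  cls <- rep(seq_along(ec$classes), lengths(ec$classes))
  n_c <- as.numeric(ec$counts)
  N <- sum(n_c)
  T <- length(ids)
  theta <- rep(1 / T, T)
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  inv_eff <- 1 / eff
  repeat {
    it <- it + 1L
    alpha <- theta[tmap] * inv_eff[tmap]
    denom <- as.vector(rowsum(alpha, cls, reorder = TRUE))
    loglik <- c(loglik, sum(n_c * log(denom)))
    w <- n_c[cls] * alpha / denom[cls]
    est_full <- numeric(T)
    est_full[sort(unique(tmap))] <- as.vector(rowsum(w, tmap, reorder = TRUE))
    theta_new <- est_full / N
    delta <- max(abs(theta_new - theta) / pmax(theta, 1e-12))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  alpha <- theta[tmap] * inv_eff[tmap]
  denom <- as.vector(rowsum(alpha, cls, reorder = TRUE))
  w <- n_c[cls] * alpha / denom[cls]
  est_full <- numeric(T)
  est_full[sort(unique(tmap))] <- as.vector(rowsum(w, tmap, reorder = TRUE))
  structure(list(
    est_counts = stats::setNames(est_full, ids),
    fractions = stats::setNames(est_full / N, ids),
    eff_lengths = stats::setNames(eff, ids),
    lengths = index$lengths,
    read_length = read_length,
    assigned = N, unassigned = ec$unassigned,
    iterations = it, converged = converged, loglik = loglik
  ), class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("Abundance estimate over", length(x$est_counts), "transcripts (",
      x$assigned, "assigned reads,", x$iterations, "EM iterations",
      if (x$converged) ", converged" else ", NOT converged", ")\n")
  print(data.frame(id = names(x$est_counts),
                   length = as.integer(x$lengths),
                   eff_length = as.integer(x$eff_lengths),
                   est_counts = round(x$est_counts, 2),
                   fraction = round(x$fractions, 5), row.names = NULL))
  invisible(x)
}

#' @export
coef.abundance_estimate <- function(object, ...) object$est_counts

#' @export
summary.abundance_estimate <- function(object, ...) {
  cat("EM abundance estimate: final log-likelihood",
      format(utils::tail(object$loglik, 1)), "after", object$iterations,
      "iterations\n")
  print(object)
  invisible(object)
}

#' Quantify a read set against a transcript reference
#'
#' One-call wrapper: build (or reuse) a k-mer index, classify the reads into
#' equivalence classes and run the EM estimator.
#'
#' @inheritParams classify_reads
#' @param transcripts a [transcript_set()] (ignored if `index` is given).
#' @param k k-mer length (default 31).
#' @param read_length read length; taken from the read set when omitted.
#' @param index optionally a prebuilt [build_index()].
#' @param ... passed to [em_abundance()].
#' @return An `abundance_estimate` with the `ec_table` attached as
#'   attribute `"ec"`.
#' @export
quantify_reads <- function(reads, transcripts = NULL, k = 31,
                           read_length = NULL, index = NULL, ...) {
  if (is.null(index)) index <- build_index(transcripts, k)
  if (is.null(read_length)) {
    read_length <- attr(reads, "read_length")
    if (is.null(read_length))
      read_length <- nchar(if (is_read_set(reads)) reads$sequence[1] else reads[1])
  }
  ec <- classify_reads(reads, index)
  ab <- em_abundance(ec, index, read_length, ...)
  attr(ab, "ec") <- ec
  ab
}

#' Write abundance estimates / equivalence classes as TSV
#'
#' @param x an `abundance_estimate` or `ec_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_estimate"))
  utils::write.table(
    data.frame(id = names(x$est_counts), length = as.integer(x$lengths),
               eff_length = as.integer(x$eff_lengths),
               est_counts = x$est_counts, fraction = x$fractions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
write_ec_tsv <- function(x, path) {
  stopifnot(inherits(x, "ec_table"))
  utils::write.table(
    data.frame(class = names(x$counts), count = as.numeric(x$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
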