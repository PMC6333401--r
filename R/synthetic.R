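# Synthetic data: paralog families, truth-labelled mixture reads, and
# edited-amplicon reads. Everything is deterministic given `seed`, and the
# caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site independently with probability `rate`, always to a
# different base (uniform over the three alternatives)
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- ceiling(stats::runif(length(hit)) * 3)
    b[hit] <- substring(alt[b[hit]], pick, pick)
  }
  paste(b, collapse = "")
}

#' Generate a family of near-identical paralogous transcripts
#'
#' Emulates a recently duplicated gene family (such as HBG1/HBG2 or
#' HBA1/HBA2): a random ancestor is drawn and each family member is an
#' independently substituted copy. With per-site divergence `d`, the expected
#' pairwise identity between two members is `1 - 2 d (1 - d) - (2/3) d^2`
#' (both copies mutate independently and two mutated sites agree with
#' probability 1/3).
#'
#' @param ancestor_length length of the common ancestor in nt (>= 100).
#' @param n_paralogs number of family members (>= 1). With `n_paralogs = 1`
#'   the unmutated ancestor itself is returned.
#' @param divergence per-site substitution probability in `[0, 1)`.
#' @param seed integer seed; the same seed reproduces the family exactly.
#' @param prefix id prefix; members are named `<prefix>1 ... <prefix>n`.
#' @return A [transcript_set()] of `n_paralogs` sequences.
#' @examples
#' fam <- make_paralog_family(200, 3, divergence = 0.02, seed = 1)
#' @export
make_paralog_family <- function(ancestor_length, n_paralogs, divergence,
                                seed = NULL, prefix = "paralog") {
  if (!is.numeric(ancestor_length) || ancestor_length < 100)
    stop("ancestor_length must be >= 100")
  if (!is.numeric(n_paralogs) || n_paralogs < 1)
    stop("n_paralogs must be >= 1")
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  with_seed(seed, {
    anc <- random_dna(ancestor_length)
    seqs <- if (n_paralogs == 1L) anc
      else vapply(seq_len(n_paralogs), function(i) mutate_sequence(anc, divergence),
                  character(1))
    transcript_set(paste0(prefix, seq_along(seqs)), seqs)
  })
}

new_read_set <- function(df, read_length, simulated) {
  rownames(df) <- NULL
  structure(df, class = c("read_set", "data.frame"),
            read_length = read_length, simulated = simulated)
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", nrow(x), "reads of", attr(x, "read_length"), "nt",
      if (isTRUE(attr(x, "simulated"))) "(simulated, truth-labelled)" else "",
      "\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more reads\n")
  invisible(x)
}

apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  L <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), L, error_rate)
  for (i in which(nerr > 0)) {
    b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L, nerr[i])
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- ceiling(stats::runif(length(pos)) * 3)
    b[pos] <- substring(alt[b[pos]], pick, pick)
    reads[i] <- paste(b, collapse = "")
  }
  reads
}

#' Simulate single-end reads from a known transcript mixture
#'
#' Reads are drawn the way fragments of a pooled transcript mixture are: a
#' source transcript is chosen with probability proportional to
#' `weight * (length - read_length + 1)` (a longer molecule contributes more
#' distinct read start positions), the start is uniform over valid positions,
#' and the strand is a fair coin between the transcript and its reverse
#' complement. Truth labels (source id, strand, 0-based start on the source)
#' are recorded with every read.
#'
#' @param transcripts a [transcript_set()].
#' @param mixture a [mixture_spec()]; every transcript with positive weight
#'   must be at least `read_length` long.
#' @param n_reads number of reads to draw.
#' @param read_length read length in nt (the screen's RNA-seq design uses 50).
#' @param seed integer seed for reproducibility.
#' @param error_rate per-base substitution probability (default 0: the
#'   calibration simulations are error-free).
#' @param length_weighting if `FALSE`, weights are treated as direct read
#'   shares instead of molar weights (no `length - read_length + 1` factor).
#' @return A `read_set` data frame with columns `id`, `sequence`,
#'   `truth_source`, `truth_strand`, `truth_start`.
#' @export
simulate_reads <- function(transcripts, mixture, n_reads, read_length = 50,
                           seed = NULL, error_rate = 0,
                           length_weighting = TRUE) {
  stopifnot(inherits(transcripts, "transcript_set"))
  mixture <- mixture_spec(mixture, transcripts)
  if (n_reads < 1) stop("n_reads must be positive")
  ids <- names(mixture)[mixture > 0]
  w <- unclass(mixture)[ids]
  len <- nchar(unclass(transcripts)[ids])
  short <- len < read_length
  if (any(short))
    stop("transcript(s) shorter than read_length with positive weight: ",
         paste(ids[short], collapse = ", "))
  npos <- len - read_length + 1
  prob <- if (length_weighting) w * npos else w
  with_seed(seed, {
    src <- sample.int(length(ids), n_reads, replace = TRUE, prob = prob)
    start0 <- floor(stats::runif(n_reads) * npos[src])  # 0-based
    fwd <- stats::runif(n_reads) < 0.5
    seg <- substring(unclass(transcripts)[ids][src], start0 + 1,
                     start0 + read_length)
    seg[!fwd] <- revcomp(seg[!fwd])
    seg <- apply_read_errors(seg, error_rate)
    new_read_set(data.frame(
      id = sprintf("read_%07d", seq_len(n_reads)),
      sequence = seg,
      truth_source = ids[src],
      truth_strand = ifelse(fwd, "+", "-"),
      truth_start = as.integer(start0),
      stringsAsFactors = FALSE
    ), read_length, simulated = TRUE)
  })
}

#' Specify an edited-amplicon allele
#'
#' Allele labels follow the repair outcomes seen after paired double-strand
#' breaks: `WT` (unedited), `DEL` (precise deletion between the two cuts),
#' `DEL_indel` (deletion with a net `delta`-bp change at the fused junction),
#' `INV` (the intervening segment reinserted in reverse complement),
#' `INDEL_A` / `INDEL_B` (a `delta`-bp indel at one cut without deletion).
#'
#' @param label one of `"WT"`, `"DEL"`, `"DEL_indel"`, `"INV"`, `"INDEL_A"`,
#'   `"INDEL_B"`.
#' @param fraction mixing fraction of the allele in the sample, in `[0, 1]`.
#' @param delta signed junction size change in bp; required non-zero for the
#'   indel labels, must be 0 otherwise.
#' @return Object of class `allele_spec`.
#' @export
allele_spec <- function(label, fraction, delta = 0L) {
  label <- match.arg(label, c("WT", "DEL", "DEL_indel", "INV", "INDEL_A", "INDEL_B"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  indel <- label %in% c("DEL_indel", "INDEL_A", "INDEL_B")
  if (indel && delta == 0) stop("delta must be non-zero for label ", label)
  if (!indel && delta != 0) stop("delta must be 0 for label ", label)
  structure(list(label = label, fraction = fraction, delta = as.integer(delta)),
            class = "allele_spec")
}

# Construct the DNA sequence of one allele. Coordinates are 0-based,
# half-open; cutA/cutB are between-base offsets. Inserted bases (delta > 0)
# are drawn from the current RNG state.
build_allele_sequence <- function(reference, cutA, cutB, label, delta = 0L) {
  n <- nchar(reference)
  left <- substr(reference, 1, cutA)              # [0, cutA)
  mid <- substr(reference, cutA + 1, cutB)        # [cutA, cutB)
  right <- substr(reference, cutB + 1, n)         # [cutB, n)
  ins <- function(d) random_dna(d)
  switch(label,
    WT = reference,
    DEL = paste0(left, right),
    DEL_indel = if (delta > 0) paste0(left, ins(delta), right)
      else {
        if (cutA + delta < 0) stop("junction indel larger than the 5' flank")
        paste0(substr(reference, 1, cutA + delta), right)
      },
    INV = paste0(left, revcomp(mid), right),
    INDEL_A = if (delta > 0) paste0(left, ins(delta), substr(reference, cutA + 1, n))
      else paste0(left, substr(reference, cutA - delta + 1, n)),
    INDEL_B = if (delta > 0) paste0(substr(reference, 1, cutB), ins(delta), right)
      else paste0(substr(reference, 1, cutB), substr(reference, cutB - delta + 1, n)),
    stop("unknown allele label: ", label)
  )
}

#' Simulate reads from a sequenced, fragmented PCR amplicon of edited cells
#'
#' Builds each allele sequence from the wild-type amplicon and the two cut
#' sites, then samples single-end reads uniformly along each allele (both
#' strands, fair coin) at the stated mixing fractions, recording the source
#' allele label as truth.
#'
#' @param reference wild-type amplicon sequence (A/C/G/T string).
#' @param cutA,cutB 0-based between-base cut offsets, `cutA <= cutB`.
#' @param alleles list of [allele_spec()]; fractions must sum to 1.
#' @param n_reads,read_length,seed,error_rate as in [simulate_reads()].
#' @return A `read_set` with `truth_source` holding the allele label (plus
#'   `truth_strand`, `truth_start` on the allele sequence). The constructed
#'   allele sequences are attached as attribute `"alleles"`.
#' @export
simulate_edited_amplicon_reads <- function(reference, cutA, cutB, alleles,
                                           n_reads, read_length, seed = NULL,
                                           error_rate = 0) {
  reference <- toupper(reference)
  if (grepl("[^ACGT]", reference)) stop("reference contains non-ACGT characters")
  n <- nchar(reference)
  if (cutA < 0 || cutB > n) stop("cut offsets outside the reference")
  if (cutA > cutB) stop("coordinate error: cutA must be <= cutB")
  if (!length(alleles)) stop("at least one allele must be specified")
  if (inherits(alleles, "allele_spec")) alleles <- list(alleles)
  stopifnot(all(vapply(alleles, inherits, logical(1), "allele_spec")))
  fr <- vapply(alleles, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("allele fractions must sum to 1 (got ", sum(fr), ")")
  labs <- vapply(alleles, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicated allele label")
  with_seed(seed, {
    seqs <- vapply(alleles, function(a)
      build_allele_sequence(reference, cutA, cutB, a$label, a$delta), character(1))
    names(seqs) <- labs
    if (any(nchar(seqs) < read_length))
      stop("read_length exceeds the shortest allele length")
    src <- sample.int(length(alleles), n_reads, replace = TRUE, prob = fr)
    npos <- nchar(seqs) - read_length + 1
    start0 <- floor(stats::runif(n_reads) * npos[src])
    fwd <- stats::runif(n_reads) < 0.5
    seg <- substring(seqs[src], start0 + 1, start0 + read_length)
    seg[!fwd] <- revcomp(seg[!fwd])
    seg <- apply_read_errors(seg, error_rate)
    rs <- new_read_set(data.frame(
      id = sprintf("amp_%07d", seq_len(n_reads)),
      sequence = unname(seg),
      truth_source = labs[src],
      truth_strand = ifelse(fwd, "+", "-"),
      truth_start = as.integer(start0),
      stringsAsFactors = FALSE
    ), read_length, simulated = TRUE)
    attr(rs, "alleles") <- seqs
    rs
  })
}

#' Write / read simulated reads as FASTQ (+ truth sidecar)
#'
#' Reads go to FASTQ with a constant quality (truth labels never enter the
#' FASTQ itself); if the read set carries truth labels they are written to a
#' tab-separated sidecar keyed by read id.
#'
#' @param reads a `read_set`.
#' @param fastq path for the FASTQ output.
#' @param truth_tsv optional path for the truth sidecar TSV.
#' @param quality_char constant Phred quality character (default `"I"`, Q40).
#' @return `write_read_set` returns `fastq` invisibly; `read_reads_fastq`
#'   returns a `read_set` without truth columns.
#' @export
write_read_set <- function(reads, fastq, truth_tsv = NULL, quality_char = "I") {
  stopifnot(is_read_set(reads))
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(ss, fastq, format = "fastq", qualities = qual)
  if (!is.null(truth_tsv) && "truth_source" %in% names(reads)) {
    utils::write.table(
      as.data.frame(reads)[c("id", "truth_source", "truth_strand", "truth_start")],
      truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fastq)
}

#' @rdname write_read_set
#' @param path FASTQ file to read.
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  lens <- unique(nchar(as.character(ss)))
  new_read_set(data.frame(id = sub("\\s.*$", "", names(ss)),
                          sequence = as.character(ss),
                          stringsAsFactors = FALSE),
               read_length = if (length(lens) == 1) lens else NA_integer_,
               simulated = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the parameters and seeds of a run so any output can be reproduced
#' exactly. Content is fully determined by its arguments (no timestamps), so
#' identical runs produce byte-identical manifests.
#'
#' @param path output path.
#' @param params named list of parameters/seeds.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
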