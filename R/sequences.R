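#' Construct a transcript set
#'
#' A transcript set is the quantification reference: a named collection of
#' DNA sequences (one per transcript isoform). Identifiers must be unique and
#' sequences must be non-empty strings over A/C/G/T. Sequences containing
#' `N` (or any other IUPAC ambiguity code) are rejected rather than silently
#' converted, since a single ambiguous base silently changes the k-mer
#' content of a near-identical paralog pair.
#'
#' @param ids character vector of unique transcript identifiers.
#' @param sequences character vector of DNA sequences (same length as `ids`).
#' @return An object of class `transcript_set`: a named character vector of
#'   upper-case sequences.
#' @export
transcript_set <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` must have the same length")
  if (length(ids) == 0L) stop("a transcript set must contain at least one sequence")
  if (anyDuplicated(ids)) stop("transcript ids must be unique")
  if (any(!nzchar(sequences))) stop("transcript sequences must be non-empty")
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("non-ACGT characters in transcript(s): ",
         paste(ids[bad], collapse = ", "),
         " (ambiguity codes such as N are not accepted)")
  structure(stats::setNames(sequences, ids), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("Transcript set with", length(x), "sequences\n")
  w <- nchar(unclass(x))
  df <- data.frame(id = names(x), length_nt = w, row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i) {
  y <- unclass(x)[i]
  transcript_set(names(y), y)
}

#' Read / write a transcript set as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path file path.
#' @param x a `transcript_set`.
#' @return `read_transcripts_fasta` returns a `transcript_set`;
#'   `write_transcripts_fasta` returns `path` invisibly.
#' @export
read_transcripts_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  transcript_set(ids, as.character(ss))
}

#' @rdname read_transcripts_fasta
#' @export
write_transcripts_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Specify a known transcript mixture
#'
#' A mixture assigns each transcript a nonnegative relative abundance
#' (molar-style weight, not a read share). Weights need not sum to one;
#' sampling probabilities are normalised internally. Every named transcript
#' must exist in the accompanying reference, and at least one weight must be
#' positive.
#'
#' @param weights named numeric vector of nonnegative relative abundances.
#' @param transcripts optional `transcript_set` to validate ids against.
#' @return Object of class `mixture_spec` (named numeric vector).
#' @export
mixture_spec <- function(weights, transcripts = NULL) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("mixture weights must be a named numeric vector")
  if (anyDuplicated(names(weights))) stop("duplicated transcript id in mixture")
  weights <- vapply(weights, as.numeric, numeric(1))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("mixture weights must be finite and nonnegative")
  if (!any(weights > 0)) stop("at least one mixture weight must be positive")
  if (!is.null(transcripts)) {
    miss <- setdiff(names(weights), names(transcripts))
    if (length(miss))
      stop("mixture names not in the transcript set: ", paste(miss, collapse = ", "))
  }
  structure(weights, class = "mixture_spec")
}

# internal: validate that a read-set-like data.frame is usable downstream
is_read_set <- function(x) inherits(x, "read_set")
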