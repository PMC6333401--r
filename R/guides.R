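# SpCas9 guide enumeration, cut-offset labelling, dual-guide deletion pair
# selection and 150-nt "stapler" ssODN construction.
#
# All coordinates are 0-based, half-open; a cut site is a between-base
# offset (the index of the first base right of the cut). SpCas9 is modelled
# as cutting bluntly exactly 3 bp 5' of the NGG PAM.

#' Enumerate every SpCas9 guide site in a reference
#'
#' Finds all 20-nt protospacers adjacent to an NGG PAM on either strand
#' ("every PAM": overlapping sites each yield their own guide, with no
#' uniqueness or off-target filtering). On the plus strand a PAM starting at
#' 0-based position `p` gives `cut_offset = p - 3`; on the minus strand the
#' site appears in the reference as `CCN` followed by the reverse complement
#' of the protospacer, and a PAM ending at (exclusive) offset `e` gives
#' `cut_offset = e + 3`.
#'
#' @param reference DNA string (A/C/G/T). Sequences shorter than 23 nt yield
#'   an empty result.
#' @return data.frame of class `guide_set` with columns `protospacer`, `pam`,
#'   `strand`, `cut_offset`, sorted by `cut_offset`.
#' @export
scan_guides <- function(reference) {
  reference <- toupper(reference)
  if (grepl("[^ACGT]", reference)) stop("reference contains non-ACGT characters")
  n <- nchar(reference)
  empty <- data.frame(protospacer = character(), pam = character(),
                      strand = character(), cut_offset = integer(),
                      stringsAsFactors = FALSE)
  if (n < 23) return(structure(empty, class = c("guide_set", "data.frame")))
  base_at <- function(i0) substring(reference, i0 + 1, i0 + 1)

  # plus strand: protospacer [p-20, p), PAM [p, p+3) with ref[p+1]==G, ref[p+2]==G
  p <- 20:(n - 3)  # candidate 0-based PAM starts
  p <- p[base_at(p + 1) == "G" & base_at(p + 2) == "G"]
  plus <- if (length(p)) data.frame(
    protospacer = substring(reference, p - 20 + 1, p),
    pam = substring(reference, p + 1, p + 3),
    strand = rep("+", length(p)),
    cut_offset = as.integer(p - 3),
    stringsAsFactors = FALSE
  ) else empty

  # minus strand: reference shows CC N at [s, s+3), protospacer revcomp at
  # [s+3, s+23); PAM end (exclusive) e = s+3, cut_offset = e + 3
  s <- 0:(n - 23)
  s <- s[base_at(s) == "C" & base_at(s + 1) == "C"]
  minus <- if (length(s)) data.frame(
    protospacer = revcomp(substring(reference, s + 4, s + 23)),
    pam = revcomp(substring(reference, s + 1, s + 3)),
    strand = rep("-", length(s)),
    cut_offset = as.integer(s + 6),
    stringsAsFactors = FALSE
  ) else empty

  out <- rbind(plus, minus)
  out <- out[order(out$cut_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("guide_set", "data.frame"))
}

#' Label guide cuts relative to a region breakpoint
#'
#' Converts absolute cut offsets into signed positions relative to a region's
#' 5' breakpoint, the convention used to name saturating-mutagenesis guides
#' (e.g. "-4" = 4 nt upstream of the breakpoint, "376" = 376 nt downstream).
#'
#' @param guides a `guide_set` (or any data.frame with a `cut_offset` column).
#' @param region_start 0-based offset of the region's 5' breakpoint.
#' @return integer vector of signed offsets, one per guide.
#' @export
label_cut_offsets <- function(guides, region_start) {
  as.integer(guides$cut_offset - region_start)
}

#' Select a dual-guide pair programming deletion of a region
#'
#' Picks, for each breakpoint of `region = c(a, b)` (0-based, half-open), the
#' guide whose cut offset is nearest; ties are broken toward the region
#' interior so the designed deletion never retains flanking target sequence.
#'
#' @param reference DNA string.
#' @param region integer vector `c(a, b)`, the half-open target interval.
#' @param guides a `guide_set`, e.g. from [scan_guides()].
#' @param max_distance maximum tolerated |cut - breakpoint| in nt (default 25);
#'   beyond it the design fails with an error naming the breakpoint.
#' @return list of class `deletion_design`: `guide5`, `guide3` (single-row
#'   guide data frames), `span` (`c(cut5, cut3)`), `deleted_allele`.
#' @export
design_deletion_pair <- function(reference, region, guides, max_distance = 25) {
  reference <- toupper(reference)
  a <- region[1]; b <- region[2]
  if (a >= b) stop("region must be a non-empty half-open interval [a, b)")
  if (!nrow(guides)) stop("design error: empty guide list")
  pick <- function(bp, interior_sign) {
    d <- abs(guides$cut_offset - bp)
    if (min(d) > max_distance)
      stop("design error: no guide cuts within ", max_distance,
           " nt of breakpoint ", bp)
    cand <- which(d == min(d))
    if (length(cand) > 1) {
      # tie: prefer the cut toward the region interior
      inward <- sign(guides$cut_offset[cand] - bp) == interior_sign
      if (any(inward)) cand <- cand[inward]
    }
    cand[1]
  }
  i5 <- pick(a, +1)
  i3 <- pick(b, -1)
  cut5 <- guides$cut_offset[i5]
  cut3 <- guides$cut_offset[i3]
  if (cut5 >= cut3)
    stop("design error: selected cuts do not define a forward deletion (",
         cut5, " >= ", cut3, ")")
  deleted <- build_allele_sequence(reference, cut5, cut3, "DEL")
  structure(list(guide5 = guides[i5, , drop = FALSE],
                 guide3 = guides[i3, , drop = FALSE],
                 span = c(cut5 = cut5, cut3 = cut3),
                 deleted_allele = deleted),
            class = "deletion_design")
}

#' @export
print.deletion_design <- function(x, ...) {
  cat("Deletion design: span [", x$span[1], ", ", x$span[2], ") = ",
      x$span[2] - x$span[1], " bp removed\n", sep = "")
  cat("  5' guide:", x$guide5$protospacer, x$guide5$pam,
      paste0("(", x$guide5$strand, ", cut ", x$guide5$cut_offset, ")\n"))
  cat("  3' guide:", x$guide3$protospacer, x$guide3$pam,
      paste0("(", x$guide3$strand, ", cut ", x$guide3$cut_offset, ")\n"))
  invisible(x)
}

#' Construct a 150-nt "stapler" ssODN for a dual-cut deletion
#'
#' The donor's two 75-nt arms are the exact reference flanks of the two cut
#' sites: 75 bp ending at the 5' cut followed by 75 bp starting at the 3'
#' cut. The oligo therefore corresponds to the precise deleted allele and
#' spans its junction centrally.
#'
#' @param reference DNA string.
#' @param cut5,cut3 0-based between-base cut offsets, `cut5 <= cut3`, with at
#'   least 75 nt of reference flanking each cut.
#' @return list of class `stapler_oligo` with `sequence` (150 nt), `arm5`,
#'   `arm3` (75 nt each).
#' @export
design_stapler <- function(reference, cut5, cut3) {
  reference <- toupper(reference)
  n <- nchar(reference)
  if (cut5 > cut3) stop("coordinate error: cut5 must be <= cut3")
  if (cut5 < 75)
    stop("flank error: 5' arm is ", 75 - cut5, " bases short of 75")
  if (cut3 > n - 75)
    stop("flank error: 3' arm is ", cut3 - (n - 75), " bases short of 75")
  arm5 <- substr(reference, cut5 - 75 + 1, cut5)
  arm3 <- substr(reference, cut3 + 1, cut3 + 75)
  structure(list(sequence = paste0(arm5, arm3), arm5 = arm5, arm3 = arm3),
            class = "stapler_oligo")
}

#' @export
print.stapler_oligo <- function(x, ...) {
  cat("Stapler ssODN (", nchar(x$sequence), " nt):\n  5' arm: ", x$arm5,
      "\n  3' arm: ", x$arm3, "\n", sep = "")
  invisible(x)
}

#' Write guide sites as TSV or BED
#'
#' The BED output represents each cut site as a zero-length interval at its
#' between-base offset.
#'
#' @param guides a `guide_set`.
#' @param path output path.
#' @param chrom chromosome/sequence name for the BED output.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(guides, path) {
  utils::write.table(as.data.frame(guides), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_guides_tsv
#' @export
write_guides_bed <- function(guides, path, chrom = "amplicon") {
  bed <- data.frame(chrom = chrom,
                    start = guides$cut_offset,
                    end = guides$cut_offset,
                    name = paste0("cut_", guides$cut_offset, guides$strand),
                    score = 0,
                    strand = guides$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
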