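# Phenotype summaries: per-sample globin expression fractions, the
# gamma-globin (HBG1+HBG2) share, and genotype-group comparisons.

#' Per-sample globin expression percentages
#'
#' Converts (adjusted) transcript counts into percentages of total globin
#' transcripts and sums the designated gamma-globin transcripts into a single
#' `gamma_pct`. The denominator is all quantified transcripts in `counts`;
#' pass a subset to restrict it (e.g. to exclude pseudogenes).
#'
#' @param counts named numeric vector of (adjusted) transcript counts.
#' @param gamma_ids ids summed into the gamma share (default
#'   `c("HBG1", "HBG2")`).
#' @return list of class `globin_report_row`: `percent` (named, sums to 100)
#'   and `gamma_pct`.
#' @export
globin_fractions <- function(counts, gamma_ids = c("HBG1", "HBG2")) {
  if (!length(counts) || sum(counts) <= 0)
    stop("report error: total globin counts must be positive")
  pct <- 100 * counts / sum(counts)
  gamma <- sum(pct[intersect(gamma_ids, names(pct))])
  structure(list(percent = pct, gamma_pct = gamma),
            class = "globin_report_row")
}

#' @export
print.globin_report_row <- function(x, ...) {
  cat("Globin expression (% of globin transcripts); gamma =",
      sprintf("%.2f%%", x$gamma_pct), "\n")
  print(round(x$percent, 3))
  invisible(x)
}

#' Compare gamma-globin expression between two sample groups
#'
#' Student's two-sample unpaired t test with pooled variance (the
#' conventional per-comparison test for clone-group expression differences);
#' Welch's correction available by flag.
#'
#' @param values_a,values_b numeric vectors of per-sample `gamma_pct` values,
#'   each of length >= 2.
#' @param welch use Welch's unequal-variance t test instead.
#' @return list with `t`, `df`, `p_value`, group means and sizes.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("statistics error: each group needs n >= 2")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b))))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2,
                  p_value = 1, mean_a = mean(values_a), mean_b = mean(values_b),
                  n_a = length(values_a), n_b = length(values_b)))
    stop("statistics error: zero variance in both groups")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(values_a), mean_b = mean(values_b),
       n_a = length(values_a), n_b = length(values_b))
}
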