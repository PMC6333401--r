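# Independent oracles used across the suite. These deliberately use naive
# string/grid methods, not the package's own code paths.

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# naive SpCas9 site enumeration: test all 23-mers on both strands
brute_force_scan <- function(ref) {
  n <- nchar(ref)
  rows <- list()
  if (n >= 23) {
    for (i in 0:(n - 23)) {  # 0-based start of a 23-mer window
      w <- substr(ref, i + 1, i + 23)
      if (substr(w, 22, 22) == "G" && substr(w, 23, 23) == "G")
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = substr(w, 1, 20), pam = substr(w, 21, 23),
          strand = "+", cut_offset = i + 17L, stringsAsFactors = FALSE)
      rcw <- rc_chr(w)
      if (substr(rcw, 22, 22) == "G" && substr(rcw, 23, 23) == "G")
        rows[[length(rows) + 1]] <- data.frame(
          protospacer = substr(rcw, 1, 20), pam = substr(rcw, 21, 23),
          strand = "-", cut_offset = i + 6L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(protospacer = character(), pam = character(),
                    strand = character(), cut_offset = integer(),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cut_offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# grid search of the EC mixture log-likelihood over the 3-simplex
grid_em_oracle <- function(classes, counts, eff, step = 1e-3) {
  g <- seq(0, 1, by = step)
  th <- expand.grid(t1 = g, t2 = g)
  th <- th[th$t1 + th$t2 <= 1 + 1e-12, ]
  th$t3 <- pmax(1 - th$t1 - th$t2, 0)
  ll <- rep(0, nrow(th))
  for (ci in seq_along(classes)) {
    members <- classes[[ci]]
    d <- rowSums(as.matrix(th[, members, drop = FALSE]) %*%
                   diag(1 / eff[members], length(members)))
    ll <- ll + counts[ci] * log(d)
  }
  unlist(th[which.max(ll), c("t1", "t2", "t3")])
}

# mean pairwise identity by direct column comparison
column_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av == bv)
}

# Student pooled-variance t statistic by hand
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# exact two-sided permutation p-value over all group relabelings
exact_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  combos <- utils::combn(length(pooled), na)
  diffs <- apply(combos, 2, function(ix)
    abs(mean(pooled[ix]) - mean(pooled[-ix])))
  mean(diffs >= obs - 1e-12)
}
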