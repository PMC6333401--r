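# Small problem sizes here keep the unit suite fast; the full-scale
# calibration behaviour is exercised in test-acceptance.R.

disjoint_family <- function(seed, n = 4, len = 400) {
  set.seed(seed)
  ts <- transcript_set(paste0("d", 1:n), vapply(1:n, function(i) random_seq(len),
                                                character(1)))
  idx <- build_index(ts, 31)
  # random unrelated sequences: verify every k-mer is transcript-specific
  stopifnot(globinquant:::.kmer_index_stats(idx$ptr)$n_distinct_sets == n)
  list(ts = ts, idx = idx)
}

test_that("factors are unity (within Monte-Carlo error) when no k-mer is shared", {
  fam <- disjoint_family(61)
  w <- stats::setNames(c(1, 0.5, 0.25, 0.1), names(fam$ts))
  spec <- calibration_spec(w, n_reads = 2e4, n_reps = 5, read_length = 50,
                           seed = 17)
  af <- compute_adjustment_factors(fam$ts, spec, index = fam$idx)
  se <- af$sd / sqrt(af$n_obs)
  expect_true(all(abs(af$factor - 1) <= 3 * se))
})

test_that("identical twin transcripts at equal weight both calibrate to 1", {
  set.seed(71)
  s <- random_seq(400)
  twins <- transcript_set(c("t1", "t2"), c(s, s))
  spec <- calibration_spec(c(t1 = 1, t2 = 1), n_reads = 2e4, n_reps = 5,
                           read_length = 50, seed = 19)
  af <- compute_adjustment_factors(twins, spec)
  se <- af$sd / sqrt(af$n_obs)
  expect_true(all(abs(af$factor - 1) <= 3 * se))
})

test_that("factor arithmetic: dividing observed by observed/expected recovers expected", {
  out <- adjust_counts(c(A = 132, B = 88), c(A = 1.32, B = 0.88))
  expect_equal(unname(out$adjusted), c(100, 100))
  expect_equal(unname(out$fractions), c(0.5, 0.5))
  ident <- adjust_counts(c(A = 7, B = 3), c(A = 1, B = 1))
  expect_equal(ident$adjusted, c(A = 7, B = 3))
  expect_error(adjust_counts(c(A = 1, Z = 2), c(A = 1)), "Z")
  mult <- adjust_counts(c(A = 100), c(A = 1.25), mode = "multiply")
  expect_equal(unname(mult$adjusted), 125)
})

test_that("factors are invariant to rescaling all mixture weights", {
  fam <- make_paralog_family(400, 3, 0.02, seed = 23, prefix = "p")
  w <- c(p1 = 0.5, p2 = 0.3, p3 = 0.2)
  spec1 <- calibration_spec(w, n_reads = 1e4, n_reps = 3, read_length = 50,
                            seed = 29)
  spec2 <- calibration_spec(4 * w, n_reads = 1e4, n_reps = 3, read_length = 50,
                            seed = 29)
  af1 <- compute_adjustment_factors(fam, spec1)
  af2 <- compute_adjustment_factors(fam, spec2)
  expect_identical(af1$factor, af2$factor)
})

test_that("the pooled factor equals the mean of per-replicate ratios in the log", {
  fam <- make_paralog_family(400, 3, 0.02, seed = 37, prefix = "p")
  spec <- calibration_spec(c(p1 = 1, p2 = 1, p3 = 0.1), gamma_ids = "p3",
                           gamma_levels = c(0.05, 0.2), n_reads = 1e4,
                           n_reps = 3, read_length = 50, seed = 41)
  af <- compute_adjustment_factors(fam, spec)
  for (id in names(af$factor)) {
    expect_equal(af$factor[[id]], mean(af$log$ratio[af$log$id == id]))
    expect_equal(af$n_obs[[id]], sum(af$log$id == id))
  }
  # 2 levels x 3 reps logged with distinct derived seeds
  expect_identical(as.integer(sort(unique(af$log$seed))), 41:46)
})

test_that("a weighted transcript that draws no reads is skipped with a warning", {
  fam <- make_paralog_family(400, 2, 0.05, seed = 43, prefix = "p")
  spec <- calibration_spec(c(p1 = 1, p2 = 1e-12), n_reads = 100, n_reps = 2,
                           read_length = 50, seed = 47)
  w <- capture_warnings(af <- compute_adjustment_factors(fam, spec))
  expect_true(length(w) >= 1 && all(grepl("no reads sampled", w)))
  expect_false("p2" %in% names(af$factor))
})

test_that("gamma sweep: a single level reproduces the plain calibration", {
  fam <- make_paralog_family(400, 3, 0.02, seed = 53, prefix = "p")
  spec <- calibration_spec(c(p1 = 1, p2 = 1, p3 = 0.1), gamma_ids = "p3",
                           gamma_levels = 0.05, n_reads = 5e3, n_reps = 2,
                           read_length = 50, seed = 59)
  sw <- sweep_gamma_levels(fam, spec)
  af <- compute_adjustment_factors(fam, spec)
  expect_equal(sw$per_level[["0.05"]]$factor, af$factor)
  expect_equal(sw$pooled$factor, af$factor)
  expect_true(all(sw$stability[!is.na(sw$stability)] >= 0))
})

test_that("gamma sweep across two levels reports per-level tables and spread", {
  fam <- make_paralog_family(400, 3, 0.02, seed = 67, prefix = "p")
  spec <- calibration_spec(c(p1 = 1, p2 = 1, p3 = 0.1), gamma_ids = "p3",
                           gamma_levels = c(0.05, 0.2), n_reads = 5e3,
                           n_reps = 2, read_length = 50, seed = 71)
  sw <- sweep_gamma_levels(fam, spec)
  expect_named(sw$per_level, c("0.05", "0.2"))
  expect_true(all(is.finite(sw$stability)))
  expect_true(all(sw$stability >= 0))
  # levels echoed in each per-level spec
  expect_identical(sw$per_level[["0.2"]]$spec$gamma_levels, 0.2)
  badspec <- calibration_spec(c(p1 = 1), n_reads = 100, n_reps = 1,
                              read_length = 50, seed = 1)
  expect_error(sweep_gamma_levels(fam, badspec), "empty gamma level")
})

test_that("calibration specs validate replicate counts and gamma levels", {
  expect_error(calibration_spec(c(a = 1), n_reps = 0), "n_reps")
  expect_error(calibration_spec(c(a = 1), gamma_ids = "a", gamma_levels = 1.5),
               "\\(0, 1\\)")
  expect_error(calibration_spec(c(a = 1), gamma_ids = "a", gamma_levels = NA),
               "gamma_levels")
})

test_that("factor TSV/JSON outputs carry the calibration parameters", {
  fam <- make_paralog_family(400, 2, 0.02, seed = 73, prefix = "p")
  spec <- calibration_spec(c(p1 = 1, p2 = 0.5), n_reads = 5e3, n_reps = 2,
                           read_length = 50, seed = 79)
  af <- compute_adjustment_factors(fam, spec)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_factors_tsv(af, tsv); write_factors_json(af, js)
  back <- utils::read.delim(tsv)
  expect_equal(back$factor, unname(af$factor))
  j <- jsonlite::read_json(js)
  expect_equal(j$params$n_reads, 5e3)
  expect_equal(j$params$seed, 79)
})
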