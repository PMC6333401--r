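test_that("transcript sets enforce unique ids and a strict ACGT alphabet", {
  expect_error(transcript_set(c("a", "a"), c("ACGT", "ACGT")), "unique")
  expect_error(transcript_set("a", "ACGNT"), "non-ACGT")
  expect_error(transcript_set("a", ""), "non-empty")
  ts <- transcript_set("a", "acgt")
  expect_identical(unclass(ts)[["a"]], "ACGT")
})

test_that("mixture specs validate ids and weights", {
  ts <- transcript_set(c("a", "b"), c(strrep("ACGT", 30), strrep("GATC", 30)))
  expect_error(mixture_spec(c(zz = 1), ts), "not in the transcript set")
  expect_error(mixture_spec(c(a = 0, b = 0)), "positive")
  expect_error(mixture_spec(c(a = -1, b = 1)), "nonnegative")
  expect_silent(mixture_spec(c(a = 1), ts))
})

test_that("paralog families: zero divergence gives identical copies, n = 1 the ancestor", {
  fam0 <- make_paralog_family(150, 3, 0, seed = 11)
  expect_length(fam0, 3)
  expect_length(unique(unclass(fam0)), 1)
  one <- make_paralog_family(150, 1, 0.5, seed = 11)
  # same seed: the single copy is the same (unmutated) ancestor
  expect_identical(unclass(one)[[1]], unclass(fam0)[[1]])
  expect_error(make_paralog_family(50, 2, 0.01), ">= 100")
  expect_error(make_paralog_family(150, 2, 1), "divergence")
})

test_that("pairwise identity of a mutated pair matches the closed form", {
  d <- 0.01
  fam <- make_paralog_family(10000, 2, d, seed = 42)
  obs <- column_identity(unclass(fam)[[1]], unclass(fam)[[2]])
  expected <- 1 - 2 * d * (1 - d) - (2 / 3) * d^2
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("reads from a single transcript are exact substrings and realign at truth", {
  ts <- make_paralog_family(300, 1, 0, seed = 7, prefix = "t")
  rs <- simulate_reads(ts, c(t1 = 1), 500, 50, seed = 8)
  src <- unclass(ts)[["t1"]]
  for (i in seq_len(nrow(rs))) {
    seg <- substr(src, rs$truth_start[i] + 1, rs$truth_start[i] + 50)
    expected <- if (rs$truth_strand[i] == "+") seg else rc_chr(seg)
    expect_identical(rs$sequence[i], expected)
  }
})

test_that("an equal 1:1 mixture of equal-length transcripts splits reads binomially", {
  set.seed(31)
  ts <- transcript_set(c("a", "b"), c(random_seq(400), random_seq(400)))
  rs <- simulate_reads(ts, c(a = 1, b = 1), 1e5, 50, seed = 3)
  n_a <- sum(rs$truth_source == "a")
  expect_lt(abs(n_a - 50000), 3 * sqrt(1e5 * 0.25))
})

test_that("truth-label counts follow the length-weighted sampling distribution", {
  ts <- transcript_set(c("a", "b", "c"),
                       c(substr(strrep("ACGGTTCAAG", 40), 1, 400),
                         substr(strrep("TTGACCGTAC", 30), 1, 260),
                         substr(strrep("CAGTGCATGA", 20), 1, 160)))
  w <- c(a = 1, b = 2, c = 5)
  npos <- c(400, 260, 160) - 50 + 1
  p <- w * npos / sum(w * npos)
  pvals <- vapply(1:5, function(s) {
    rs <- simulate_reads(ts, w, 2e4, 50, seed = 100 + s)
    obs <- table(factor(rs$truth_source, levels = c("a", "b", "c")))
    stats::chisq.test(as.numeric(obs), p = p)$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("read-share weighting mode removes the length factor", {
  ts <- transcript_set(c("a", "b"),
                       c(substr(strrep("ACGGTTCAAG", 60), 1, 600),
                         substr(strrep("TTGACCGTAC", 15), 1, 150)))
  rs <- simulate_reads(ts, c(a = 1, b = 1), 4e4, 50, seed = 5,
                       length_weighting = FALSE)
  n_a <- sum(rs$truth_source == "a")
  expect_lt(abs(n_a - 20000), 4 * sqrt(4e4 * 0.25))
})

test_that("simulation is deterministic: same seed, byte-identical FASTQ", {
  ts <- make_paralog_family(200, 2, 0.05, seed = 1)
  mx <- c(paralog1 = 1, paralog2 = 1)
  r1 <- simulate_reads(ts, mx, 200, 50, seed = 99)
  r2 <- simulate_reads(ts, mx, 200, 50, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_read_set(r1, f1, truth_tsv = paste0(f1, ".tsv"))
  write_read_set(r2, f2, truth_tsv = paste0(f2, ".tsv"))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(paste0(f1, ".tsv"))),
                   unname(tools::md5sum(paste0(f2, ".tsv"))))
  # FASTQ round trip preserves ids and sequences
  back <- read_reads_fastq(f1)
  expect_identical(back$sequence, r1$sequence)
  expect_identical(back$id, r1$id)
})

test_that("simulate_reads rejects weighted transcripts shorter than the read", {
  ts <- transcript_set(c("long", "tiny"), c(strrep("ACGT", 50), strrep("ACGT", 10)))
  expect_error(simulate_reads(ts, c(long = 1, tiny = 1), 10, 50, seed = 1),
               "tiny")
  expect_silent(simulate_reads(ts, c(long = 1), 10, 50, seed = 1))
})

test_that("edited-amplicon alleles are built exactly (hand-constructed toy)", {
  ref <- "AAAACCCCTTTT"
  rs <- simulate_edited_amplicon_reads(
    ref, 4, 8, list(allele_spec("WT", 0.4), allele_spec("DEL", 0.3),
                    allele_spec("INV", 0.3)),
    n_reads = 50, read_length = 6, seed = 2)
  al <- attr(rs, "alleles")
  expect_identical(unname(al["DEL"]), "AAAATTTT")
  expect_identical(unname(al["INV"]), "AAAAGGGGTTTT")
  expect_identical(unname(al["WT"]), ref)
  expect_identical(nchar(al[["DEL"]]), nchar(ref) - 4L)
})

test_that("junction and cut-site indel alleles change length by delta", {
  ref <- paste0(strrep("ACGT", 10), strrep("GATC", 10), strrep("TGCA", 10))
  rs <- simulate_edited_amplicon_reads(
    ref, 40, 80,
    list(allele_spec("DEL_indel", 0.4, delta = -3),
         allele_spec("INDEL_A", 0.3, delta = 2),
         allele_spec("INDEL_B", 0.3, delta = -5)),
    n_reads = 30, read_length = 20, seed = 4)
  al <- attr(rs, "alleles")
  expect_identical(nchar(al[["DEL_indel"]]), nchar(ref) - 40L - 3L)
  expect_identical(nchar(al[["INDEL_A"]]), nchar(ref) + 2L)
  expect_identical(nchar(al[["INDEL_B"]]), nchar(ref) - 5L)
  # deletion at a cut removes bases immediately 3' of the cut
  expect_identical(al[["INDEL_B"]],
                   paste0(substr(ref, 1, 80), substr(ref, 86, nchar(ref))))
})

test_that("amplicon reads from a pure WT sample are substrings of the reference", {
  ref <- paste0(strrep("ACGGT", 30), strrep("TTGCA", 30))
  rs <- simulate_edited_amplicon_reads(ref, 50, 100, list(allele_spec("WT", 1)),
                                       n_reads = 100, read_length = 40, seed = 6)
  hit <- vapply(rs$sequence, function(s)
    grepl(s, ref, fixed = TRUE) || grepl(rc_chr(s), ref, fixed = TRUE),
    logical(1))
  expect_true(all(hit))
})

test_that("amplicon simulation validates coordinates, fractions and labels", {
  ref <- strrep("ACGT", 30)
  expect_error(simulate_edited_amplicon_reads(ref, 50, 20,
               list(allele_spec("WT", 1)), 10, 20, seed = 1), "coordinate")
  expect_error(simulate_edited_amplicon_reads(ref, 20, 50,
               list(allele_spec("WT", 0.5)), 10, 20, seed = 1), "sum to 1")
  expect_error(allele_spec("DEL_indel", 0.5, delta = 0), "non-zero")
  expect_error(allele_spec("WT", 0.5, delta = 3), "must be 0")
  expect_error(allele_spec("WT", 1.2), "fraction")
})
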