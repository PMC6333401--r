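make_amplicon <- function(seed = 101, len = 240, cutA = 80, cutB = 160) {
  set.seed(seed)
  list(ref = random_seq(len), cutA = cutA, cutB = cutB)
}

test_that("allele models are hand-constructible and carry junction windows", {
  m <- build_allele_models("AAAACCCCTTTT", 4, 8, window = 3)
  expect_identical(m$DEL$sequence, "AAAATTTT")
  expect_identical(m$INV$sequence, "AAAAGGGGTTTT")
  expect_identical(m$WT$sequence, "AAAACCCCTTTT")
  # DEL junction window straddles the fused flank boundary (offset 4)
  expect_true(m$DEL$junction_windows$J[1] < 4 && m$DEL$junction_windows$J[2] > 4)
  # degenerate cut pair: DEL equals WT
  m0 <- build_allele_models("AAAACCCCTTTT", 6, 6)
  expect_identical(m0$DEL$sequence, m0$WT$sequence)
  expect_error(build_allele_models("AAAACCCCTTTT", 8, 4), "coordinate")
})

test_that("junction-spanning reads call their allele; flank reads stay ambiguous", {
  a <- make_amplicon()
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  del <- models$DEL$sequence
  read_del <- substr(del, a$cutA - 30 + 1, a$cutA + 30)   # spans DEL junction
  read_flank <- substr(a$ref, 1, 60)                      # shared 5' flank
  read_wt <- substr(a$ref, a$cutA - 30 + 1, a$cutA + 30)  # spans cutA on WT
  read_alien <- strrep("ACGTG", 12)
  calls <- classify_amplicon_reads(
    c(read_del, read_flank, read_wt, read_alien), models)
  expect_identical(calls$call, c("DEL", "ambiguous", "WT", "unmapped"))
  expect_true(calls$informative[1])
  expect_false(calls$informative[2])
  expect_true(calls$informative[3])
})

test_that("reverse-complement reads classify identically", {
  a <- make_amplicon(103)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  read_del <- substr(models$DEL$sequence, a$cutA - 25 + 1, a$cutA + 25)
  calls <- classify_amplicon_reads(c(read_del, rc_chr(read_del)), models)
  expect_identical(calls$call, c("DEL", "DEL"))
  expect_identical(calls$informative, c(TRUE, TRUE))
})

test_that("a cut-site indel in a wild-type context is re-labelled with site and size", {
  a <- make_amplicon(107)
  # WT-context read with a 2-nt deletion right at cutA
  read <- paste0(substr(a$ref, a$cutA - 30 + 1, a$cutA),
                 substr(a$ref, a$cutA + 3, a$cutA + 32))
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  calls <- classify_amplicon_reads(read, models)
  expect_identical(calls$call, "junction_indel")
  expect_identical(calls$base, "WT")
  expect_identical(calls$site, "A")
  expect_identical(calls$delta, -2L)
  # and a 3-nt insertion at cutB
  read2 <- paste0(substr(a$ref, a$cutB - 30 + 1, a$cutB), "GGG",
                  substr(a$ref, a$cutB + 1, a$cutB + 27))
  calls2 <- classify_amplicon_reads(read2, models)
  expect_identical(calls2$call, "junction_indel")
  expect_identical(calls2$site, "B")
  expect_identical(calls2$delta, 3L)
})

test_that("allele labels are never assigned below the score margin", {
  a <- make_amplicon(109)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  rs <- simulate_edited_amplicon_reads(
    a$ref, a$cutA, a$cutB,
    list(allele_spec("WT", 0.4), allele_spec("DEL", 0.4),
         allele_spec("INV", 0.2)),
    n_reads = 300, read_length = 60, seed = 11, error_rate = 0.01)
  calls <- classify_amplicon_reads(rs, models)
  labelled <- calls$call %in% c("WT", "DEL", "INV", "junction_indel")
  expect_true(all(calls$margin[labelled] >= 2))
})

test_that("homozygous and heterozygous genotypes are called from allele fractions", {
  a <- make_amplicon(113)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  sim_calls <- function(alleles, n = 200, err = 0) {
    rs <- simulate_edited_amplicon_reads(a$ref, a$cutA, a$cutB, alleles,
                                         n_reads = n, read_length = 60,
                                         seed = 13, error_rate = err)
    classify_amplicon_reads(rs, models)
  }
  expect_identical(call_genotype(sim_calls(list(allele_spec("DEL", 1))))$call,
                   "hom_DEL")
  expect_identical(call_genotype(sim_calls(list(allele_spec("WT", 1))))$call,
                   "hom_WT")
  het <- call_genotype(sim_calls(list(allele_spec("WT", 0.5),
                                      allele_spec("DEL", 0.5)), n = 400,
                                 err = 0.005))
  expect_identical(het$call, "het_DEL")
  inv <- call_genotype(sim_calls(list(allele_spec("INV", 0.5),
                                      allele_spec("WT", 0.5))))
  expect_identical(inv$call, "INV_carrier")
})

test_that("deletion alleles differing by junction indels group as homozygous deletion", {
  a <- make_amplicon(127)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  rs <- simulate_edited_amplicon_reads(
    a$ref, a$cutA, a$cutB,
    list(allele_spec("DEL", 0.5), allele_spec("DEL_indel", 0.5, delta = -4)),
    n_reads = 300, read_length = 60, seed = 17)
  gt <- call_genotype(classify_amplicon_reads(rs, models))
  expect_identical(gt$call, "hom_DEL")
  expect_length(gt$present, 2L)
})

test_that("cut-site-indel-only samples are complex, not deletions", {
  a <- make_amplicon(131)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  rs <- simulate_edited_amplicon_reads(
    a$ref, a$cutA, a$cutB,
    list(allele_spec("INDEL_A", 0.5, delta = -3),
         allele_spec("INDEL_B", 0.5, delta = 2)),
    n_reads = 300, read_length = 60, seed = 19)
  gt <- call_genotype(classify_amplicon_reads(rs, models))
  expect_identical(gt$call, "complex")
})

test_that("too few informative reads yields a low-coverage call", {
  a <- make_amplicon(137)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  rs <- simulate_edited_amplicon_reads(a$ref, a$cutA, a$cutB,
                                       list(allele_spec("DEL", 1)),
                                       n_reads = 10, read_length = 60, seed = 23)
  calls <- classify_amplicon_reads(rs, models)
  gt <- call_genotype(calls, min_reads = 20)
  expect_identical(gt$call, "low_coverage")
  expect_lte(gt$n_informative, 10L)
})

test_that("genotype fractions are computed over informative reads and sum to <= 1", {
  a <- make_amplicon(139)
  models <- build_allele_models(a$ref, a$cutA, a$cutB)
  rs <- simulate_edited_amplicon_reads(
    a$ref, a$cutA, a$cutB,
    list(allele_spec("WT", 0.5), allele_spec("DEL", 0.5)),
    n_reads = 300, read_length = 60, seed = 29)
  calls <- classify_amplicon_reads(rs, models)
  gt <- call_genotype(calls)
  expect_lte(sum(gt$fractions), 1 + 1e-12)
  expect_identical(sum(gt$counts), gt$n_informative)
})
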