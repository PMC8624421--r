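ann_row <- function(consequence = "missense", cadd = NA_real_, pli = 0,
                    misz = 0, splice = FALSE, v1 = 0, v2 = 0, v3 = 0,
                    fe = "na", me = "na") {
  tibble::tibble(consequence = consequence, cadd = cadd, pli = pli, misz = misz,
                 splice_affecting = splice, votes_c1 = v1, votes_c2 = v2,
                 votes_c3 = v3, fe = fe, me = me)
}

test_that("the three disjunct criteria gate passage", {
  # frameshift in a constrained gene passes on loss-of-function alone
  v <- prioritize(ann_row("frameshift", pli = 0.99, fe = "no", me = "yes"))
  expect_true(v$passes)
  expect_true(v$lof_or_splice_in_intolerant)
  expect_equal(v$expression_support, "mouse")

  # CADD boundary: 14.9 fails, 15 passes
  expect_false(prioritize(ann_row(cadd = 14.9))$passes)
  expect_true(prioritize(ann_row(cadd = 15))$passes)
  expect_true(prioritize(ann_row(cadd = 15))$cadd_ge_15)
  expect_false(prioritize(ann_row(cadd = NA))$passes)

  # cluster consensus needs a majority in all three clusters
  expect_true(prioritize(ann_row(v1 = 3, v2 = 3, v3 = 2))$passes)
  expect_false(prioritize(ann_row(v1 = 3, v2 = 3, v3 = 1))$passes)

  # frameshift in a tolerant gene hits nothing
  expect_false(prioritize(ann_row("frameshift", pli = 0.1))$passes)
  # splice-affecting missense in a constrained (misz) gene passes
  expect_true(prioritize(ann_row("missense", misz = 3.4, splice = TRUE))$passes)
})

test_that("verdicts match a brute-force evaluation on random records", {
  cfg <- prioritization_config()
  set.seed(11)
  for (i in 1:300) {
    a <- ann_row(sample(c("missense", "frameshift", "premature_stop",
                          "synonymous", "splice"), 1),
                 cadd = sample(c(NA_real_, round(stats::runif(1, 0, 40), 1)), 1),
                 pli = stats::runif(1), misz = stats::rnorm(1, 0, 2),
                 splice = stats::runif(1) < 0.2,
                 v1 = sample(0:4, 1), v2 = sample(0:4, 1), v3 = sample(0:3, 1),
                 fe = sample(c("yes", "no", "na"), 1),
                 me = sample(c("yes", "no", "na"), 1))
    intolerant <- a$pli >= 0.9 || a$misz >= 3
    c1 <- (a$consequence %in% c("frameshift", "premature_stop") ||
             a$splice_affecting) && intolerant
    c2 <- !is.na(a$cadd) && a$cadd >= 15
    c3 <- a$votes_c1 >= 3 && a$votes_c2 >= 3 && a$votes_c3 >= 2
    v <- prioritize(a, cfg)
    expect_equal(v$passes, c1 || c2 || c3)
    expect_equal(v$n_criteria, sum(c1, c2, c3))
  }
})

test_that("adding a criterion hit never revokes passage", {
  set.seed(12)
  for (i in 1:100) {
    a <- ann_row(sample(c("missense", "frameshift"), 1),
                 cadd = stats::runif(1, 0, 30), pli = stats::runif(1),
                 v1 = sample(0:4, 1), v2 = sample(0:4, 1), v3 = sample(0:3, 1))
    before <- prioritize(a)$passes
    a$cadd <- 20  # force the CADD criterion on
    expect_true(prioritize(a)$passes >= before)
  }
})

test_that("validation ranking is deterministic and ordered by evidence", {
  pl <- dplyr::bind_rows(
    planted_variant("chr1", 100, "A", "T", 0.4, 0),
    planted_variant("chr1", 200, "A", "T", 0.4, 0),
    planted_variant("chr2", 300, "G", "C", 0.4, 0))
  sim <- gen_paired_counts(count_sim_config(n_sites = 10, error_rate = 0,
                                            planted = pl, seed = 61))
  calls <- call_pairs(pair_tables(sim$counts_a, sim$counts_b))
  overrides <- dplyr::bind_cols(
    pl[, c("chrom", "pos", "ref", "alt")],
    tibble::tibble(cadd = c(18, 25, 5), pli = 0, misz = 0,
                   gnomad_exome_af = 0, gnomad_genome_af = 0))
  ann <- gen_annotations(sim$truth, planted_annotations = overrides, seed = 62)
  ann$votes_c1 <- 0L; ann$votes_c2 <- 0L; ann$votes_c3 <- 0L
  ann$fe <- "na"; ann$me <- "na"; ann$splice_affecting <- FALSE
  ann$pli[!paste(ann$chrom, ann$pos) %in% paste(pl$chrom, pl$pos)] <- 0

  ranked <- rank_for_validation(calls, ann, k = 5)
  expect_lte(nrow(ranked), 3L)
  # cadd 25 outranks cadd 18 outranks the non-passing cadd 5
  expect_equal(ranked$pos[1:2], c(200L, 100L))

  # permuting the call order leaves the ranking unchanged
  set.seed(63)
  for (i in 1:5) {
    shuffled <- calls[sample(nrow(calls)), ]
    expect_equal(rank_for_validation(shuffled, ann, k = 5)$pos, ranked$pos)
  }

  one <- rank_for_validation(calls[which(calls$pos == 200), ], ann, k = 5)
  expect_equal(nrow(one), 1L)
  expect_error(rank_for_validation(calls, ann, k = -1), "nonnegative")
})

test_that("HSCR gene membership is a normalized list lookup", {
  expect_true(flag_hscr_genes("RET"))
  expect_true(flag_hscr_genes(" ret "))
  expect_false(flag_hscr_genes("FMN2"))
  expect_equal(flag_hscr_genes(c("RET", "EDNRB", "ABC1")),
               c(TRUE, TRUE, FALSE))
  expect_warning(res <- flag_hscr_genes("RET", character(0)), "empty gene list")
  expect_false(res)
})

test_that("the fixture replica configuration reproduces the per-patient prioritized counts", {
  t2 <- load_fixture("table2")
  ann <- table2_annotations(t2)
  v <- prioritize(ann, table2_replica())
  expect_true(all(v$passes))
  per_patient <- vapply(1:5, function(p) sum(v$passes[ann$patient == p]), numeric(1))
  expect_equal(per_patient, c(5, 1, 0, 15, 2))
  expect_equal(load_fixture("table1")$vape, per_patient)
})
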