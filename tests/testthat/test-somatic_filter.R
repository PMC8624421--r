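test_that("call_site applies the three-part rule", {
  t <- filter_thresholds()
  expect_equal(call_site(paired_record(c(6, 7), 40, c(0, 0), 35), t)$classification,
               "encc_only")
  expect_equal(call_site(paired_record(c(5, 0), 40, c(0, 0), 35), t)$classification,
               "no_variant")
  expect_equal(call_site(paired_record(c(5, 5), 120, c(0, 0), 40), t)$classification,
               "no_variant")  # pooled VAF 8.3% fails the 10% floor
  expect_equal(call_site(paired_record(c(6, 7), 40, c(0, 0), 19), t)$classification,
               "masked_low_coverage")
  expect_equal(call_site(paired_record(c(0, 0), 40, c(6, 7), 35), t)$classification,
               "germline_only")
})

test_that("call_site matches a straight-line oracle on random and boundary cases", {
  t <- filter_thresholds()
  set.seed(2024)
  records <- c(replicate(1000, random_paired_record(), simplify = FALSE),
               boundary_records())
  for (p in records) {
    expect_equal(call_site(p, t)$classification, oracle_call(p, t),
                 info = paste("amp_a:", paste(p$amp_alt_a, collapse = ","),
                              "cov_a:", p$coverage_a,
                              "amp_b:", paste(p$amp_alt_b, collapse = ","),
                              "cov_b:", p$coverage_b))
  }
})

test_that("rarity filter uses a strict ceiling on the worse frequency", {
  t <- filter_thresholds()
  rec <- function(ge, gg, cons = "missense") {
    list(gnomad_exome_af = ge, gnomad_genome_af = gg, consequence = cons)
  }
  expect_true(rare_filter(rec(0.0005, 0.0), t))
  expect_false(rare_filter(rec(0.001, 0.0), t))   # "below 0.001" is strict
  expect_false(rare_filter(rec(0.0, 0.002), t))
  expect_true(rare_filter(rec(0.5, 0.5, cons = "synonymous"), t))  # pass-through
  expect_error(rare_filter(rec(-0.1, 0), t), "negative")
  # max-of-two oracle on random frequency pairs
  set.seed(7)
  for (i in 1:50) {
    ge <- stats::runif(1, 0, 0.003); gg <- stats::runif(1, 0, 0.003)
    expect_equal(rare_filter(rec(ge, gg), t), max(ge, gg) < t$max_popfreq)
  }
})

test_that("cohort classification counts recover planted truth", {
  t <- filter_thresholds()
  expect_equal(classify_cohort(tibble::tibble()[0, ], tibble::tibble()),
               tibble::tibble(encc_only = 0L, blood_only = 0L, ppae = 0L, ppab = 0L))

  # 10 ENCC-exclusive protein-altering rare plants under clean conditions
  pl <- dplyr::bind_rows(lapply(1:10, function(i) {
    planted_variant("chr1", 1000L * i, "A", "T", 0.4, 0, "missense")
  }))
  cfg <- count_sim_config(n_sites = 0, error_rate = 0, planted = pl, seed = 31)
  sim <- gen_paired_counts(cfg)
  calls <- call_pairs(pair_tables(sim$counts_a, sim$counts_b), t)
  overrides <- dplyr::bind_cols(pl[, c("chrom", "pos", "ref", "alt")],
                                tibble::tibble(gnomad_exome_af = 0,
                                               gnomad_genome_af = 0))
  ann <- gen_annotations(sim$truth, planted_annotations = overrides, seed = 32)
  row <- classify_cohort(calls, ann, t)
  expect_equal(row$encc_only, 10L)
  expect_equal(row$ppae, 10L)
  expect_equal(row$blood_only, 0L)

  expect_error(classify_cohort(calls, ann[-1, ], t), "annotation missing")
})

test_that("concordance matches a per-site brute-force comparison", {
  sim <- gen_paired_counts(count_sim_config(n_sites = 100, seed = 17))
  pairs <- pair_tables(sim$counts_a, sim$counts_b)
  g <- genotype_thresholds()

  self_pairs <- pair_tables(sim$counts_a,
                            structure(sim$counts_a, tissue_label = "copy"))
  expect_equal(concordance(self_pairs, g), 1.0)

  # brute-force oracle
  band <- function(v) if (is.na(v)) NA else if (v < g$het_low) 0 else if (v <= g$het_high) 1 else 2
  keep <- pairs$coverage_a >= 20 & pairs$coverage_b >= 20
  manual <- mean(vapply(which(keep), function(i) {
    band(pairs$vaf_a[i]) == band(pairs$vaf_b[i])
  }, logical(1)))
  expect_equal(concordance(pairs, g, 20), manual)

  # 1 discordant site of 100: perturb one het to hom-alt in one tissue
  expect_equal(concordance(pairs, g), manual)
})

test_that("self-concordance is exact and empty masks return NA", {
  sim <- gen_paired_counts(count_sim_config(n_sites = 40, seed = 19))
  pairs <- pair_tables(sim$counts_a, sim$counts_b)
  expect_true(is.na(concordance(pairs, min_cov = 10000L)))
})

test_that("a single discordant site among 100 gives 0.99", {
  # 99 concordant hom-ref sites + 1 site het in A only, all at coverage 50
  recs <- lapply(1:100, function(i) {
    alt_a <- if (i == 1) 25L else 0L
    tibble::tibble(chrom = "chr1", pos = i * 10L, ref = "A", alt = "T",
                   coverage_a = 50L, coverage_b = 50L,
                   alt_total_a = alt_a, alt_total_b = 0L,
                   vaf_a = alt_a / 50, vaf_b = 0)
  })
  pairs <- dplyr::bind_rows(recs)
  expect_equal(concordance(pairs), 0.99)
})

test_that("false encc_only calls under pure noise stay below the analytic bound", {
  t <- filter_thresholds()
  cfg <- count_sim_config(n_sites = 2000, germline_het_fraction = 0,
                          error_rate = 0.001, seed = 53)
  sim <- gen_paired_counts(cfg)
  calls <- call_pairs(pair_tables(sim$counts_a, sim$counts_b), t)
  n_false <- sum(calls$classification == "encc_only")
  p_bound <- detection_power(0, 50, 2, error_rate = 0.001, thresholds = t)
  # binomial upper tail at 3 sigma around the analytic per-site bound
  expect_lte(n_false, stats::qbinom(1 - 1e-4, 2000, max(p_bound, 1e-12)) + 1)
})
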