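test_that("expected het BAF bands follow the allele-dosage model", {
  expect_equal(unname(expected_het_baf("loss", 0)), c(0.5, 0.5))
  expect_equal(unname(expected_het_baf("loss", 1)), c(0, 1))
  expect_equal(unname(expected_het_baf("loss", 0.5)), c(1/3, 2/3))
  expect_equal(unname(expected_het_baf("gain", 0)), c(0.5, 0.5))
  expect_equal(unname(expected_het_baf("gain", 1)), c(1/3, 2/3))
  expect_error(expected_het_baf("inversion", 0.5), "loss.*gain")

  # brute-force allele dosage: mix f cells with (1, 0) copies of (B, A) lost
  for (f in seq(0, 1, by = 0.1)) {
    b_copies <- f * 1 + (1 - f) * 1   # het B allele retained everywhere
    a_copies <- f * 0 + (1 - f) * 1   # A allele lost in fraction f
    expect_equal(unname(expected_het_baf("loss", f))[2],
                 b_copies / (b_copies + a_copies))
  }
})

test_that("fraction_from_deviation inverts the band model on both states", {
  for (state in c("loss", "gain")) {
    for (f in seq(0, 1, by = 0.05)) {
      d <- unname(expected_het_baf(state, f))[2] - 0.5
      expect_equal(fraction_from_deviation(state, d), f, tolerance = 1e-10)
    }
  }
})

test_that("noise-free profiles are exact and round-trip through segmentation", {
  ev <- tibble::tibble(chrom = "chr1", start = 400000, end = 1200000,
                       state = "loss", f_germline = 0, f_encc = 0.4)
  prof <- gen_cn_profiles(ev, chroms = "chr1", baf_sd = 0, lrr_sd = 0, seed = 5)
  het_out <- prof$encc$genotype_call == "AB" &
    (prof$encc$pos < 400000 | prof$encc$pos > 1200000)
  expect_true(all(prof$encc$baf[het_out] == 0.5))
  het_in <- prof$encc$genotype_call == "AB" & !het_out &
    prof$encc$pos >= 400000
  bands <- unname(expected_het_baf("loss", 0.4))
  expect_true(all(round(prof$encc$baf[het_in], 10) %in% round(bands, 10)))

  seg <- segment_profile(prof$encc)
  loss <- seg[seg$state == "loss", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$start, 400000)
  expect_equal(loss$end, 1200000)
  expect_equal(loss$mosaic_fraction, 0.4, tolerance = 1e-6)

  # no events, zero noise: single neutral segment, all het baf exactly 0.5
  flat <- gen_cn_profiles(NULL, chroms = "chr1", baf_sd = 0, lrr_sd = 0, seed = 6)
  expect_true(all(flat$encc$baf[flat$encc$genotype_call == "AB"] == 0.5))
})

test_that("flat noisy profiles yield one neutral segment per chromosome", {
  prof <- gen_cn_profiles(NULL, seed = 9)
  seg <- segment_profile(prof$encc)
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$state == "neutral"))
})

test_that("a full-clonality deletion is recovered at fraction ~1", {
  ev <- tibble::tibble(chrom = "chr1", start = 400000, end = 1000000,
                       state = "loss", f_germline = 0, f_encc = 1)
  prof <- gen_cn_profiles(ev, chroms = "chr1", seed = 12)
  seg <- segment_profile(prof$encc)
  loss <- seg[seg$state == "loss", ]
  expect_gte(max(loss$mosaic_fraction), 0.95)
})

test_that("planted mosaic fractions are recovered from the BAF shift", {
  for (f in c(0.2, 0.4, 0.8)) {
    est <- vapply(1:10, function(s) {
      ev <- tibble::tibble(chrom = "chr1", start = 300000, end = 1730000,
                           state = "loss", f_germline = 0, f_encc = f)
      prof <- gen_cn_profiles(ev, chroms = "chr1", seed = 100 * f + s)
      seg <- segment_profile(prof$encc)
      cand <- seg[seg$state == "loss", ]
      if (nrow(cand) == 0) return(NA_real_)
      cand$mosaic_fraction[which.max(cand$n_probes)]
    }, numeric(1))
    expect_lt(abs(stats::median(est, na.rm = TRUE) - f), 0.05)
  }
})

test_that("BAF mirror symmetry leaves every statistic unchanged", {
  ev <- tibble::tibble(chrom = "chr1", start = 300000, end = 1500000,
                       state = "loss", f_germline = 0, f_encc = 0.3)
  prof <- gen_cn_profiles(ev, seed = 21)
  mirror <- function(p) { p$baf <- 1 - p$baf; p }
  seg1 <- segment_profile(prof$encc)
  seg2 <- segment_profile(mirror(prof$encc))
  expect_equal(seg2, seg1)
  rep1 <- compare_paired_profiles(prof$germline, prof$encc)
  rep2 <- compare_paired_profiles(mirror(prof$germline), mirror(prof$encc))
  expect_equal(rep2, rep1)
})

test_that("paired comparison flags new events and respects the 20% limit", {
  # identical profiles: nothing flagged
  prof0 <- gen_cn_profiles(NULL, seed = 31)
  rep0 <- compare_paired_profiles(prof0$germline, prof0$germline)
  expect_true(all(rep0$flag == "none"))

  # ENCC-only loss at f = 0.3: flagged as a new event
  ev <- tibble::tibble(chrom = "chr1", start = 300000, end = 1500000,
                       state = "loss", f_germline = 0, f_encc = 0.3)
  hits <- vapply(1:5, function(s) {
    prof <- gen_cn_profiles(ev, seed = 40 + s)
    rep <- compare_paired_profiles(prof$germline, prof$encc)
    any(rep$flag == "new_event")
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # shared event with fraction difference 0.05 (< 0.20): not flagged
  ev2 <- tibble::tibble(chrom = "chr1", start = 300000, end = 1500000,
                        state = "loss", f_germline = 0.45, f_encc = 0.5)
  prof2 <- gen_cn_profiles(ev2, seed = 51)
  rep2 <- compare_paired_profiles(prof2$germline, prof2$encc)
  expect_false(any(rep2$flag == "allele_specific_difference"))
})

test_that("input contracts are enforced", {
  prof <- gen_cn_profiles(NULL, chroms = "chr1", n_probes_per_chrom = 100, seed = 3)
  shuffled <- prof$encc[sample(nrow(prof$encc)), ]
  expect_error(segment_profile(shuffled), "not sorted")
  expect_error(compare_paired_profiles(prof$encc[-1, ], prof$encc),
               "unmatched probes")
  ov <- tibble::tibble(chrom = "chr1", start = c(1, 500), end = c(1000, 2000),
                       state = "loss", f_germline = 0, f_encc = c(0.5, 0.5))
  expect_error(gen_cn_profiles(ov), "overlapping events")
  p1 <- gen_cn_profiles(NULL, seed = 8)
  p2 <- gen_cn_profiles(NULL, seed = 8)
  expect_identical(p1, p2)
})
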