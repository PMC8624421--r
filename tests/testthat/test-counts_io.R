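test_that("count tables read back validated and intact", {
  fx <- random_count_fixture(n_sites = 3, seed = 11)
  tab <- read_count_table(fx$cnt_path, fx$amp_path, tissue_label = "ENCC")
  expect_equal(nrow(tab), 6L)
  expect_identical(tissue_label(tab), "ENCC")
  expect_equal(tibble::as_tibble(tab), fx$counts, ignore_attr = TRUE)
})

test_that("malformed count tables raise named errors", {
  fx <- random_count_fixture(n_sites = 3, seed = 12)
  dir <- withr::local_tempdir()

  bad <- fx$counts
  bad$alt_reads[2] <- -1L
  p <- file.path(dir, "neg.tsv")
  readr::write_tsv(bad, p, progress = FALSE)
  expect_error(read_count_table(p, fx$amp_path), "negative read count at row 2")

  bad <- fx$counts[, setdiff(names(fx$counts), "alt_reads")]
  p <- file.path(dir, "miscol.tsv")
  readr::write_tsv(bad, p, progress = FALSE)
  expect_error(read_count_table(p, fx$amp_path), "alt_reads")

  bad <- fx$counts[c(1, 1, 2), ]
  p <- file.path(dir, "dup.tsv")
  readr::write_tsv(bad, p, progress = FALSE)
  expect_error(read_count_table(p, fx$amp_path), "duplicate \\(site, amplicon\\)")

  bad <- fx$counts
  bad$pos[1] <- bad$pos[1] + 1000L
  p <- file.path(dir, "outside.tsv")
  readr::write_tsv(bad, p, progress = FALSE)
  expect_error(read_count_table(p, fx$amp_path), "outside its amplicon")
})

test_that("write then read is the identity on randomized tables", {
  for (seed in 1:5) {
    fx <- random_count_fixture(n_sites = sample(2:12, 1), n_amps = sample(1:3, 1),
                               seed = seed)
    tab <- read_count_table(fx$cnt_path, fx$amp_path, "ENCC")
    dir <- withr::local_tempdir()
    p2 <- file.path(dir, "roundtrip.tsv")
    write_count_table(tab, p2)
    tab2 <- read_count_table(p2, fx$amp_path, "ENCC")
    expect_identical(tibble::as_tibble(tab2), tibble::as_tibble(tab))
  }
})

test_that("pairing joins sites across tissues with zero-fill", {
  fx <- random_count_fixture(n_sites = 4, seed = 21)
  a <- read_count_table(fx$cnt_path, fx$amp_path, "ENCC")
  b_tbl <- fx$counts[fx$counts$pos %in% unique(fx$counts$pos)[1:2], ]
  dir <- withr::local_tempdir()
  pb <- file.path(dir, "b.tsv")
  readr::write_tsv(b_tbl, pb, progress = FALSE)
  b <- read_count_table(pb, fx$amp_path, "blood")

  pairs <- pair_tables(a, b)
  expect_equal(nrow(pairs), 4L)
  only_a <- pairs[pairs$coverage_b == 0, ]
  expect_equal(nrow(only_a), 2L)
  expect_true(all(is.na(only_a$vaf_b)))
  both <- pairs[pairs$coverage_b > 0, ]
  expect_equal(both$coverage_a, both$coverage_b)  # same table on both sides

  expect_error(pair_tables(a, a), "same tissue label")
})

test_that("pairing is a set union, symmetric up to label swap", {
  for (seed in 31:33) {
    fa <- random_count_fixture(n_sites = 8, seed = seed)
    fb <- random_count_fixture(n_sites = 6, seed = seed + 100)
    a <- read_count_table(fa$cnt_path, fa$amp_path, "ENCC")
    b <- read_count_table(fb$cnt_path, fb$amp_path, "blood")
    pairs <- pair_tables(a, b)
    union_n <- length(unique(c(paste(fa$counts$chrom, fa$counts$pos, fa$counts$ref, fa$counts$alt),
                               paste(fb$counts$chrom, fb$counts$pos, fb$counts$ref, fb$counts$alt))))
    expect_equal(nrow(pairs), union_n)
    swapped <- pair_tables(b, a)
    expect_equal(swapped$coverage_a, pairs$coverage_b)
    expect_equal(swapped$coverage_b, pairs$coverage_a)
    expect_equal(swapped$vaf_a, pairs$vaf_b)
    expect_equal(swapped$amp_alt_a, pairs$amp_alt_b)
  }
})

test_that("calls export as VCF 4.2 that a standard reader reproduces", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()

  empty <- call_pairs(pair_tables(
    read_count_table(random_count_fixture(3, seed = 41)$cnt_path,
                     random_count_fixture(3, seed = 41)$amp_path, "ENCC"),
    read_count_table(random_count_fixture(3, seed = 41)$cnt_path,
                     random_count_fixture(3, seed = 41)$amp_path, "blood")))[0, ]
  p0 <- file.path(dir, "empty.vcf")
  write_calls_vcf(empty, p0)
  v0 <- vcfR::read.vcfR(p0, verbose = FALSE)
  expect_equal(nrow(v0@fix), 0L)

  pl <- planted_variant("chr7", 55555, "G", "A", 0.4, 0)
  sim <- gen_paired_counts(count_sim_config(n_sites = 5, planted = pl, seed = 7))
  calls <- call_pairs(pair_tables(sim$counts_a, sim$counts_b))
  p1 <- file.path(dir, "calls.vcf")
  write_calls_vcf(calls, p1)
  v1 <- vcfR::read.vcfR(p1, verbose = FALSE)
  expect_equal(nrow(v1@fix), nrow(calls))
  expect_equal(as.integer(v1@fix[, "POS"]), calls$pos)
  expect_equal(v1@fix[, "REF"], calls$ref)
  expect_equal(unname(vcfR::extract.info(v1, "CLS")), calls$classification)
  expect_equal(unname(as.numeric(vcfR::extract.info(v1, "DPA"))), calls$coverage_a)
  vafa <- suppressWarnings(as.numeric(vcfR::extract.info(v1, "VAFA")))
  expect_equal(vafa, calls$vaf_a, tolerance = 1e-5)
  planted_row <- which(calls$pos == 55555)
  expect_equal(unname(vcfR::extract.info(v1, "CLS"))[planted_row], "encc_only")
})
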