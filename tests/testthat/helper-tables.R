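# Builders for small in-memory fixtures used across the test files.

# Random amplicon panel + count table written to disk; returns paths and the
# tibble that was written.
random_count_fixture <- function(n_sites = 10, n_amps = 2, seed = 1,
                                 dir = withr::local_tempdir(.local_envir = parent.frame())) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  amps <- tibble::tibble(
    chrom = rep("chr1", n_sites * n_amps),
    start = rep(pos, each = n_amps) - 50L,
    end = rep(pos, each = n_amps) + 50L + rep(seq_len(n_amps), n_sites),
    amplicon_id = sprintf("a%03d_%d", rep(seq_len(n_sites), each = n_amps),
                          rep(seq_len(n_amps), n_sites))
  )
  counts <- tibble::tibble(
    chrom = amps$chrom,
    pos = rep(pos, each = n_amps),
    ref = rep(ref, each = n_amps),
    alt = rep(unname(alt), each = n_amps),
    amplicon_id = amps$amplicon_id,
    ref_reads = sample(0:80, n_sites * n_amps, TRUE),
    alt_reads = sample(0:20, n_sites * n_amps, TRUE)
  )
  amp_path <- file.path(dir, paste0("amps", seed, ".bed"))
  cnt_path <- file.path(dir, paste0("counts", seed, ".tsv"))
  enccmosaic::write_amplicons(amps, amp_path)
  readr::write_tsv(counts, cnt_path, progress = FALSE)
  list(amps = amps, counts = counts, amp_path = amp_path, cnt_path = cnt_path)
}

# A paired-site record in the shape call_site() consumes.
paired_record <- function(amp_alt_a, cov_a, amp_alt_b, cov_b,
                          chrom = "chr1", pos = 1000L) {
  list(chrom = chrom, pos = pos, ref = "A", alt = "T",
       coverage_a = as.integer(cov_a), coverage_b = as.integer(cov_b),
       amp_alt_a = as.integer(amp_alt_a), amp_alt_b = as.integer(amp_alt_b))
}

# Independent straight-line restatement of the three-part calling rule, kept
# deliberately separate from the package implementation.
oracle_call <- function(p, t = enccmosaic::filter_thresholds()) {
  if (p$coverage_a < t$min_coverage_both || p$coverage_b < t$min_coverage_both) {
    return("masked_low_coverage")
  }
  pres <- function(amp, cov) {
    sum(amp >= t$min_alt_reads_per_amplicon) >= t$min_supporting_amplicons &&
      cov > 0 && sum(amp) / cov >= t$min_vaf
  }
  absent <- function(amp, cov) {
    cov > 0 && sum(amp) / cov <= t$absence_max_vaf &&
      sum(amp) <= t$absence_max_alt_reads
  }
  pa <- pres(p$amp_alt_a, p$coverage_a)
  pb <- pres(p$amp_alt_b, p$coverage_b)
  if (pa && pb) "shared"
  else if (pa && absent(p$amp_alt_b, p$coverage_b)) "encc_only"
  else if (pb && absent(p$amp_alt_a, p$coverage_a)) "germline_only"
  else "no_variant"
}

random_paired_record <- function() {
  n_amp <- sample(1:3, 1)
  cov_a <- sample(0:40, n_amp, TRUE)
  cov_b <- sample(0:40, n_amp, TRUE)
  alt_a <- vapply(cov_a, function(cc) sample(0:cc, 1), integer(1))
  alt_b <- vapply(cov_b, function(cc) sample(0:cc, 1), integer(1))
  paired_record(alt_a, sum(cov_a), alt_b, sum(cov_b))
}

# Boundary grid around the printed criteria: exactly 5 alt reads, exactly 2
# amplicons, VAF exactly 0.10, coverage exactly 20.
boundary_records <- function() {
  list(
    paired_record(c(5L, 5L), 100L, c(0L, 0L), 40L),   # VAF exactly 0.10
    paired_record(c(5L, 5L), 120L, c(0L, 0L), 40L),   # VAF 8.3%, fails
    paired_record(c(5L, 4L), 40L, c(0L, 0L), 40L),    # one amplicon at 4
    paired_record(c(5L, 5L), 40L, c(0L, 0L), 20L),    # coverage exactly 20
    paired_record(c(5L, 5L), 40L, c(0L, 0L), 19L),    # coverage 19, masked
    paired_record(c(4L, 4L, 4L), 40L, c(0L, 0L, 0L), 40L), # 12 reads, no amp at 5
    paired_record(c(6L, 7L), 40L, c(1L, 1L), 40L),    # B: 2 alt reads, absent
    paired_record(c(6L, 7L), 40L, c(2L, 1L), 40L),    # B: 3 alt reads, not absent
    paired_record(c(6L, 7L), 40L, c(6L, 7L), 40L),    # shared
    paired_record(c(5L, 0L), 40L, c(0L, 0L), 35L)     # single supporting amplicon
  )
}
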