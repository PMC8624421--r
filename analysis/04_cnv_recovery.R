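#!/usr/bin/env Rscript

# Mosaic copy-number analysis on synthetic paired array profiles: how well the
# BAF-shift statistic recovers planted mosaic cell fractions, and whether the
# paired comparison flags ENCC-only events while respecting the platform
# limits (~10% for new events, ~20% for allele-specific paired differences).

suppressPackageStartupMessages(library(enccmosaic))
dir.create("results", showWarnings = FALSE)

recover <- function(f, n_seeds = 40, seed0 = 500) {
  vapply(seq_len(n_seeds), function(k) {
    ev <- tibble::tibble(chrom = "chr1", start = 300000, end = 1730000,
                         state = "loss", f_germline = 0, f_encc = f)
    prof <- gen_cn_profiles(ev, chroms = "chr1", seed = seed0 + 100 * f + k)
    seg <- segment_profile(prof$encc)
    cand <- seg[seg$state == "loss", ]
    if (nrow(cand) == 0) return(NA_real_)
    cand$mosaic_fraction[which.max(cand$n_probes)]
  }, numeric(1))
}

fractions <- c(0.1, 0.2, 0.4, 0.8)
tab <- dplyr::bind_rows(lapply(fractions, function(f) {
  est <- recover(f)
  tibble::tibble(true_fraction = f,
                 median_estimate = stats::median(est, na.rm = TRUE),
                 mad = stats::mad(est, na.rm = TRUE),
                 detected = mean(!is.na(est)))
}))
readr::write_tsv(tab, "results/cnv_fraction_recovery.tsv")
cat("Mosaic fraction recovery from ~500 het probes per event (40 seeds):\n")
print(as.data.frame(tab), digits = 3)

cat("\nPaired comparison: ENCC-only loss at f = 0.3\n")
ev <- tibble::tibble(chrom = "chr1", start = 300000, end = 1730000,
                     state = "loss", f_germline = 0, f_encc = 0.3)
prof <- gen_cn_profiles(ev, seed = 11)
rep1 <- compare_paired_profiles(prof$germline, prof$encc)
print(as.data.frame(rep1), digits = 3)
readr::write_tsv(rep1, "results/cnv_paired_comparison.tsv")

cat("\nPaired fraction difference 0.05 (below the 20% limit): flags ->\n")
ev2 <- tibble::tibble(chrom = "chr1", start = 300000, end = 1730000,
                      state = "loss", f_germline = 0.45, f_encc = 0.5)
prof2 <- gen_cn_profiles(ev2, seed = 12)
rep2 <- compare_paired_profiles(prof2$germline, prof2$encc)
print(table(rep2$flag))
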