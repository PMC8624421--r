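#!/usr/bin/env Rscript

# Sensitivity of the threshold-based somatic caller: exact detection
# probability of the presence rule (>=5 alt reads in each of >=2 amplicons and
# pooled VAF >= 10%) as a function of true VAF and per-amplicon coverage, plus
# the Sanger validation floor.

suppressPackageStartupMessages(library(enccmosaic))
dir.create("results", showWarnings = FALSE)

tab <- power_table(c(0.02, 0.05, 0.08, 0.10, 0.12, 0.15, 0.20, 0.25, 0.30,
                     0.40, 0.50),
                   c(20, 30, 50, 100, 200), error_rate = 0.001)
readr::write_tsv(tab, "results/detection_power.tsv")

cat("Detection power at selected points (analytic, 2 amplicons):\n")
sel <- tab[tab$true_vaf %in% c(0.05, 0.10, 0.15, 0.30) &
             tab$coverage_per_amplicon %in% c(20, 50, 200), ]
print(as.data.frame(sel), digits = 3)

cat("\nAt the 10% VAF floor the caller transitions sharply; a 5% variant is\n")
cat("effectively undetectable at any depth (deep sequencing concentrates its\n")
cat("observed VAF below the floor), mirroring the Sanger sensitivity of ~10%:\n")
cat("sanger_validate(0.05):", sanger_validate(0.05), "\n")
cat("sanger_validate(0.15):", sanger_validate(0.15), "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- ggplot2::ggplot(tab, ggplot2::aes(true_vaf, power,
                                         colour = factor(coverage_per_amplicon))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true VAF", y = "detection probability",
                  colour = "coverage/amplicon") +
    ggplot2::theme_minimal()
  ggplot2::ggsave("results/detection_power.pdf", p, width = 6, height = 4)
  cat("\nWrote results/detection_power.pdf\n")
}
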