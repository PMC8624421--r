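# Detection power of the threshold-based somatic caller, and the Sanger
# validation sensitivity model.
#
# Alt reads per amplicon are Binomial(coverage, p_eff) with
# p_eff = v (1 - e) + (1 - v) e for true VAF v and per-read error e. The
# presence rule holds when at least `min_supporting_amplicons` amplicons each
# carry `min_alt_reads_per_amplicon` alt reads and the pooled VAF reaches
# `min_vaf`. The analytic method sums the joint per-amplicon outcome space
# exactly (dynamic programme over amplicons tracking the supporting-amplicon
# count and the pooled alt total); Monte Carlo estimates the same probability
# from seeded replicates.

p_effective <- function(true_vaf, error_rate) {
  true_vaf * (1 - error_rate) + (1 - true_vaf) * error_rate
}

#' Probability that the presence rule detects a variant
#'
#' @param true_vaf True variant allele fraction in the affected tissue.
#' @param coverage_per_amplicon Reads per amplicon.
#' @param n_amplicons Number of amplicons covering the site (default 2).
#' @param error_rate Per-read miscall probability (default 0.001).
#' @param thresholds A [filter_thresholds()].
#' @param method `"analytic"` (exact) or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates (default 1e4).
#' @param seed Seed for the Monte-Carlo method.
#' @param include_absence Also require the absence rule to hold in the other
#'   tissue (joint two-tissue power); off by default — power concerns the
#'   affected tissue.
#' @param true_vaf_b,coverage_b True VAF and pooled coverage in the other
#'   tissue when `include_absence = TRUE`.
#' @param max_outcomes Refuse the analytic method above this outcome-space
#'   size (default 1e8) with a message directing to `monte_carlo`.
#' @return Detection probability. Monte-Carlo results carry an `"se"`
#'   attribute (binomial standard error).
#' @export
detection_power <- function(true_vaf, coverage_per_amplicon, n_amplicons = 2L,
                            error_rate = 0.001,
                            thresholds = filter_thresholds(),
                            method = c("analytic", "monte_carlo"),
                            reps = 10000L, seed = 1L,
                            include_absence = FALSE,
                            true_vaf_b = 0, coverage_b = NULL,
                            max_outcomes = 1e8) {
  method <- match.arg(method)
  stopifnot(true_vaf >= 0, true_vaf <= 1, coverage_per_amplicon >= 0,
            n_amplicons >= 1, error_rate >= 0, error_rate <= 1)
  C <- as.integer(coverage_per_amplicon)
  n <- as.integer(n_amplicons)
  p <- p_effective(true_vaf, error_rate)
  t <- thresholds
  s_min <- ceiling(t$min_vaf * n * C - 1e-9)
  if (method == "analytic") {
    # DP cost ~ n * (n+1) * (nC+1) * (C+1)
    cost <- as.numeric(n) * (n + 1) * (n * C + 1) * (C + 1)
    if (cost > max_outcomes) {
      stop("detection_power: analytic outcome space too large (",
           format(cost, big.mark = ","), " states); use method = \"monte_carlo\"",
           call. = FALSE)
    }
    px <- dbinom(0:C, C, p)
    s_max <- n * C
    P <- matrix(0, nrow = n + 1L, ncol = s_max + 1L)
    P[1L, 1L] <- 1
    for (i in seq_len(n)) {
      newP <- matrix(0, nrow = n + 1L, ncol = s_max + 1L)
      for (j in 0:(i - 1L)) {
        row <- P[j + 1L, ]
        if (all(row == 0)) next
        for (x in 0:C) {
          if (px[x + 1L] == 0) next
          j2 <- j + (x >= t$min_alt_reads_per_amplicon)
          if (x == 0L) {
            newP[j2 + 1L, ] <- newP[j2 + 1L, ] + row * px[1L]
          } else {
            idx <- seq_len(s_max + 1L - x)
            newP[j2 + 1L, idx + x] <- newP[j2 + 1L, idx + x] + row[idx] * px[x + 1L]
          }
        }
      }
      P <- newP
    }
    ok_rows <- (t$min_supporting_amplicons:n) + 1L
    ok_cols <- which((0:s_max) >= s_min)
    power <- if (t$min_supporting_amplicons > n) 0 else sum(P[ok_rows, ok_cols, drop = FALSE])
    power <- min(max(power, 0), 1)
  } else {
    stopifnot(reps >= 1)
    set.seed(seed)
    x <- matrix(rbinom(n * reps, C, p), nrow = n)
    support <- colSums(x >= t$min_alt_reads_per_amplicon)
    s <- colSums(x)
    hit <- support >= t$min_supporting_amplicons & s >= s_min
    power <- mean(hit)
    attr(power, "se") <- sqrt(power * (1 - power) / reps)
  }
  if (include_absence) {
    cb <- if (is.null(coverage_b)) n * C else as.integer(coverage_b)
    pb <- p_effective(true_vaf_b, error_rate)
    s_abs <- min(t$absence_max_alt_reads, floor(t$absence_max_vaf * cb + 1e-9))
    power <- power * pbinom(s_abs, cb, pb)
  }
  power
}

#' Sanger validation outcome for a candidate
#'
#' Sanger sequencing is modelled as a deterministic VAF threshold: a known
#' variant is detectable down to roughly 10% allele fraction, so a candidate
#' is confirmed iff its true VAF reaches `sensitivity_vaf`. A sequencing
#' artifact (true VAF 0) is never confirmed.
#'
#' @param true_vaf True VAF(s) in the validated tissue.
#' @param sensitivity_vaf Detection threshold (default 0.10).
#' @return Character vector, `"confirmed"` or `"not_confirmed"`.
#' @export
sanger_validate <- function(true_vaf, sensitivity_vaf = 0.10) {
  stopifnot(all(true_vaf >= 0), all(true_vaf <= 1),
            sensitivity_vaf > 0, sensitivity_vaf < 1)
  ifelse(true_vaf >= sensitivity_vaf, "confirmed", "not_confirmed")
}

#' Detection power over a VAF x coverage grid
#'
#' @param vaf_grid,coverage_grid Nonempty numeric grids.
#' @param ... Passed to [detection_power()] (thresholds, n_amplicons, method,
#'   ...).
#' @return Tibble with one row per grid point carrying the inputs and the
#'   power.
#' @export
power_table <- function(vaf_grid, coverage_grid, ...) {
  stopifnot(length(vaf_grid) > 0, length(coverage_grid) > 0)
  grid <- expand.grid(true_vaf = vaf_grid,
                      coverage_per_amplicon = coverage_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(function(v, cc) {
    as.numeric(detection_power(v, cc, ...))
  }, grid$true_vaf, grid$coverage_per_amplicon)
  tibble::as_tibble(grid)
}
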