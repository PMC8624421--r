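# Stochastic simulator of enteric neural crest colonization with a mutant
# clone, formalizing three verbal selection models: neutral (the mutation
# rides along), selective advantage (mutants divide/survive/migrate more) and
# selective disadvantage (less). The gut is a 1-D chain of segments with a
# per-segment carrying capacity; founders start at the rostral end and the
# wavefront moves caudally. Failure to reach the caudal end leaves an
# aganglionic segment, the disease lesion. A biopsy readout converts the
# mutant cell fraction at a segment into the allele fraction bulk sequencing
# of that biopsy would see, diluted by the non-ENCC tissue majority.

#' Configuration for the colonization simulator
#'
#' Defaults are chosen so that wild-type colonization of the full gut
#' succeeds in well over 95% of seeds, leaving selection — not baseline
#' failure — as the driver of aganglionosis.
#'
#' @param n_segments Gut length in segments (default 50).
#' @param carrying_capacity Maximum cells per segment (default 40).
#' @param n_founders Founder cells at the rostral end (default 10).
#' @param n_steps Time steps (default 120).
#' @param p_divide Baseline per-step division probability (default 0.3).
#' @param p_advance Baseline per-step probability of migrating one segment
#'   caudally (default 0.5).
#' @param p_survive Baseline per-step survival probability (default 0.98).
#' @param model `"neutral"`, `"advantage"` or `"disadvantage"`.
#' @param s Selection coefficient in \[0, 1\]; mutant probabilities are
#'   multiplied by `1 + s` (advantage) or `1 - s` (disadvantage) on the
#'   processes named in `sel_on`, clipped to \[0, 1\].
#' @param sel_on Processes selection acts on; subset of
#'   `c("division", "migration", "survival")` (default all three).
#' @param t_mut Step at whose end one uniformly chosen living cell mutates;
#'   `0` mutates a founder before the first step.
#' @param superstar Draw founder division-rate multipliers from a heavy-tailed
#'   (Pareto) law so few clones dominate the final ENS (default `FALSE`).
#' @param superstar_alpha Pareto tail index (default 1.2; smaller = heavier
#'   tail).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_segments = 50L, carrying_capacity = 40L,
                       n_founders = 10L, n_steps = 120L,
                       p_divide = 0.3, p_advance = 0.5, p_survive = 0.98,
                       model = c("neutral", "advantage", "disadvantage"),
                       s = 0, sel_on = c("division", "migration", "survival"),
                       t_mut = 0L, superstar = FALSE, superstar_alpha = 1.2,
                       seed = 1L) {
  model <- match.arg(model)
  sel_on <- match.arg(sel_on, several.ok = TRUE)
  stopifnot(n_segments >= 1, carrying_capacity >= 1, n_founders >= 1,
            n_steps >= 1, p_divide >= 0, p_divide <= 1,
            p_advance >= 0, p_advance <= 1, p_survive >= 0, p_survive <= 1,
            s >= 0, s <= 1, superstar_alpha > 0)
  if (t_mut > n_steps) {
    stop("sim_config: t_mut exceeds n_steps", call. = FALSE)
  }
  structure(list(n_segments = as.integer(n_segments),
                 carrying_capacity = as.integer(carrying_capacity),
                 n_founders = as.integer(n_founders),
                 n_steps = as.integer(n_steps),
                 p_divide = p_divide, p_advance = p_advance,
                 p_survive = p_survive, model = model, s = s, sel_on = sel_on,
                 t_mut = as.integer(t_mut), superstar = superstar,
                 superstar_alpha = superstar_alpha, seed = as.integer(seed)),
            class = "sim_config")
}

mutant_multiplier <- function(config, process) {
  if (config$model == "neutral" || !(process %in% config$sel_on)) return(1)
  if (config$model == "advantage") 1 + config$s else 1 - config$s
}

#' Simulate rostro-caudal colonization with a mutant clone
#'
#' @param config A [sim_config()].
#' @return A `colonization_result` list: `wt` and `mut` matrices
#'   (`(n_steps + 1) x n_segments` cell counts, row 1 = founders),
#'   `wavefront` (most caudal segment ever occupied, per step), `colonized`,
#'   `aganglionic_length`, `clone_sizes` (final cells per founder clone) and
#'   the config.
#' @export
simulate_colonization <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  res <- colonize_cpp(config$n_segments, config$carrying_capacity,
                      config$n_founders, config$n_steps,
                      config$p_divide, config$p_advance, config$p_survive,
                      mutant_multiplier(config, "division"),
                      mutant_multiplier(config, "migration"),
                      mutant_multiplier(config, "survival"),
                      config$t_mut, config$superstar, config$superstar_alpha)
  wavefront <- as.integer(res$wavefront)
  final_front <- wavefront[length(wavefront)]
  structure(list(wt = res$wt, mut = res$mut, wavefront = wavefront,
                 colonized = final_front == config$n_segments,
                 aganglionic_length = config$n_segments - final_front,
                 clone_sizes = as.integer(res$clone_sizes),
                 config = config),
            class = "colonization_result")
}

#' @export
print.colonization_result <- function(x, ...) {
  n_final <- sum(x$wt[nrow(x$wt), ]) + sum(x$mut[nrow(x$mut), ])
  cat(sprintf(paste0("<colonization_result: %s model, %d cells at end, ",
                     "wavefront %d/%d, aganglionic length %d>\n"),
              x$config$model, n_final,
              x$wavefront[length(x$wavefront)], x$config$n_segments,
              x$aganglionic_length))
  invisible(x)
}

#' Final mutant cell fraction at a gut segment
#'
#' @param r A `colonization_result`.
#' @param segment Segment index (1 = rostral), or `NULL` for the whole gut.
#' @return Mutant / (mutant + wild-type) at the final step; 0 for an empty
#'   segment.
#' @export
mutant_fraction <- function(r, segment = NULL) {
  last <- nrow(r$wt)
  if (is.null(segment)) {
    w <- sum(r$wt[last, ]); m <- sum(r$mut[last, ])
  } else {
    stopifnot(segment >= 1, segment <= r$config$n_segments)
    w <- r$wt[last, segment]; m <- r$mut[last, segment]
  }
  if (w + m == 0) 0 else m / (w + m)
}

#' Expected biopsy allele fraction at a gut segment
#'
#' A full-thickness biopsy is mostly non-ENCC tissue; only
#' `encc_tissue_fraction` of its cells are ENCC-derived. For a heterozygous
#' somatic variant the expected VAF is
#' `mutant_fraction * encc_tissue_fraction / 2` (at most 0.5). Set
#' `encc_tissue_fraction = 1` for a sorted / purified ENCC sample.
#'
#' @param r A `colonization_result`.
#' @param position Segment index of the biopsy.
#' @param encc_tissue_fraction ENCC-derived fraction of biopsy cells
#'   (default 0.05).
#' @return One-row tibble: `position`, `mutant_fraction`,
#'   `encc_tissue_fraction`, `expected_vaf`, and `empty_segment` (TRUE, with a
#'   warning, when no cell reached the biopsied segment).
#' @export
biopsy_vaf <- function(r, position, encc_tissue_fraction = 0.05) {
  stopifnot(position >= 1, position <= r$config$n_segments,
            encc_tissue_fraction >= 0, encc_tissue_fraction <= 1)
  last <- nrow(r$wt)
  empty <- (r$wt[last, position] + r$mut[last, position]) == 0
  if (empty) {
    warning("biopsy_vaf: biopsied segment ", position, " holds no ENCC-derived cells")
  }
  mf <- mutant_fraction(r, position)
  tibble::tibble(position = as.integer(position), mutant_fraction = mf,
                 encc_tissue_fraction = encc_tissue_fraction,
                 expected_vaf = mf * encc_tissue_fraction / 2,
                 empty_segment = empty)
}

#' Gini coefficient of final clone sizes
#'
#' Quantifies clonal dominance: 0 when every founder clone contributes
#' equally, approaching 1 when a few "superstar" clones form the entire ENS.
#'
#' @param r A `colonization_result`.
#' @return Gini coefficient in \[0, 1\] (NA when no cells remain).
#' @export
clone_gini <- function(r) {
  x <- sort(r$clone_sizes)
  n <- length(x)
  if (sum(x) == 0) return(NA_real_)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Sweep selection scenarios over a grid
#'
#' Runs `n_seeds` replicates per grid point (seeds derived deterministically
#' from the base config's seed) and summarizes colonization success,
#' aganglionic length, the proximal-biopsy expected VAF, the distal mutant
#' fraction, and the probability that the amplicon filter would detect the
#' variant in a bulk proximal biopsy at the given sequencing depth.
#'
#' @param base A [sim_config()] supplying all non-swept parameters.
#' @param grid Tibble with any of the columns `model`, `s`, `t_mut`,
#'   `superstar`; one row per scenario.
#' @param n_seeds Replicates per scenario (default 100).
#' @param biopsy_position Segment of the proximal biopsy (default 1).
#' @param encc_tissue_fraction ENCC fraction of biopsy cells (default 0.05).
#' @param coverage_per_amplicon,n_amplicons Sequencing depth assumed for the
#'   detectability column (defaults 50, 2).
#' @param thresholds [filter_thresholds()] for the detectability column.
#' @return Tibble, one row per scenario, with means, Monte-Carlo standard
#'   errors and `p_detect_biopsy`.
#' @export
scenario_sweep <- function(base, grid, n_seeds = 100L, biopsy_position = 1L,
                           encc_tissue_fraction = 0.05,
                           coverage_per_amplicon = 50L, n_amplicons = 2L,
                           thresholds = filter_thresholds()) {
  stopifnot(nrow(grid) >= 1, n_seeds >= 1)
  grid <- tibble::as_tibble(grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (col in intersect(names(grid), c("model", "s", "t_mut", "superstar"))) {
      cfg[[col]] <- grid[[col]][i]
    }
    reps <- lapply(seq_len(n_seeds), function(j) {
      cfg$seed <- base$seed + (i - 1L) * n_seeds + j
      r <- simulate_colonization(cfg)
      bio <- suppressWarnings(biopsy_vaf(r, biopsy_position, encc_tissue_fraction))
      last_front <- max(r$wavefront[length(r$wavefront)], 1L)
      tibble::tibble(colonized = r$colonized,
                     aganglionic_length = r$aganglionic_length,
                     proximal_vaf = bio$expected_vaf,
                     whole_gut_mutant_fraction = mutant_fraction(r),
                     distal_mutant_fraction = mutant_fraction(r, last_front))
    })
    reps <- dplyr::bind_rows(reps)
    se <- function(x) stats::sd(x) / sqrt(length(x))
    mean_vaf <- mean(reps$proximal_vaf)
    tibble::tibble(
      grid[i, ],
      n_seeds = n_seeds,
      p_colonized = mean(reps$colonized),
      mean_aganglionic_length = mean(reps$aganglionic_length),
      se_aganglionic_length = se(reps$aganglionic_length),
      mean_proximal_vaf = mean_vaf,
      se_proximal_vaf = se(reps$proximal_vaf),
      mean_mutant_fraction = mean(reps$whole_gut_mutant_fraction),
      se_mutant_fraction = se(reps$whole_gut_mutant_fraction),
      mean_distal_mutant_fraction = mean(reps$distal_mutant_fraction),
      p_detect_biopsy = as.numeric(detection_power(
        min(mean_vaf, 1), coverage_per_amplicon, n_amplicons,
        thresholds = thresholds))
    )
  })
  dplyr::bind_rows(out)
}
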