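# End-to-end synthetic-cohort analysis: generation -> pairing -> calling ->
# rarity filter -> prioritization -> in-silico Sanger validation, summarized
# per patient in the study-table layout (ENCC-only, blood-only, PPAE, PPAB,
# VAPE, validated) plus a per-variant listing and a confusion matrix against
# the generator's ground truth.

#' Run the full paired-tissue analysis on a synthetic cohort
#'
#' Each in-silico patient gets a deterministic seed derived from the global
#' one. The per-patient flow is: simulate paired counts, pair, call sites,
#' simulate annotations, count classifications (with the protein-altering
#' rarity filter), prioritize and rank the ENCC-exclusive candidates, and
#' validate the top-ranking ones against ground truth with the Sanger
#' sensitivity model — a candidate is confirmed only if it is truly somatic in
#' the ENCC at a VAF the validation assay can see.
#'
#' @param n_patients Number of in-silico patients (default 5).
#' @param base_config A [count_sim_config()] template; its seed is replaced
#'   per patient.
#' @param planted_per_patient Optional list (length `n_patients`) of planted
#'   variant tibbles; `NULL` entries mean no plants.
#' @param planted_annotations_per_patient Optional list of annotation
#'   overrides for the plants (see [gen_annotations()]).
#' @param thresholds A [filter_thresholds()].
#' @param prio_cfg A [prioritization_config()].
#' @param sanger_sensitivity Sanger VAF sensitivity (default 0.10).
#' @param top_k Candidates taken to validation per patient (default 10).
#' @param seed Global seed.
#' @param out_dir Optional directory; when given, writes `summary.tsv`,
#'   `candidates.tsv`, `confusion.tsv`, per-patient call VCFs and a plain-text
#'   summary there.
#' @return List: `summary` (per-patient tibble), `candidates` (ranked
#'   per-variant tibble with truth and validation columns), `confusion`
#'   (site-level truth vs call table), `per_patient` (full per-patient
#'   objects).
#' @export
run_end_to_end <- function(n_patients = 5L,
                           base_config = count_sim_config(),
                           planted_per_patient = NULL,
                           planted_annotations_per_patient = NULL,
                           thresholds = filter_thresholds(),
                           prio_cfg = prioritization_config(),
                           sanger_sensitivity = 0.10,
                           top_k = 10L,
                           seed = 1L,
                           out_dir = NULL) {
  stopifnot(n_patients >= 1)
  if (!is.null(planted_per_patient)) {
    stopifnot(length(planted_per_patient) == n_patients)
  }
  per_patient <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    stage <- "synthetic counts"
    res <- tryCatch({
      cfg <- base_config
      cfg$seed <- as.integer(seed + 1000L * i)
      cfg$planted <- if (is.null(planted_per_patient)) NULL else
        planted_per_patient[[i]]
      sim <- gen_paired_counts(cfg)
      stage <- "pairing"
      pairs <- pair_tables(sim$counts_a, sim$counts_b)
      stage <- "somatic calling"
      calls <- call_pairs(pairs, thresholds)
      stage <- "annotation"
      pl_ann <- if (is.null(planted_annotations_per_patient)) NULL else
        planted_annotations_per_patient[[i]]
      ann <- gen_annotations(sim$truth, planted_annotations = pl_ann,
                             seed = cfg$seed + 1L)
      stage <- "classification"
      counts_row <- classify_cohort(calls, ann, thresholds)
      stage <- "prioritization"
      ranked <- rank_for_validation(calls, ann, prio_cfg, k = top_k)
      # VAPE: ENCC-exclusive, protein-altering, rare, meeting a criterion
      encc <- calls[calls$classification == "encc_only", ]
      vape <- 0L
      if (nrow(encc) > 0L) {
        ea <- ann[match(site_key(encc), site_key(ann)), ]
        keep <- ea$consequence %in% protein_altering & rare_filter(ea, thresholds)
        vape <- sum(prioritize(ea, prio_cfg)$passes & keep)
      }
      stage <- "validation"
      validated <- 0L
      if (nrow(ranked) > 0L) {
        ti <- match(site_key(ranked), site_key(sim$truth))
        truth_vaf <- sim$truth$true_vaf_a[ti]
        truly_somatic <- sim$truth$is_somatic[ti] & truth_vaf > 0
        outcome <- sanger_validate(truth_vaf, sanger_sensitivity)
        ranked$true_vaf_encc <- truth_vaf
        ranked$sanger <- ifelse(truly_somatic & outcome == "confirmed",
                                "confirmed", "not_confirmed")
        validated <- sum(ranked$sanger == "confirmed")
      }
      truth_somatic_a <- sim$truth$is_somatic & sim$truth$true_vaf_a > 0
      called_encc <- calls$classification[match(site_key(sim$truth),
                                                site_key(calls))] == "encc_only"
      confusion <- tibble::tibble(
        patient = i,
        tp = sum(truth_somatic_a & called_encc),
        fp = sum(!truth_somatic_a & called_encc),
        fn = sum(truth_somatic_a & !called_encc),
        tn = sum(!truth_somatic_a & !called_encc)
      )
      list(sim = sim, calls = calls, annotations = ann, ranked = ranked,
           summary = tibble::tibble(patient = i, counts_row, vape = vape,
                                    validated = validated),
           confusion = confusion)
    }, error = function(e) {
      stop("run_end_to_end: patient ", i, " failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    per_patient[[i]] <- res
  }
  summary <- dplyr::bind_rows(lapply(per_patient, `[[`, "summary"))
  confusion <- dplyr::bind_rows(lapply(per_patient, `[[`, "confusion"))
  candidates <- dplyr::bind_rows(lapply(seq_len(n_patients), function(i) {
    r <- per_patient[[i]]$ranked
    if (nrow(r) == 0L) return(NULL)
    sel <- c("chrom", "pos", "ref", "alt", "gene", "classification",
             "vaf_a", "vaf_b", "passes", "n_criteria", "expression_support",
             "cadd", "true_vaf_encc", "sanger")
    dplyr::bind_cols(tibble::tibble(patient = i), r[, intersect(sel, names(r))])
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"), progress = FALSE)
    if (nrow(candidates) > 0L) {
      readr::write_tsv(candidates, file.path(out_dir, "candidates.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(confusion, file.path(out_dir, "confusion.tsv"),
                     progress = FALSE)
    for (i in seq_len(n_patients)) {
      write_calls_vcf(per_patient[[i]]$calls,
                      file.path(out_dir, sprintf("patient%02d_calls.vcf", i)))
    }
    txt <- c("Synthetic paired-tissue somatic mosaicism analysis",
             sprintf("patients: %d  seed: %d", n_patients, seed),
             sprintf("thresholds: >=%d alt reads in >=%d amplicons, VAF >= %.2f, coverage >= %dx, popfreq < %g",
                     thresholds$min_alt_reads_per_amplicon,
                     thresholds$min_supporting_amplicons, thresholds$min_vaf,
                     thresholds$min_coverage_both, thresholds$max_popfreq),
             "",
             utils::capture.output(print(as.data.frame(summary))))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  list(summary = summary, candidates = candidates, confusion = confusion,
       per_patient = per_patient)
}
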