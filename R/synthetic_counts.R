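# Synthetic paired-tissue amplicon counts with known ground truth.
#
# The generator emulates the study conditions: two cell types from one
# individual (ENCC vs blood/fibroblast), per-amplicon allele counts at exonic
# sites, a shared germline background, planted tissue-exclusive somatic
# variants, and sequencing noise including optional systematic artifact sites
# that show elevated error in *both* tissues (the unvalidatable-candidate
# pattern).

#' Describe a planted variant
#'
#' @param chrom,pos,ref,alt Genomic site (1-based position).
#' @param true_vaf_a,true_vaf_b True variant allele fraction in each tissue. A
#'   somatic plant has a positive VAF in exactly one tissue and 0 in the other;
#'   a germline het has ~0.5 in both.
#' @param consequence One of `missense`, `frameshift`, `premature_stop`,
#'   `splice`, `synonymous`.
#' @return One-row tibble describing the plant.
#' @export
planted_variant <- function(chrom, pos, ref, alt, true_vaf_a, true_vaf_b,
                            consequence = "missense") {
  stopifnot(true_vaf_a >= 0, true_vaf_a <= 1, true_vaf_b >= 0, true_vaf_b <= 1)
  consequence <- match.arg(consequence, c("missense", "frameshift",
                                          "premature_stop", "splice",
                                          "synonymous"))
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 true_vaf_a = true_vaf_a, true_vaf_b = true_vaf_b,
                 consequence = consequence)
}

#' Configuration for the paired-count generator
#'
#' @param n_sites Number of background sites (shared between tissues).
#' @param n_amplicons_per_site Amplicons covering each site (default 2, the
#'   minimum the calling rule can ever satisfy).
#' @param mean_coverage_per_amplicon Mean reads per amplicon (default 50).
#' @param coverage_dispersion Negative-binomial size parameter; `Inf` gives
#'   Poisson coverage. Default 10 (moderate capture variability).
#' @param error_rate Per-read miscall probability (default 0.001).
#' @param germline_het_fraction Fraction of background sites that are
#'   heterozygous in both tissues (default 0.3).
#' @param artifact_fraction Fraction of hom-ref background sites that are
#'   systematic artifacts, showing `artifact_error_rate` in both tissues
#'   (default 0).
#' @param artifact_error_rate Elevated per-read error at artifact sites
#'   (default 0.05).
#' @param planted Tibble of planted variants (rows from [planted_variant()]),
#'   or `NULL`.
#' @param tissue_a,tissue_b Tissue labels (defaults `"ENCC"`, `"blood"`).
#' @param seed Integer seed; fixes the full output.
#' @return A `count_sim_config` list.
#' @export
count_sim_config <- function(n_sites = 200L,
                             n_amplicons_per_site = 2L,
                             mean_coverage_per_amplicon = 50,
                             coverage_dispersion = 10,
                             error_rate = 0.001,
                             germline_het_fraction = 0.3,
                             artifact_fraction = 0,
                             artifact_error_rate = 0.05,
                             planted = NULL,
                             tissue_a = "ENCC", tissue_b = "blood",
                             seed = 1L) {
  stopifnot(n_sites >= 0, n_amplicons_per_site >= 1,
            mean_coverage_per_amplicon > 0, coverage_dispersion > 0,
            error_rate >= 0, error_rate <= 1,
            germline_het_fraction >= 0, germline_het_fraction <= 1,
            artifact_fraction >= 0, artifact_fraction <= 1,
            artifact_error_rate >= 0, artifact_error_rate <= 1)
  if (!is.null(planted) && nrow(planted) > 0L) {
    if (anyDuplicated(site_key(planted)) > 0L) {
      stop("count_sim_config: duplicated planted site", call. = FALSE)
    }
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_amplicons_per_site = as.integer(n_amplicons_per_site),
                 mean_coverage_per_amplicon = mean_coverage_per_amplicon,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate,
                 germline_het_fraction = germline_het_fraction,
                 artifact_fraction = artifact_fraction,
                 artifact_error_rate = artifact_error_rate,
                 planted = planted,
                 tissue_a = tissue_a, tissue_b = tissue_b,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

draw_coverage <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Generate paired tissue count tables with ground truth
#'
#' Per site and amplicon, coverage is negative-binomial with the configured
#' mean and dispersion; alt reads are binomial with success probability
#' `true_vaf * (1 - error) + (1 - true_vaf) * error`. Both tissues share the
#' same site and amplicon set (the same capture design).
#'
#' @param config A [count_sim_config()].
#' @return A list with `counts_a`, `counts_b` (`tissue_counts` tables),
#'   `amplicons` (BED-style tibble) and `truth` (one row per emitted site with
#'   true VAFs, genotypes and flags).
#' @export
gen_paired_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  n_bg <- config$n_sites
  # Background sites: unique positions scattered over the autosomes.
  chroms <- paste0("chr", sample.int(22L, n_bg, replace = TRUE))
  pos <- sample.int(100000000L, n_bg, replace = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_bg, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  is_het <- runif(n_bg) < config$germline_het_fraction
  truth <- tibble::tibble(
    chrom = chroms, pos = as.integer(pos), ref = ref, alt = unname(alt),
    true_vaf_a = ifelse(is_het, 0.5, 0),
    true_vaf_b = ifelse(is_het, 0.5, 0),
    consequence = sample(c("synonymous", "missense"), n_bg, TRUE, c(0.4, 0.6)),
    planted = FALSE
  )
  truth$artifact <- !is_het & runif(n_bg) < config$artifact_fraction
  if (!is.null(config$planted) && nrow(config$planted) > 0L) {
    pl <- config$planted
    if (any(site_key(pl) %in% site_key(truth))) {
      stop("gen_paired_counts: planted site collides with a background site; ",
           "use a distinct position", call. = FALSE)
    }
    pl$planted <- TRUE
    pl$artifact <- FALSE
    truth <- dplyr::bind_rows(truth, pl)
  }
  truth$is_somatic <- truth$true_vaf_a != truth$true_vaf_b &
    (truth$true_vaf_a == 0 | truth$true_vaf_b == 0)
  truth <- truth[order(truth$chrom, truth$pos), ]
  n <- nrow(truth)
  k <- config$n_amplicons_per_site
  # One amplicon panel shared by both tissues; staggered windows over each site.
  amplicons <- tibble::tibble(
    chrom = rep(truth$chrom, each = k),
    start = pmax(0L, rep(truth$pos, each = k) - 80L + (seq_len(k) - 1L) * 15L),
    end = rep(truth$pos, each = k) + 80L + (rep(seq_len(k), n) - 1L) * 15L,
    amplicon_id = sprintf("amp_%05d_%d", rep(seq_len(n), each = k),
                          rep(seq_len(k), n))
  )
  err <- ifelse(truth$artifact, config$artifact_error_rate, config$error_rate)
  draw_tissue <- function(true_vaf, label) {
    p_eff <- rep(true_vaf * (1 - err) + (1 - true_vaf) * err, each = k)
    cov <- draw_coverage(n * k, config$mean_coverage_per_amplicon,
                         config$coverage_dispersion)
    alt_reads <- rbinom(n * k, cov, p_eff)
    new_tissue_counts(tibble::tibble(
      chrom = amplicons$chrom,
      pos = rep(truth$pos, each = k),
      ref = rep(truth$ref, each = k),
      alt = rep(truth$alt, each = k),
      amplicon_id = amplicons$amplicon_id,
      ref_reads = as.integer(cov - alt_reads),
      alt_reads = as.integer(alt_reads)
    ), label)
  }
  counts_a <- draw_tissue(truth$true_vaf_a, config$tissue_a)
  counts_b <- draw_tissue(truth$true_vaf_b, config$tissue_b)
  list(counts_a = counts_a, counts_b = counts_b,
       amplicons = amplicons, truth = truth)
}

#' Distribution parameters for synthetic annotations
#'
#' Background annotation values are drawn from simple parametric laws; planted
#' sites can override any column exactly via `planted_annotations` in
#' [gen_annotations()].
#'
#' @param af_shape1,af_shape2 Beta parameters for background population allele
#'   frequencies (defaults 0.5, 20: mostly sub-percent with a common tail).
#' @param cadd_mean,cadd_sd Normal parameters for background CADD, truncated at
#'   0 (defaults 8, 6).
#' @param pli_shape1,pli_shape2 Beta parameters for pLI (defaults 0.25, 0.75:
#'   U-shaped mass near 0 with a constrained tail).
#' @param misz_mean,misz_sd Normal parameters for missense-Z (defaults 0, 1.5).
#' @param cluster_sizes Tool counts of the three prediction-tool clusters
#'   (default `c(4, 4, 3)`).
#' @param vote_prob Per-tool probability of a deleterious vote at a background
#'   site (default 0.15).
#' @param p_splice Probability a background site is splice-affecting (default
#'   0.01).
#' @param expr_probs Probabilities of `yes`/`no`/`na` for the fetal-human and
#'   mouse-ENS expression flags (default `c(0.4, 0.3, 0.3)`).
#' @return An `annotation_model` list.
#' @export
annotation_model <- function(af_shape1 = 0.5, af_shape2 = 20,
                             cadd_mean = 8, cadd_sd = 6,
                             pli_shape1 = 0.25, pli_shape2 = 0.75,
                             misz_mean = 0, misz_sd = 1.5,
                             cluster_sizes = c(4L, 4L, 3L),
                             vote_prob = 0.15,
                             p_splice = 0.01,
                             expr_probs = c(yes = 0.4, no = 0.3, na = 0.3)) {
  structure(as.list(environment()), class = "annotation_model")
}

#' Generate an annotation table for simulated sites
#'
#' One record per truth site. Background values follow the configured
#' distributions; rows of `planted_annotations` (matched on site) overwrite
#' their non-NA columns exactly, so deleterious plants carry their configured
#' annotations verbatim.
#'
#' @param truth Truth tibble from [gen_paired_counts()] (may be empty).
#' @param model An [annotation_model()].
#' @param planted_annotations Optional tibble with site columns plus any of the
#'   annotation columns to pin.
#' @param seed Integer seed.
#' @return An annotation tibble (one row per site) with gene, consequence,
#'   population frequencies, cadd, pli, misz, splice/intolerance flags,
#'   per-cluster deleterious vote counts and tri-state fe/me expression flags.
#' @export
gen_annotations <- function(truth, model = annotation_model(),
                            planted_annotations = NULL, seed = 1L) {
  cols <- c("gene", "consequence", "gnomad_exome_af", "gnomad_genome_af",
            "cadd", "pli", "misz", "splice_affecting", "intolerant_gene",
            "votes_c1", "votes_c2", "votes_c3", "fe", "me", "hscr_gene")
  if (nrow(truth) == 0L) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
    for (cl in cols) out[[cl]] <- logical(0)
    return(out)
  }
  set.seed(seed)
  n <- nrow(truth)
  expr_levels <- c("yes", "no", "na")
  ann <- tibble::tibble(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    gene = sprintf("GENE%05d", seq_len(n)),
    consequence = truth$consequence,
    gnomad_exome_af = rbeta(n, model$af_shape1, model$af_shape2),
    gnomad_genome_af = rbeta(n, model$af_shape1, model$af_shape2),
    cadd = pmax(0, rnorm(n, model$cadd_mean, model$cadd_sd)),
    pli = rbeta(n, model$pli_shape1, model$pli_shape2),
    misz = rnorm(n, model$misz_mean, model$misz_sd),
    splice_affecting = runif(n) < model$p_splice,
    votes_c1 = rbinom(n, model$cluster_sizes[1], model$vote_prob),
    votes_c2 = rbinom(n, model$cluster_sizes[2], model$vote_prob),
    votes_c3 = rbinom(n, model$cluster_sizes[3], model$vote_prob),
    fe = sample(expr_levels, n, TRUE, model$expr_probs),
    me = sample(expr_levels, n, TRUE, model$expr_probs),
    hscr_gene = FALSE
  )
  ann$intolerant_gene <- ann$pli >= 0.9 | ann$misz >= 3
  if (!is.null(planted_annotations) && nrow(planted_annotations) > 0L) {
    idx <- match(site_key(planted_annotations), site_key(ann))
    if (anyNA(idx)) {
      stop("gen_annotations: planted_annotations reference unknown site(s)",
           call. = FALSE)
    }
    for (cl in intersect(names(planted_annotations), cols)) {
      val <- planted_annotations[[cl]]
      keep <- !is.na(val)
      ann[[cl]][idx[keep]] <- val[keep]
    }
  }
  ann
}

#' Load a packaged in-paper fixture table
#'
#' `table1` holds the per-patient variant counts (ENCC-only, blood-only,
#' protein-altering subsets, prioritized and validated counts); `table2` the
#' per-variant listing of prioritized ENCC candidates (patient, gene, cDNA,
#' type, class, population frequencies, constraint scores and expression
#' flags). Patient 3 has no rows in `table2`: none of its candidates met the
#' quality criteria.
#'
#' @param name Either `"table1"` or `"table2"`.
#' @return The fixture as a tibble, verbatim.
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  if (length(name) != 1L || !name %in% c("table1", "table2")) {
    stop("load_fixture: unknown fixture name; use \"table1\" or \"table2\"",
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "enccmosaic",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
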