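#' @useDynLib enccmosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rbinom rnbinom rbeta rnorm runif setNames median quantile
#'   p.adjust wilcox.test pbinom dbinom
#' @importFrom utils head
"_PACKAGE"

# Coordinate conventions used throughout: variant positions are 1-based (VCF),
# amplicon intervals are 0-based half-open (BED).

site_cols <- c("chrom", "pos", "ref", "alt")

validate_sites <- function(df, context = "table") {
  bad <- which(df$pos < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: pos must be >= 1 (row %d)", context, bad[1]), call. = FALSE)
  }
  bad <- which(!grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt))
  if (length(bad) > 0L) {
    stop(sprintf("%s: ref/alt must be non-empty uppercase ACGT (row %d)",
                 context, bad[1]), call. = FALSE)
  }
  bad <- which(df$ref == df$alt)
  if (length(bad) > 0L) {
    stop(sprintf("%s: ref equals alt (row %d)", context, bad[1]), call. = FALSE)
  }
  invisible(df)
}

site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Read an amplicon definition file (BED)
#'
#' Columns: chrom, start, end, amplicon_id; 0-based half-open intervals.
#'
#' @param path Path to a BED file (tab-separated, no header, `#` comments
#'   allowed).
#' @return A tibble with columns `chrom`, `start`, `end`, `amplicon_id`.
#' @export
read_amplicons <- function(path) {
  if (!file.exists(path)) stop("amplicon file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("chrom", "start", "end", "amplicon_id"),
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          start = readr::col_integer(),
                          end = readr::col_integer(),
                          amplicon_id = readr::col_character()
                        ),
                        progress = FALSE)
  if (any(df$end <= df$start)) {
    stop("amplicon definitions: end must exceed start", call. = FALSE)
  }
  if (anyDuplicated(df$amplicon_id) > 0L) {
    stop("amplicon definitions: duplicate amplicon_id", call. = FALSE)
  }
  df
}

#' Write an amplicon definition file (BED)
#'
#' @param amplicons Tibble as returned by [read_amplicons()].
#' @param path Output path.
#' @export
write_amplicons <- function(amplicons, path) {
  readr::write_tsv(amplicons[, c("chrom", "start", "end", "amplicon_id")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

new_tissue_counts <- function(df, tissue_label) {
  df <- tibble::as_tibble(df)
  attr(df, "tissue_label") <- tissue_label
  class(df) <- c("tissue_counts", class(df))
  df
}

#' @export
print.tissue_counts <- function(x, ...) {
  cat(sprintf("<tissue_counts: %s, %d records, %d sites>\n",
              tissue_label(x), nrow(x), length(unique(site_key(x)))))
  NextMethod()
}

#' Tissue label of a count table
#' @param x A `tissue_counts` table.
#' @return The tissue label string.
#' @export
tissue_label <- function(x) attr(x, "tissue_label")

#' Read a per-amplicon allele-count table for one tissue
#'
#' The table is tab-separated with a header line
#' `chrom pos ref alt amplicon_id ref_reads alt_reads` (positions 1-based).
#' Every row's site must fall inside the named amplicon's interval.
#'
#' @param path Path to the count TSV.
#' @param amplicon_defs Path to the amplicon BED file, or a tibble already read
#'   with [read_amplicons()].
#' @param tissue_label Tissue label, e.g. `"ENCC"` or `"blood"`.
#' @return A `tissue_counts` tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `amplicon_id`, `ref_reads`, `alt_reads`.
#' @export
read_count_table <- function(path, amplicon_defs, tissue_label = "tissue") {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  amps <- if (is.character(amplicon_defs)) read_amplicons(amplicon_defs) else amplicon_defs
  # suppressed: readr warns when a declared column is absent; the explicit
  # format error below names the missing column instead
  df <- suppressWarnings(readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          pos = readr::col_integer(),
                          ref = readr::col_character(),
                          alt = readr::col_character(),
                          amplicon_id = readr::col_character(),
                          ref_reads = readr::col_integer(),
                          alt_reads = readr::col_integer()
                        )))
  need <- c(site_cols, "amplicon_id", "ref_reads", "alt_reads")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("count table format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_count_table(df, amps)
  new_tissue_counts(df, tissue_label)
}

validate_count_table <- function(df, amps) {
  validate_sites(df, "count table")
  bad <- which(df$ref_reads < 0L | df$alt_reads < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("count table: negative read count at row %d", bad[1]),
         call. = FALSE)
  }
  key <- paste(site_key(df), df$amplicon_id)
  if (anyDuplicated(key) > 0L) {
    stop(sprintf("count table: duplicate (site, amplicon) at row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  idx <- match(df$amplicon_id, amps$amplicon_id)
  if (anyNA(idx)) {
    stop(sprintf("count table: unknown amplicon_id at row %d",
                 which(is.na(idx))[1]), call. = FALSE)
  }
  # BED half-open [start, end) in 0-based; a 1-based pos lies inside iff
  # start < pos <= end.
  inside <- df$chrom == amps$chrom[idx] &
    df$pos > amps$start[idx] & df$pos <= amps$end[idx]
  if (any(!inside)) {
    stop(sprintf("count table: site outside its amplicon at row %d",
                 which(!inside)[1]), call. = FALSE)
  }
  invisible(df)
}

#' Write a tissue count table
#'
#' @param counts A `tissue_counts` tibble.
#' @param path Output path (TSV with header).
#' @export
write_count_table <- function(counts, path) {
  cols <- c(site_cols, "amplicon_id", "ref_reads", "alt_reads")
  readr::write_tsv(tibble::as_tibble(counts)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Pair two tissue count tables site by site
#'
#' Produces one record per genomic site present in either table. A site absent
#' from one tissue gets zero coverage and an undefined (NA) VAF there; the
#' coverage mask downstream handles it. Output is ordered by (chrom, pos).
#'
#' @param a,b `tissue_counts` tables with distinct tissue labels.
#' @return A `paired_counts` tibble with per-site pooled coverage, alt totals,
#'   VAFs and per-amplicon alt/coverage list-columns for each tissue.
#' @export
pair_tables <- function(a, b) {
  la <- tissue_label(a); lb <- tissue_label(b)
  if (identical(la, lb)) {
    stop("pair_tables: the two tables carry the same tissue label '",
         la, "'", call. = FALSE)
  }
  per_site <- function(df) {
    tibble::as_tibble(df) |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(
        coverage = sum(.data$ref_reads + .data$alt_reads),
        alt_total = sum(.data$alt_reads),
        amp_alt = list(setNames(.data$alt_reads, .data$amplicon_id)),
        amp_cov = list(setNames(.data$ref_reads + .data$alt_reads,
                                .data$amplicon_id)),
        .groups = "drop"
      )
  }
  sa <- per_site(a)
  sb <- per_site(b)
  out <- dplyr::full_join(sa, sb, by = site_cols, suffix = c("_a", "_b"))
  zero_fill <- function(cov, alt, amp_alt, amp_cov) {
    miss <- is.na(cov)
    cov[miss] <- 0L
    alt[miss] <- 0L
    amp_alt[miss] <- list(setNames(integer(0), character(0)))
    amp_cov[miss] <- list(setNames(integer(0), character(0)))
    list(cov = cov, alt = alt, amp_alt = amp_alt, amp_cov = amp_cov)
  }
  fa <- zero_fill(out$coverage_a, out$alt_total_a, out$amp_alt_a, out$amp_cov_a)
  fb <- zero_fill(out$coverage_b, out$alt_total_b, out$amp_alt_b, out$amp_cov_b)
  out$coverage_a <- fa$cov; out$alt_total_a <- fa$alt
  out$amp_alt_a <- fa$amp_alt; out$amp_cov_a <- fa$amp_cov
  out$coverage_b <- fb$cov; out$alt_total_b <- fb$alt
  out$amp_alt_b <- fb$amp_alt; out$amp_cov_b <- fb$amp_cov
  out$vaf_a <- ifelse(out$coverage_a > 0, out$alt_total_a / out$coverage_a, NA_real_)
  out$vaf_b <- ifelse(out$coverage_b > 0, out$alt_total_b / out$coverage_b, NA_real_)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  attr(out, "tissue_a") <- la
  attr(out, "tissue_b") <- lb
  class(out) <- c("paired_counts", class(out))
  out
}

#' Write somatic calls as VCF 4.2
#'
#' One record per call. INFO carries the classification, per-tissue pooled VAF
#' and depth, and the per-amplicon alt-read counts; the header documents every
#' key.
#'
#' @param calls A calls tibble as returned by [call_pairs()].
#' @param path Output path.
#' @param tissue_a,tissue_b Tissue labels written into the header (defaults
#'   taken from the calls' attributes when present).
#' @export
write_calls_vcf <- function(calls, path,
                            tissue_a = attr(calls, "tissue_a") %||% "A",
                            tissue_b = attr(calls, "tissue_b") %||% "B") {
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 6))
  fmt_amp <- function(lst) {
    vapply(lst, function(v) {
      if (length(v) == 0L) "." else paste(sprintf("%s|%d", names(v), v), collapse = ",")
    }, character(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=enccmosaic",
    sprintf("##enccmosaic_tissue_a=%s", tissue_a),
    sprintf("##enccmosaic_tissue_b=%s", tissue_b),
    '##INFO=<ID=CLS,Number=1,Type=String,Description="Somatic classification: encc_only, germline_only, shared, masked_low_coverage or no_variant">',
    '##INFO=<ID=VAFA,Number=1,Type=Float,Description="Pooled variant allele fraction in tissue A">',
    '##INFO=<ID=VAFB,Number=1,Type=Float,Description="Pooled variant allele fraction in tissue B">',
    '##INFO=<ID=DPA,Number=1,Type=Integer,Description="Pooled read depth in tissue A">',
    '##INFO=<ID=DPB,Number=1,Type=Integer,Description="Pooled read depth in tissue B">',
    '##INFO=<ID=SAA,Number=1,Type=Integer,Description="Supporting amplicons (alt reads >= per-amplicon minimum) in tissue A">',
    '##INFO=<ID=SAB,Number=1,Type=Integer,Description="Supporting amplicons in tissue B">',
    '##INFO=<ID=AMPA,Number=1,Type=String,Description="Per-amplicon alt counts in tissue A as id|count,...">',
    '##INFO=<ID=AMPB,Number=1,Type=String,Description="Per-amplicon alt counts in tissue B as id|count,...">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- header
  if (nrow(calls) > 0L) {
    info <- sprintf(
      "CLS=%s;VAFA=%s;VAFB=%s;DPA=%d;DPB=%d;SAA=%d;SAB=%d;AMPA=%s;AMPB=%s",
      calls$classification,
      fmt_num(calls$vaf_a), fmt_num(calls$vaf_b),
      calls$coverage_a, calls$coverage_b,
      calls$supporting_amplicons_a, calls$supporting_amplicons_b,
      fmt_amp(calls$amp_alt_a), fmt_amp(calls$amp_alt_b)
    )
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                              calls$chrom, calls$pos, calls$ref, calls$alt, info))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("write_calls_vcf: cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
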