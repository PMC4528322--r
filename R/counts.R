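#' Read a long-format allele-count table
#'
#' One row per (transcript, SNP, family, library, parental allele): the
#' number of uniquely mapped reads supporting that allele in that library.
#'
#' @param path Tab-delimited file with header columns `transcript_id`,
#'   `chrom`, `pos`, `family`, `replicate_id`, `sample_group`, `parent`,
#'   `lineage`, `count`.
#' @return A validated tibble of allele-count records (see
#'   [validate_counts()]).
#' @export
read_allele_counts <- function(path) {
  rec <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    family = readr::col_character(),
    replicate_id = readr::col_character(),
    sample_group = readr::col_character(),
    parent = readr::col_character(),
    lineage = readr::col_character(),
    count = readr::col_double()
  ))
  validate_counts(rec)
}

#' Validate allele-count records
#'
#' Checks controlled vocabularies, non-negative integer counts, uniqueness
#' of (transcript, SNP, family, library, parent), and the design identity
#' linking family, parent and lineage (in family AE the maternal allele is
#' Africanized; in EA it is European). Rows whose lineage contradicts that
#' mapping are rejected and reported (with row numbers) in the `"dropped"`
#' attribute. If an informative-SNP table is supplied, rows at SNPs absent
#' from it are rejected too.
#'
#' @param records Allele-count tibble (columns as in [read_allele_counts()]).
#' @param snps Optional informative-SNP table ([select_informative_snps()]).
#' @return The retained records; rejected rows in `attr(, "dropped")`.
#' @export
validate_counts <- function(records, snps = NULL) {
  assert_cols(records, c("transcript_id", "chrom", "pos", "family", "replicate_id",
                         "sample_group", "parent", "lineage", "count"), "`records`")
  records <- tibble::as_tibble(records)
  assert_tokens(records$family, .families, "family")
  assert_tokens(records$sample_group, .sample_groups, "sample_group")
  assert_tokens(records$parent, .parents, "parent")
  assert_tokens(records$lineage, .lineages, "lineage")
  if (any(is.na(records$count)) || any(records$count < 0)) {
    abort("counts must be non-negative and non-missing")
  }
  if (any(records$count != floor(records$count))) {
    abort("counts must be integers (read counts)")
  }
  key <- paste(records$transcript_id, records$chrom, records$pos,
               records$family, records$replicate_id, records$parent)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated (transcript, snp, family, replicate, parent) record(s), e.g. row %d",
                  which(duplicated(key))[1]))
  }

  reason <- rep(NA_character_, nrow(records))
  bad_lin <- lineage_of(records$family, records$parent) != records$lineage
  reason[bad_lin] <- "lineage_inconsistent_with_family_parent"
  if (!is.null(snps)) {
    snp_key <- paste(snps$family, snps$chrom, snps$pos)
    unknown <- is.na(reason) & !paste(records$family, records$chrom, records$pos) %in% snp_key
    reason[unknown] <- "snp_not_informative"
  }
  dropped <- records[!is.na(reason), , drop = FALSE]
  if (nrow(dropped) > 0) {
    dropped$row <- which(!is.na(reason))
    dropped$reason <- reason[!is.na(reason)]
    inform(sprintf("validate_counts: rejected %d row(s): %s",
                   nrow(dropped), paste(head(dropped$row, 5), collapse = ", ")))
  }
  out <- records[is.na(reason), , drop = FALSE]
  attr(out, "dropped") <- tibble::as_tibble(dropped)
  out
}

#' Filter allele counts for coverage and design support
#'
#' Two passes, mirroring per-SNP coverage filtering followed by
#' per-transcript testability requirements:
#' 1. drop every (SNP, library) cell whose maternal + paternal total is
#'    below `min_total_per_snp_library`;
#' 2. within each sample group, drop transcripts with fewer than
#'    `min_snps_per_transcript` surviving SNPs or represented in fewer than
#'    `min_libraries_per_family` libraries in either family.
#'
#' @param records Validated allele-count tibble.
#' @param min_total_per_snp_library Minimum maternal + paternal reads per
#'   SNP per library (default 10).
#' @param min_snps_per_transcript Minimum surviving SNPs per transcript per
#'   sample group (default 1).
#' @param min_libraries_per_family Minimum libraries per family in which a
#'   transcript retains counts (default 2).
#' @return The retained records, with a [filter_report()] attribute that
#'   reconciles input = retained + dropped.
#' @export
filter_counts <- function(records,
                          min_total_per_snp_library = 10,
                          min_snps_per_transcript = 1,
                          min_libraries_per_family = 2) {
  if (min_total_per_snp_library < 0 || min_snps_per_transcript < 0 ||
      min_libraries_per_family < 0) {
    abort("filter thresholds must be non-negative")
  }
  n_input <- nrow(records)
  cells <- records |>
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$pos,
                    .data$family, .data$replicate_id, .data$sample_group) |>
    dplyr::mutate(.cell_total = sum(.data$count)) |>
    dplyr::ungroup()
  keep_cov <- cells$.cell_total >= min_total_per_snp_library
  n_low <- sum(!keep_cov)
  surv <- cells[keep_cov, , drop = FALSE]
  surv$.cell_total <- NULL

  support <- surv |>
    dplyr::group_by(.data$transcript_id, .data$sample_group) |>
    dplyr::summarise(
      n_snps = dplyr::n_distinct(paste(.data$chrom, .data$pos)),
      n_lib_AE = dplyr::n_distinct(.data$replicate_id[.data$family == "AE"]),
      n_lib_EA = dplyr::n_distinct(.data$replicate_id[.data$family == "EA"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(testable = .data$n_snps >= min_snps_per_transcript &
                    .data$n_lib_AE >= min_libraries_per_family &
                    .data$n_lib_EA >= min_libraries_per_family)
  ok <- dplyr::filter(support, .data$testable)
  keep_support <- paste(surv$transcript_id, surv$sample_group) %in%
    paste(ok$transcript_id, ok$sample_group)
  out <- surv[keep_support, , drop = FALSE]
  n_few <- sum(!keep_support)

  tested <- ok |>
    dplyr::count(.data$sample_group, name = "n_transcripts_tested")
  report <- list(
    n_input_records = n_input,
    n_dropped_low_coverage = n_low,
    n_dropped_few_snps = n_few,
    n_retained_records = nrow(out),
    n_transcripts_tested = setNames(tested$n_transcripts_tested, tested$sample_group),
    thresholds = c(min_total_per_snp_library = min_total_per_snp_library,
                   min_snps_per_transcript = min_snps_per_transcript,
                   min_libraries_per_family = min_libraries_per_family)
  )
  stopifnot(report$n_input_records ==
              report$n_retained_records + report$n_dropped_low_coverage +
              report$n_dropped_few_snps)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report attached by [filter_counts()]
#'
#' @param records Tibble returned by [filter_counts()].
#' @return A list with record counts per filtering stage and the number of
#'   transcripts tested per sample group.
#' @export
filter_report <- function(records) {
  attr(records, "filter_report") %||% list()
}

#' Per-transcript, per-family maternal and Africanized read ratios
#'
#' For each transcript and sample group, pools raw counts over SNPs and
#' replicates within each family and computes the maternal read fraction
#' `R_f = sum(maternal) / sum(total)` and the Africanized-lineage fraction
#' `Q_f`. Pooling raw counts (rather than averaging per-SNP ratios) weights
#' each SNP by its coverage; per-SNP averaging is available via
#' `method = "mean_of_ratios"`.
#'
#' @param records Filtered allele-count tibble.
#' @param method `"pooled"` (default) or `"mean_of_ratios"`.
#' @return One row per (transcript_id, sample_group) with `R_AE`, `R_EA`,
#'   `Q_AE`, `Q_EA` in `[0, 1]` (NA when a family has zero total, which
#'   makes the transcript untestable for rules requiring that family).
#' @export
family_ratios <- function(records, method = c("pooled", "mean_of_ratios")) {
  method <- match.arg(method)
  assert_cols(records, c("transcript_id", "sample_group", "family", "parent",
                         "lineage", "count"), "`records`")
  if (method == "pooled") {
    per_fam <- records |>
      dplyr::group_by(.data$transcript_id, .data$sample_group, .data$family) |>
      dplyr::summarise(
        maternal = sum(.data$count[.data$parent == "maternal"]),
        africanized = sum(.data$count[.data$lineage == "Africanized"]),
        total = sum(.data$count),
        .groups = "drop"
      ) |>
      dplyr::mutate(R = ifelse(.data$total > 0, .data$maternal / .data$total, NA_real_),
                    Q = ifelse(.data$total > 0, .data$africanized / .data$total, NA_real_))
  } else {
    per_fam <- records |>
      dplyr::group_by(.data$transcript_id, .data$sample_group, .data$family,
                      .data$chrom, .data$pos, .data$replicate_id) |>
      dplyr::summarise(
        r = sum(.data$count[.data$parent == "maternal"]) / sum(.data$count),
        q = sum(.data$count[.data$lineage == "Africanized"]) / sum(.data$count),
        .groups = "drop"
      ) |>
      dplyr::group_by(.data$transcript_id, .data$sample_group, .data$family) |>
      dplyr::summarise(R = mean(.data$r, na.rm = TRUE), Q = mean(.data$q, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(R = ifelse(is.nan(.data$R), NA_real_, .data$R),
                    Q = ifelse(is.nan(.data$Q), NA_real_, .data$Q))
  }
  out <- per_fam |>
    dplyr::select("transcript_id", "sample_group", "family", "R", "Q") |>
    tidyr::pivot_wider(names_from = "family", values_from = c("R", "Q"),
                       names_sep = "_")
  for (col in c("R_AE", "R_EA", "Q_AE", "Q_EA")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  dplyr::select(out, "transcript_id", "sample_group", "R_AE", "R_EA", "Q_AE", "Q_EA")
}

#' Write allele-count records to TSV
#'
#' @param records Allele-count tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_allele_counts <- function(records, path) {
  readr::write_tsv(
    dplyr::select(records, "transcript_id", "chrom", "pos", "family",
                  "replicate_id", "sample_group", "parent", "lineage", "count"),
    path)
  invisible(records)
}
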