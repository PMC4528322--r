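#' Run the full reciprocal-cross analysis
#'
#' Orchestrates the pipeline on a validated allele-count table: coverage
#' and support filtering, per-family read ratios, per-transcript mixed
#' models, Benjamini-Hochberg correction within each sample group and
#' term, bias classification, per-group tallies, Storer-Kim comparison of
#' maternal- vs paternal-biased counts, and pairwise hypergeometric list
#' overlap across sample groups.
#'
#' The run is deterministic: every stage is a pure function of the inputs
#' and thresholds, so re-running with the same arguments reproduces the
#' result (and any files written) byte for byte.
#'
#' @param counts Allele-count tibble (long format; see
#'   [read_allele_counts()]).
#' @param snps Optional informative-SNP table for record validation.
#' @param out_dir Optional directory; when given, per-group fit TSVs, the
#'   calls TSV and a `summary.json` (tallies, enrichment p-values, the full
#'   configuration and its hash) are written there.
#' @param min_total_per_snp_library,min_snps_per_transcript,min_libraries_per_family
#'   Filter thresholds; see [filter_counts()].
#' @param ratio_threshold,q_threshold Classification thresholds; see
#'   [call_bias()].
#' @param response Model response scale; see [build_design()].
#' @param ratio_method Ratio pooling; see [family_ratios()].
#' @return A `psge_result` list: `fits`, `ratios`, `calls`, `summary`,
#'   `storer_kim` (per-group maternal vs paternal p), `overlaps`
#'   (parent-biased and lineage-biased pairwise overlap tables),
#'   `filter_report`, `config`.
#' @export
run_psge <- function(counts, snps = NULL, out_dir = NULL,
                     min_total_per_snp_library = 10,
                     min_snps_per_transcript = 1,
                     min_libraries_per_family = 2,
                     ratio_threshold = 0.6, q_threshold = 0.05,
                     response = c("log2", "raw"),
                     ratio_method = c("pooled", "mean_of_ratios")) {
  response <- match.arg(response)
  ratio_method <- match.arg(ratio_method)
  config <- list(
    min_total_per_snp_library = min_total_per_snp_library,
    min_snps_per_transcript = min_snps_per_transcript,
    min_libraries_per_family = min_libraries_per_family,
    ratio_threshold = ratio_threshold, q_threshold = q_threshold,
    response = response, ratio_method = ratio_method
  )
  config$hash <- rlang::hash(config)

  counts <- validate_counts(counts, snps = snps)
  filtered <- filter_counts(counts,
                            min_total_per_snp_library = min_total_per_snp_library,
                            min_snps_per_transcript = min_snps_per_transcript,
                            min_libraries_per_family = min_libraries_per_family)
  freport <- filter_report(filtered)

  empty_result <- function() {
    structure(list(
      fits = fit_psge(filtered[0, ]), ratios = family_ratios(filtered[0, ]),
      calls = tibble::tibble(), summary = summarize_calls(tibble::tibble()),
      storer_kim = tibble::tibble(sample_group = character(), n_maternal = integer(),
                                  n_paternal = integer(), n_tested = integer(),
                                  p_value = double()),
      overlaps = list(), filter_report = freport, config = config
    ), class = "psge_result")
  }
  if (nrow(filtered) == 0) {
    inform("run_psge: no testable transcripts after filtering")
    res <- empty_result()
    if (!is.null(out_dir)) write_result(res, out_dir)
    return(res)
  }

  ratios <- family_ratios(filtered, method = ratio_method)
  fits <- fit_psge(filtered, response = response) |> adjust_fdr()
  calls <- call_bias(fits, ratios, ratio_threshold = ratio_threshold,
                     q_threshold = q_threshold)
  summary <- summarize_calls(calls)

  storer_kim <- summary |>
    dplyr::rowwise() |>
    dplyr::mutate(p_value = storer_kim_test(.data$n_maternal, .data$n_tested,
                                            .data$n_paternal, .data$n_tested)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_group", "n_maternal", "n_paternal", "n_tested", "p_value")

  universes <- split(calls$transcript_id, calls$sample_group)
  parent_lists <- split(calls$transcript_id[calls$maternal_psge | calls$paternal_psge],
                        calls$sample_group[calls$maternal_psge | calls$paternal_psge])
  lineage_lists <- split(calls$transcript_id[calls$lineage_A | calls$lineage_E],
                         calls$sample_group[calls$lineage_A | calls$lineage_E])
  pad <- function(lists) {
    out <- setNames(vector("list", length(universes)), names(universes))
    for (g in names(universes)) out[[g]] <- lists[[g]] %||% character()
    out
  }
  overlaps <- list(parent = overlap_matrix(pad(parent_lists), universes),
                   lineage = overlap_matrix(pad(lineage_lists), universes))

  res <- structure(list(
    fits = fits, ratios = ratios, calls = calls, summary = summary,
    storer_kim = storer_kim, overlaps = overlaps,
    filter_report = freport, config = config
  ), class = "psge_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

#' Write a `psge_result` to disk
#'
#' Writes per-group fit tables, the calls table and `summary.json`
#' (tallies, enrichment statistics, filter report, configuration and its
#' hash). Every file is a pure function of the result, so identical runs
#' produce identical files.
#'
#' @param result A `psge_result` from [run_psge()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "psge_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(result$fits) > 0) write_fits(result$fits, dir)
  readr::write_tsv(if (nrow(result$calls) > 0) result$calls else
                     tibble::tibble(transcript_id = character()),
                   file.path(dir, "calls.tsv"))
  payload <- list(
    config = result$config,
    filter_report = result$filter_report,
    summary = result$summary,
    storer_kim = result$storer_kim,
    overlap_parent = result$overlaps$parent %||% list(),
    overlap_lineage = result$overlaps$lineage %||% list()
  )
  jsonlite::write_json(payload, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.psge_result <- function(x, ...) {
  cat("<psge_result>\n")
  cat(sprintf("  %d fit(s) across %d sample group(s); config hash %s\n",
              nrow(x$fits), dplyr::n_distinct(x$fits$sample_group), x$config$hash))
  print(x$summary)
  invisible(x)
}

#' Human-readable run report
#'
#' @param result A `psge_result` from [run_psge()].
#' @return A list of tibbles: `tallies` (per-group counts with the
#'   Storer-Kim maternal-vs-paternal p-value) and `ratio_matrix` (one row
#'   per transcript, maternal read fraction per family and sample group,
#'   for flagged transcripts).
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "psge_result"))
  tallies <- result$summary |>
    dplyr::left_join(dplyr::select(result$storer_kim, "sample_group",
                                   storer_kim_p = "p_value"),
                     by = "sample_group")
  flagged <- if (nrow(result$calls) == 0) result$calls else
    dplyr::filter(result$calls,
                  .data$maternal_psge | .data$paternal_psge | .data$lineage_A |
                    .data$lineage_E | .data$asym_maternal_AE | .data$asym_maternal_EA)
  ratio_matrix <- if (nrow(flagged) == 0) tibble::tibble() else
    flagged |>
      dplyr::select("transcript_id", "sample_group", "R_AE", "R_EA") |>
      tidyr::pivot_wider(names_from = "sample_group",
                         values_from = c("R_AE", "R_EA"), names_sep = ".")
  list(tallies = tallies, ratio_matrix = ratio_matrix)
}
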