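#' Parent-of-origin bias calls from q-values and family ratios
#'
#' A transcript is called maternally biased when the parent term is
#' significant after FDR correction and the maternal read fraction exceeds
#' the ratio threshold in *both* crosses (same direction in each);
#' paternally biased when the fraction is below `1 - threshold` in both.
#' A transcript untestable in either family receives no call: the rule
#' requires both crosses.
#'
#' @param q_P FDR-adjusted p-values for the parent-of-origin term.
#' @param R_AE,R_EA Maternal read fraction per family (NA if untestable).
#' @param ratio_threshold Direction-consistency threshold (default 0.6).
#' @param q_threshold False-discovery threshold (default 0.05).
#' @return Character vector: `"maternal"`, `"paternal"` or `NA` (no call).
#' @export
call_parent_bias <- function(q_P, R_AE, R_EA, ratio_threshold = 0.6,
                             q_threshold = 0.05) {
  sig <- !is.na(q_P) & q_P < q_threshold
  both <- !is.na(R_AE) & !is.na(R_EA)
  maternal <- sig & both & pmin(R_AE, R_EA) > ratio_threshold
  paternal <- sig & both & pmax(R_AE, R_EA) < 1 - ratio_threshold
  dplyr::case_when(maternal ~ "maternal", paternal ~ "paternal",
                   TRUE ~ NA_character_)
}

#' Lineage-of-origin bias calls
#'
#' Mirrors [call_parent_bias()] with the Africanized read fraction: a
#' transcript is Africanized-biased when the lineage term is significant
#' and the Africanized fraction exceeds the threshold in both crosses,
#' European-biased when it is below `1 - threshold` in both.
#'
#' @param q_L FDR-adjusted p-values for the lineage-of-origin term.
#' @param Q_AE,Q_EA Africanized read fraction per family.
#' @inheritParams call_parent_bias
#' @return Character vector: `"Africanized"`, `"European"` or `NA`.
#' @export
call_lineage_bias <- function(q_L, Q_AE, Q_EA, ratio_threshold = 0.6,
                              q_threshold = 0.05) {
  sig <- !is.na(q_L) & q_L < q_threshold
  both <- !is.na(Q_AE) & !is.na(Q_EA)
  afr <- sig & both & pmin(Q_AE, Q_EA) > ratio_threshold
  eur <- sig & both & pmax(Q_AE, Q_EA) < 1 - ratio_threshold
  dplyr::case_when(afr ~ "Africanized", eur ~ "European", TRUE ~ NA_character_)
}

#' Maternal bias in only one of the reciprocal crosses
#'
#' Flags transcripts significant for the parent-by-lineage interaction term
#' whose maternal read fraction exceeds the threshold in exactly one cross.
#' When the fraction exceeds the threshold in both crosses the transcript
#' belongs to the both-cross parent-of-origin list instead and is not
#' flagged here, so the two asymmetric flags are mutually exclusive with
#' each other and with the both-cross case.
#'
#' @param q_PL FDR-adjusted p-values for the interaction term.
#' @inheritParams call_parent_bias
#' @return Character vector: `"AE"`, `"EA"` (the cross showing the maternal
#'   bias) or `NA`.
#' @export
call_asymmetric_maternal <- function(q_PL, R_AE, R_EA, ratio_threshold = 0.6,
                                     q_threshold = 0.05) {
  sig <- !is.na(q_PL) & q_PL < q_threshold
  in_AE <- !is.na(R_AE) & R_AE > ratio_threshold
  in_EA <- !is.na(R_EA) & R_EA > ratio_threshold
  dplyr::case_when(sig & in_AE & !in_EA ~ "AE",
                   sig & in_EA & !in_AE ~ "EA",
                   TRUE ~ NA_character_)
}

#' Classify every tested transcript
#'
#' Joins model q-values with family ratios and applies the three list
#' rules: both-cross parent-of-origin bias, both-cross lineage bias, and
#' interaction-driven maternal bias in a single cross. A transcript may
#' carry a parent flag and a lineage flag simultaneously; the asymmetric
#' flags are suppressed when the both-cross maternal rule already applies.
#'
#' @param fits Tibble from [fit_psge()] + [adjust_fdr()].
#' @param ratios Tibble from [family_ratios()].
#' @inheritParams call_parent_bias
#' @return One row per (transcript, sample group) with logical flag columns
#'   `maternal_psge`, `paternal_psge`, `lineage_A`, `lineage_E`,
#'   `asym_maternal_AE`, `asym_maternal_EA`, the supporting ratios and
#'   q-values.
#' @export
call_bias <- function(fits, ratios, ratio_threshold = 0.6, q_threshold = 0.05) {
  calls <- dplyr::inner_join(fits, ratios,
                             by = c("transcript_id", "sample_group")) |>
    dplyr::mutate(
      parent_call = call_parent_bias(.data$q_P, .data$R_AE, .data$R_EA,
                                     ratio_threshold, q_threshold),
      lineage_call = call_lineage_bias(.data$q_L, .data$Q_AE, .data$Q_EA,
                                       ratio_threshold, q_threshold),
      asym_call = call_asymmetric_maternal(.data$q_PL, .data$R_AE, .data$R_EA,
                                           ratio_threshold, q_threshold),
      maternal_psge = !is.na(.data$parent_call) & .data$parent_call == "maternal",
      paternal_psge = !is.na(.data$parent_call) & .data$parent_call == "paternal",
      lineage_A = !is.na(.data$lineage_call) & .data$lineage_call == "Africanized",
      lineage_E = !is.na(.data$lineage_call) & .data$lineage_call == "European",
      asym_maternal_AE = !is.na(.data$asym_call) & .data$asym_call == "AE",
      asym_maternal_EA = !is.na(.data$asym_call) & .data$asym_call == "EA"
    ) |>
    dplyr::select("transcript_id", "sample_group", "n_snps",
                  "maternal_psge", "paternal_psge", "lineage_A", "lineage_E",
                  "asym_maternal_AE", "asym_maternal_EA",
                  "R_AE", "R_EA", "Q_AE", "Q_EA", "q_P", "q_L", "q_PL")
  stopifnot(!any(calls$maternal_psge & calls$paternal_psge),
            !any(calls$lineage_A & calls$lineage_E),
            !any(calls$asym_maternal_AE & calls$asym_maternal_EA))
  calls
}

#' Per-group tallies of bias calls
#'
#' @param calls Tibble from [call_bias()].
#' @return One row per sample group with counts of each flag, the number of
#'   tested transcripts and the number of SNPs behind those tests.
#' @export
summarize_calls <- function(calls) {
  base <- tibble::tibble(sample_group = character(), n_tested = integer(),
                         n_snps = integer(), n_maternal = integer(),
                         n_paternal = integer(), n_lineage_A = integer(),
                         n_lineage_E = integer(), n_asym_AE = integer(),
                         n_asym_EA = integer())
  if (nrow(calls) == 0) return(base)
  calls |>
    dplyr::group_by(.data$sample_group) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_snps = sum(.data$n_snps),
      n_maternal = sum(.data$maternal_psge),
      n_paternal = sum(.data$paternal_psge),
      n_lineage_A = sum(.data$lineage_A),
      n_lineage_E = sum(.data$lineage_E),
      n_asym_AE = sum(.data$asym_maternal_AE),
      n_asym_EA = sum(.data$asym_maternal_EA),
      .groups = "drop"
    )
}
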