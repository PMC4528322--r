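# single mutually-exclusive label per call, for plotting
call_category <- function(calls) {
  dplyr::case_when(
    calls$maternal_psge ~ "maternal",
    calls$paternal_psge ~ "paternal",
    calls$asym_maternal_AE ~ "asym maternal (AE)",
    calls$asym_maternal_EA ~ "asym maternal (EA)",
    calls$lineage_A ~ "lineage (Africanized)",
    calls$lineage_E ~ "lineage (European)",
    TRUE ~ "none"
  )
}

#' Maternal read fraction in one cross against the other
#'
#' Each point is a tested transcript; the dashed lines mark the
#' direction-consistency threshold in each family. Transcripts with a
#' parent-of-origin bias sit in the upper-right (maternal) or lower-left
#' (paternal) corner; asymmetric maternal transcripts hug one axis.
#'
#' @param calls Tibble from [call_bias()].
#' @param ratio_threshold Threshold drawn as guide lines (default 0.6).
#' @return A ggplot object, faceted by sample group.
#' @export
plot_ratio_scatter <- function(calls, ratio_threshold = 0.6) {
  df <- dplyr::mutate(calls, category = call_category(calls))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R_AE, y = .data$R_EA,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_hline(yintercept = c(ratio_threshold, 1 - ratio_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(ratio_threshold, 1 - ratio_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~sample_group) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "maternal read fraction, family AE",
                  y = "maternal read fraction, family EA",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Counts of biased transcripts per sample group
#'
#' @param calls Tibble from [call_bias()].
#' @return A ggplot bar chart of flag counts per sample group.
#' @export
plot_call_counts <- function(calls) {
  long <- summarize_calls(calls) |>
    tidyr::pivot_longer(
      cols = c("n_maternal", "n_paternal", "n_lineage_A", "n_lineage_E",
               "n_asym_AE", "n_asym_EA"),
      names_to = "flag", values_to = "n") |>
    dplyr::mutate(flag = sub("^n_", "", .data$flag))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$flag, y = .data$n,
                                     fill = .data$flag)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~sample_group) +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pipeline results
#'
#' @param object A `psge_result` from [run_psge()].
#' @param ... Passed to [plot_ratio_scatter()].
#' @return A ggplot object.
#' @export
autoplot.psge_result <- function(object, ...) {
  plot_ratio_scatter(object$calls, ...)
}
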