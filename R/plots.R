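#' Plot a recurrence matrix as a presence/frequency heatmap
#'
#' Tiles are colored by log10 frequency of each query CDR3 sequence in
#' each sample's repertoire; absent combinations are left blank. Samples
#' are ordered by group so patient and control columns read side by side.
#'
#' @param object A `tcrgd_recurrence` tibble from
#'   [build_recurrence_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcrgd_recurrence
#' @export
autoplot.tcrgd_recurrence <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(
      sample_id = factor(.data$sample_id,
                         levels = unique(.data$sample_id[order(.data$group)])),
      log_freq = ifelse(.data$frequency > 0, log10(.data$frequency), NA)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$cdr3_aa,
                                   fill = .data$log_freq)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "log10 frequency") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot combinatorial V-(D)-J usage of major clonotypes
#'
#' Bar chart of major-clonotype counts per gene combination, one facet per
#' chain.
#'
#' @param usage Output of [compute_vdj_usage()].
#' @return A ggplot object.
#' @export
plot_vdj_usage <- function(usage) {
  df <- usage %>%
    dplyr::mutate(combination = ifelse(
      is.na(.data$d_call) | .data$d_call == "none",
      paste(.data$v_call, .data$j_call, sep = "-"),
      paste(.data$v_call, .data$d_call, .data$j_call, sep = "-")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$combination, .data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~chain, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Major clonotype entries") +
    ggplot2::theme_minimal()
}

#' Plot VAF against clone fraction with concordance labels
#'
#' Scatter of observed variant allele fraction versus the flow-determined
#' T gamma/delta clone fraction; the heterozygous (VAF = clone fraction /
#' 2) and homozygous (VAF = clone fraction) expectations are drawn as
#' reference lines.
#'
#' @param concordance Output of [concordance_call()].
#' @return A ggplot object.
#' @export
plot_vaf_concordance <- function(concordance) {
  ggplot2::ggplot(concordance,
                  ggplot2::aes(x = .data$clone_fraction, y = .data$vaf,
                               colour = .data$concordance)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = 0.5, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Clone fraction (Tgd % of PBMC)",
                  y = "Variant allele fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
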