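CLASS_COLOURS <- c(abolished = "#b2182b", decreased = "#ef8a62",
                   increased = "#2166ac", unchanged = "grey60",
                   undetermined = "grey85")

#' Scatter plot of wild-type vs mutant editing efficiencies
#'
#' One point per site, coloured by differential class; the diagonal band
#' marks changes smaller than the alteration threshold.
#'
#' @param records differential tibble from [compare_editing()].
#' @param alter_threshold band half-width in percentage points.
#' @return a ggplot object.
#' @export
plot_editing_comparison <- function(records, alter_threshold = 10) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$eff_wt, y = .data$eff_mut,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = c(-alter_threshold,
                                                  alter_threshold),
                         linetype = "dashed", colour = "grey70") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = CLASS_COLOURS, drop = TRUE) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "wild-type editing (%)", y = "mutant editing (%)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Bar plot of the percentage of altered sites per transcript
#'
#' @param summary tibble from [summarize_transcripts()]; transcripts with
#'   no altered site are dropped.
#' @return a ggplot object.
#' @export
plot_transcript_summary <- function(summary) {
  d <- dplyr::filter(summary, .data$n_altered > 0) |>
    dplyr::arrange(dplyr::desc(.data$pct_altered))
  d$gene_id <- factor(d$gene_id, levels = d$gene_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id, y = .data$pct_altered)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "altered editing sites per transcript (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
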