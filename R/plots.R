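#' Histogram of pairwise Ks values
#'
#' Peaks in the paralog Ks distribution mark bursts of duplication
#' (paleopolyploidies); vertical lines can be added for calibration
#' intervals.
#'
#' @param pairs Tibble with a Ks column (infinite/undefined values are
#'   dropped).
#' @param value Name of the Ks column (default `"dS"`).
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot.
#' @export
plot_ks_distribution <- function(pairs, value = "dS", binwidth = 0.05) {
  df <- tibble(ks = pairs[[value]])
  df <- filter(df, is.finite(.data$ks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = "Ks", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Block median-Ks plot
#'
#' One point per collinear block, grouped by species pair, with assigned
#' events mapped to colour - the within-genome analogue of a block
#' median-Ks range figure.
#'
#' @param block_stats Result of [block_median_ks()], optionally with an
#'   `event` column.
#' @return A ggplot.
#' @export
plot_block_median_ks <- function(block_stats) {
  df <- block_stats |>
    mutate(pair = paste(.data$species_a, .data$species_b, sep = " / "))
  if (!"event" %in% names(df)) df$event <- NA_character_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$median_ks,
                                   colour = .data$event)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::labs(x = NULL, y = "block median Ks", colour = "event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
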