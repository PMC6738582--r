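# ggplot2 displays for the main result types.

#' Stacked-bar plot of an abundance matrix
#'
#' One bar per sample, stacked by taxon, mirroring the standard phylum- or
#' family-level composition overview of a cohort.
#'
#' @param object An `abundance_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_matrix <- function(object, ...) {
  long <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "taxon",
                        values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "relative abundance (%)",
                  fill = attr(object, "rank") %||% "taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-cycle quality plot of a FASTQ file
#'
#' @param stats A `qc_stats` object from [read_stats()].
#' @param floor Positional quality floor to draw (default 20).
#' @return A ggplot object.
#' @export
plot_positional_quality <- function(stats, floor = 20) {
  df <- tibble::tibble(cycle = seq_along(stats$per_position_mean_quality),
                       mean_quality = stats$per_position_mean_quality)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle,
                                   y = .data$mean_quality)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = floor, linetype = "dashed") +
    ggplot2::labs(x = "cycle", y = "mean Phred quality") +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation matrix
#'
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  long <- tidy.correlation_matrix(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature,
                                     y = .data$organism_id,
                                     fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = "feature", y = "organism", fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
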