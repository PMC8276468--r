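#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile coord_flip
#'   labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot an abundance table as a ranked bar chart
#'
#' @param object An `abund_table` from [summarize_abundance()].
#' @param top_n Show only the `top_n` most abundant taxa (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abund_table <- function(object, top_n = 30, ...) {
  df <- rank_abundance_report(object, top_n)
  ggplot(df, aes(x = stats::reorder(.data$taxon, .data$rel_abundance),
                 y = .data$rel_abundance)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = "Relative abundance (%)",
         title = sprintf("Dominant groups at %s rank (top %d)",
                         attr(object, "rank"), min(top_n, nrow(object)))) +
    theme_minimal()
}

#' Heat-map of pathway module completeness across genomes
#'
#' @param completeness Long completeness tibble from [pathway_completeness()]
#'   or [tidy()] on a `trait_profiles` object.
#' @return A ggplot object.
#' @export
plot_trait_heatmap <- function(completeness) {
  ggplot(completeness,
         aes(x = .data$pathway, y = .data$genome_id,
             fill = .data$completeness)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 100), name = "Module\ncompleteness (%)") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a virus-host association network as a weighted incidence grid
#'
#' @param object A `vh_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vh_network <- function(object, ...) {
  ggplot(object$edges,
         aes(x = .data$host_class, y = .data$virus_family,
             fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c(name = "Virus-host\npairs") +
    labs(x = "Host class", y = "Virus family") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
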