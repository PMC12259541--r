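# ggplot2 views of the main result types. These are plain data plots; the
# publication-style tree/raincloud/pie renderings are out of scope.

#' Heat-map view of an interaction matrix
#'
#' Tile plot of the parasite-genus x host-family presence matrix, columns in
#' phylogenetic tip order, rows grouped by parasite family.
#'
#' @param object a `host_interaction_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.host_interaction_matrix <- function(object, ...) {
  long <- tidy(object)
  long$host_family <- factor(long$host_family, levels = colnames(object))
  long$parasite_genus <- factor(long$parasite_genus,
                                levels = rev(rownames(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$host_family,
                                     y = .data$parasite_genus)) +
    ggplot2::geom_tile(fill = "goldenrod") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$parasite_family),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "host family (phylogenetic order)",
                  y = "parasite genus") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Host-specificity distributions by lineage
#'
#' Jittered points of per-parasite host counts at a chosen rank, grouped by
#' parasite lineage, with the lineage median marked.
#'
#' @param profiles a profile tibble ([specificity_profiles()]).
#' @param rank one of `"species"`, `"genera"`, `"families"`.
#' @return a ggplot object.
#' @export
plot_specificity <- function(profiles, rank = c("species", "genera",
                                                "families")) {
  rank <- match.arg(rank)
  col <- paste0("n_host_", rank)
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data[[col]],
                                         y = .data$parasite_family)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.5) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.6,
                          colour = "firebrick") +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = paste("host", rank, "per parasite species"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Host-habit composition
#'
#' @param habits a [habit_summary()] tibble.
#' @return a ggplot bar chart of host proportions per habit class.
#' @export
plot_habits <- function(habits) {
  ggplot2::ggplot(habits,
                  ggplot2::aes(x = stats::reorder(.data$host_habit,
                                                  .data$prop_hosts),
                               y = .data$prop_hosts)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of hosts") +
    ggplot2::theme_minimal()
}
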