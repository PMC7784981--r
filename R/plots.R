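#' Plot an enrichment result
#'
#' Score-versus-rank plot of the enrichment records, coloured by associated
#' group set, with the q < 0.05 records emphasised.
#'
#' @param object A `panphen_enrichment` object.
#' @param q_cutoff Significance threshold drawn on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot panphen_enrichment
#' @export
autoplot.panphen_enrichment <- function(object, q_cutoff = 0.05, ...) {
  rec <- object$records
  rec$rank <- seq_len(nrow(rec))
  rec$significant <- rec$q_value < q_cutoff
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$associated_groups,
                                     alpha = .data$significant)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "rank", y = "enrichment score",
                  colour = "associated groups",
                  title = "Function enrichment across phenotype groups") +
    ggplot2::theme_minimal()
}

#' Plot a topology-screen result
#'
#' Bar chart of matched-constraint counts, split by whether the tree is
#' fully resolved (under-resolved trees match permissively).
#'
#' @param object A `panphen_screen` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot panphen_screen
#' @export
autoplot.panphen_screen <- function(object, ...) {
  res <- object$results
  res$resolution <- ifelse(
    res$n_internal_edges >= res$n_leaves - 3, "resolved", "polytomous")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$matched,
                                    fill = .data$resolution)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "matched constraint", y = "gene clusters",
                  title = "Gene-tree constraint screen") +
    ggplot2::theme_minimal()
}

#' Plot passage series
#'
#' Density (with the host-alone control) and parasite score over passages,
#' faceted by strain and dose — the standard growth/crash/recovery view.
#'
#' @param df Passage tibble including `dose == 0` control rows.
#' @return A ggplot.
#' @export
plot_passage_series <- function(df) {
  withctl <- attach_controls(df)
  long <- tidyr::pivot_longer(
    withctl, c("density", "control_density", "parasite_score"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$passage, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$strain + .data$dose,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "passage", y = NULL,
                  title = "Serial-passage growth and parasite score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
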