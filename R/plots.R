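#' Plot methods for emnet results
#'
#' ggplot2 `autoplot()` methods: response-ratio forest plots, Zi-Pi role
#' scatter, alpha-diversity boxplots by forest type, and PLS-PM path
#' coefficient charts.
#'
#' @param object An emnet result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name emnet-autoplot
NULL

#' @rdname emnet-autoplot
#' @export
autoplot.emnet_rr <- function(object, ...) {
  stopifnot(all(c("variable", "treat") %in% names(object)))
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$percent_change, y = .data$variable
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = (exp(.data$ci_lo) - 1) * 100,
      xmax = (exp(.data$ci_hi) - 1) * 100
    ), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$treat)) +
    ggplot2::labs(x = "Change vs control (%)", y = NULL,
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @rdname emnet-autoplot
#' @export
autoplot.emnet_roles <- function(object, ...) {
  zi_cut <- attr(object, "zi_cut") %||% 2.5
  pi_cut <- attr(object, "pi_cut") %||% 0.62
  ggplot2::ggplot(object, ggplot2::aes(.data$pi, .data$zi,
                                       colour = .data$role)) +
    ggplot2::geom_vline(xintercept = pi_cut, linetype = 2) +
    ggplot2::geom_hline(yintercept = zi_cut, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module connectivity (Zi)",
                  colour = "Role") +
    ggplot2::theme_minimal()
}

#' @rdname emnet-autoplot
#' @param meta Optional metadata with `sample` and `forest_type` for
#'   grouping.
#' @export
autoplot.emnet_alpha <- function(object, meta = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("richness", "shannon", "simpson", "chao1", "ace"),
    names_to = "index", values_to = "value"
  )
  if (!is.null(meta)) {
    long <- dplyr::inner_join(long, meta[c("sample", "forest_type")],
                              by = "sample")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$forest_type, .data$value,
                                            fill = .data$forest_type)) +
      ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE)
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$value)) +
      ggplot2::geom_col() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname emnet-autoplot
#' @export
autoplot.emnet_plspm <- function(object, ...) {
  paths <- dplyr::mutate(object$paths,
                         label = paste(.data$from, "→", .data$to))
  p <- ggplot2::ggplot(paths, ggplot2::aes(.data$estimate, .data$label,
                                           fill = .data$estimate > 0))
  if ("ci_lo" %in% names(paths)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    )
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_col(width = 0.6, alpha = 0.8, show.legend = FALSE) +
    ggplot2::labs(
      x = "Path coefficient", y = NULL,
      subtitle = sprintf("GoF = %.3f", object$gof)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plots of diversity metrics against plant richness
#'
#' Log-log scatter of one EM diversity metric against neighboring plant
#' richness, with the overall and per-forest-type OLS fits.
#'
#' @param div Tibble with `sample` and metric columns.
#' @param meta Metadata with `sample`, `forest_type`, `plant_richness`.
#' @param metric Metric column to plot.
#' @param log_y Log-transform the response axis (only for positive
#'   metrics).
#' @return A ggplot object.
#' @export
plot_diversity_regression <- function(div, meta, metric, log_y = TRUE) {
  dat <- dplyr::inner_join(div, meta[c("sample", "forest_type",
                                       "plant_richness")], by = "sample")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$plant_richness,
                                         .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$forest_type)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::geom_smooth(ggplot2::aes(colour = .data$forest_type),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Neighboring plant richness", y = metric,
                  colour = "Forest type") +
    ggplot2::theme_minimal()
  if (log_y && all(dat[[metric]] > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
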