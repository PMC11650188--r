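# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.ge_curve <- function(object, ...) {
  means <- object |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(ge = mean(.data$ge), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$ge)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = means, linewidth = 0.8, colour = "steelblue") +
    ggplot2::geom_point(data = means, size = 2, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "k_best"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "number of factors K",
                  y = "generalizability error",
                  title = "Split-half generalizability error") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.factor_model <- function(object, ...) {
  tidy(object, "loadings") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region, y = .data$factor,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, title = "Factor loadings") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.subtype_model <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$s, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$s, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "number of subtypes", y = "BIC",
                  title = "Subtype count selection") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$region, .data$t),
                               y = .data$t,
                               fill = .data$p_fdr < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = NULL, y = "t statistic (patients - controls)",
                  title = "Group difference map") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.epicenter_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f, y = .data$d,
                                       colour = .data$likelihood)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "epicenter\nlikelihood") +
    ggplot2::labs(x = "regional factor value F",
                  y = "neighbor statistic D",
                  title = "Epicenter likelihood") +
    ggplot2::theme_minimal()
}
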