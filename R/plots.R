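#' Plot a degree-to-clustering hierarchy curve
#'
#' Bars show each degree bin's mean clustering normalised by the global
#' mean; values below 1 at high degrees indicate hierarchical organisation.
#'
#' @param object A [hierarchy_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hierarchy_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$mean_clustering_norm)) +
    ggplot2::geom_col(width = diff(c(df$bin_lo[1], df$bin_hi[1])) * 0.9,
                      fill = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "degree", y = "mean clustering / global mean",
                  subtitle = sprintf("Spearman rho(degree, clustering) = %.3f",
                                     object$spearman_rho)) +
    ggplot2::theme_minimal()
}

#' Plot a core-size decay profile
#'
#' Core size as a function of the peeling threshold (degree for k-cores,
#' strength for s-cores); the right end of the staircase is the innermost
#' core.
#'
#' @param object A [core_decomposition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.core_decomposition <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$threshold, y = .data$size)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = if (object$kind == "s_core") "strength threshold s"
                  else "degree threshold k",
                  y = "core size") +
    ggplot2::theme_minimal()
}

#' Plot a weighted rich-club density profile
#'
#' @param object A [weighted_rich_club()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rich_club <- function(object, ...) {
  df <- object$profile[object$profile$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$phi_w)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "degree threshold k",
                  y = expression(phi^w * "(k)")) +
    ggplot2::theme_minimal()
}

#' Bar summary of an analysis report
#'
#' One panel per metric: the source network's value as a horizontal line
#' and each surrogate ensemble's mean as a bar with a standard-deviation
#' whisker and its star annotation.
#'
#' @param object A `wirecost_report` from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wirecost_report <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$surrogate_type,
                                   y = .data$ensemble_mean,
                                   fill = .data$surrogate_type)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ensemble_mean - .data$ensemble_sd,
                                        ymax = .data$ensemble_mean + .data$ensemble_sd),
                           width = 0.25) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$source_value),
                        linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = 0,
                       nudge_y = 0) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "value (source dashed, ensembles as bars)") +
    ggplot2::theme_minimal()
}
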