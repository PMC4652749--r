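#' Plot methods for pipeline result objects
#'
#' `autoplot()` methods return ggplot objects: TSS-anchored metagene lines
#' per group, per-position correlation curves for sense and antisense
#' transcription, enrichment tables as ranked -log10 p points, turnover
#' quartile boxes per class and nucleosome index, and sense-versus-antisense
#' change scatterplots.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a `ggplot`.
#' @name antisensr-plots
NULL

#' @rdname antisensr-plots
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean signal", colour = "group") +
    ggplot2::theme_minimal()
}

#' @rdname antisensr-plots
#' @method autoplot correlation_profile
#' @export
autoplot.correlation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$rho,
                                       colour = .data$target)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(sense = "firebrick",
                                            antisense = "steelblue")) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "Spearman r_s with window counts") +
    ggplot2::theme_minimal()
}

#' @rdname antisensr-plots
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(factor = factor(.data$factor, levels = rev(.data$factor)))
  ggplot2::ggplot(utils::head(d, 30L),
                  ggplot2::aes(x = -log10(.data$p_value), y = .data$factor,
                               colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "-log10 p (Wilcoxon rank-sum)", y = NULL,
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' @rdname antisensr-plots
#' @method autoplot turnover_distributions
#' @export
autoplot.turnover_distributions <- function(object, ...) {
  d <- object$summary |> mutate(class = factor(.data$class))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$index), fill = .data$class)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$q1, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$q3),
      stat = "identity", position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "nucleosome index", y = "histone turnover rate",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' @rdname antisensr-plots
#' @method autoplot shift_scatter
#' @export
autoplot.shift_scatter <- function(object, ...) {
  r <- object$correlation
  ggplot2::ggplot(object$deltas,
                  ggplot2::aes(x = .data$d_antisense, y = .data$d_sense)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::labs(
      x = "change in antisense reads (mutant - wild-type)",
      y = "change in sense reads",
      subtitle = sprintf("Spearman r_s = %s (n = %d)",
                         if (r$defined) sprintf("%.2f", r$rho) else "undefined",
                         r$n)) +
    ggplot2::theme_minimal()
}

#' @rdname antisensr-plots
#' @method autoplot difference_profile
#' @export
autoplot.difference_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = .data$difference,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mutant - wild-type mean signal", colour = "shift group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
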