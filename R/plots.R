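#' Plot replicate phenotype values with compact letter labels
#'
#' Column-and-jitter view of per-allele replicate values, annotated with
#' the letter groups: alleles sharing a letter are statistically
#' indistinguishable at the grouping's alpha.
#'
#' @param data Replicate tibble with `allele` (or the grouping column used)
#'   and `value`.
#' @param grouping A `letter_grouping` from [pairwise_letter_groups()].
#' @param value,group Column names in `data`.
#' @return A ggplot object.
#' @export
plot_letter_groups <- function(data, grouping, value = "value",
                               group = "allele") {
  d <- tibble::tibble(group = data[[group]], value = data[[value]])
  lab <- tibble::tibble(group = grouping$group, letters = grouping$letters,
                        mean = grouping$mean)
  ymax <- max(d$value)
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey75",
                          width = 0.7) +
    ggplot2::geom_jitter(width = 0.08, size = 1) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = group, y = ymax * 1.08,
                                    label = letters),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "value",
                  subtitle = sprintf(
                    "letters: pairwise t-tests at p < %g", attr(grouping, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Plot an allele count table as within-group proportions
#'
#' Stacked-proportion view of a `count_table`: each bar is an isolate
#' group, filled by allele share.
#'
#' @param counts A `count_table`.
#' @return A ggplot object.
#' @export
plot_allele_distribution <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = group, y = count, fill = allele)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of isolates", fill = "allele") +
    ggplot2::theme_minimal()
}

#' @rdname slope_ci_association
#' @param object A `slope_ci` result.
#' @param ... Unused.
#' @export
autoplot.slope_ci <- function(object, ...) {
  fit <- attr(object, "fit")
  d <- tibble::tibble(x = fit$model$x, y = fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         level = attr(object, "conf"), colour = "firebrick",
                         linewidth = 0.6) +
    ggplot2::labs(subtitle = sprintf(
      "slope %.3g [%.3g, %.3g]; %s",
      object$slope, object$ci_lower, object$ci_upper,
      if (object$significant) "significant" else "not significant")) +
    ggplot2::theme_minimal()
}
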