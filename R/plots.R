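#' Accumulation plot of per-site repeat lengths or densities
#'
#' Draws the non-increasing step curves produced by
#' [accumulation_curve()], one per site set.
#'
#' @param ... Named numeric vectors of per-site values (one per site set),
#'   or a single named list of them.
#' @param xlab X-axis label.
#' @return A ggplot.
#' @export
plot_accumulation <- function(..., xlab = "threshold") {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  labels <- names(sets) %||% paste0("set", seq_along(sets))
  thresholds <- sort(unique(c(0, unlist(sets))))
  d <- purrr::map2_dfr(sets, labels, function(v, l) {
    out <- accumulation_curve(v, thresholds)
    out$set <- l
    out
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$fraction,
                                  colour = .data$set)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = xlab, y = "fraction of sites ≥ threshold",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of per-site strand-bias log2 ratios
#'
#' Mirrors the frequency distribution used to define one-ended breaks:
#' vertical lines mark the +/- threshold on |log2(plus/minus)|.
#'
#' @param bias Output of [bias_distribution()], or a site tibble already
#'   carrying a `log2_ratio` column.
#' @param bias_threshold_log2 Threshold drawn as vertical lines.
#' @param binwidth Histogram bin width.
#' @return A ggplot.
#' @export
plot_bias_distribution <- function(bias, bias_threshold_log2 = 1.5,
                                   binwidth = 0.25) {
  d <- if (is.data.frame(bias)) {
    tibble(log2_ratio = bias$log2_ratio[is.finite(bias$log2_ratio)])
  } else bias$ratios
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * bias_threshold_log2,
                        colour = "blue", linetype = 2) +
    ggplot2::labs(x = "log2(plus / minus) tag counts", y = "sites") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' @param object An `intersection_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of null overlap counts with the observed
#'   count marked.
#' @method autoplot intersection_result
#' @export
autoplot.intersection_result <- function(object, ...) {
  d <- tibble(null = object$null_counts)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "null overlap count",
                  subtitle = sprintf("observed %d, p = %.4g",
                                     object$observed, object$p_value),
                  y = "trials") +
    ggplot2::theme_minimal()
}

#' Per-type recall of a recovery result
#'
#' @param object A `recovery_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of recall by planted site type.
#' @method autoplot recovery_result
#' @export
autoplot.recovery_result <- function(object, ...) {
  ggplot2::ggplot(object$recall_by_type,
                  ggplot2::aes(x = .data$type, y = .data$recall)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "recall",
                  subtitle = sprintf("precision %.3f", object$precision)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
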