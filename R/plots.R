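# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
NULL

#' Plot a biomarker-response curve
#'
#' Displays the point response rate `pi(B)` and the subset response rate
#' `Pi(B)` over the quantile range, optionally with the reference rate.
#'
#' @param object A [logistic_curve()].
#' @param rho Optional reference rate drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbatt_curve <- function(object, rho = NULL, ...) {
  b <- seq(0, 1, by = 0.005)
  df <- tibble::tibble(
    quantile = rep(b, 2),
    rate = c(response_rate(object, b), subset_rate(object, b)),
    which = rep(c("pi(B): point rate", "Pi(B): subset rate"), each = length(b))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$quantile, .data$rate,
                                        colour = .data$which)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "biomarker quantile B", y = "response rate",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(rho)) {
    p <- p + ggplot2::geom_hline(yintercept = rho, linetype = "dashed")
  }
  p
}

#' Plot a predicted-power curve
#'
#' Predicted power against candidate stage-2 threshold, with the target
#' power line.
#'
#' @param object A [predicted_power_curve()] tibble.
#' @param target_power Optional target power line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbatt_power_curve <- function(object, target_power = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "candidate stage-2 threshold",
                  y = "predicted power") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(target_power)) {
    p <- p + ggplot2::geom_hline(yintercept = target_power,
                                 linetype = "dashed")
  }
  p
}

#' Plot simulated operating characteristics
#'
#' Histogram of the chosen stage-2 thresholds among completed trials,
#' facetted by final significance.
#'
#' @param object A [simulate_oc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbatt_oc <- function(object, ...) {
  df <- dplyr::filter(object$trials, !.data$stopped_at_interim)
  ggplot2::ggplot(df, ggplot2::aes(.data$chosen_t2,
                                   fill = .data$significant)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            position = "stack") +
    ggplot2::labs(x = "chosen stage-2 threshold t2", y = "trials",
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Boxplot of threshold-estimate bias across designs
#'
#' Compares the distribution of `T_hat - T` from several simulation
#' batches, in the style of design-comparison bias plots.
#'
#' @param ocs Named list of [simulate_oc()] results on scenarios with a
#'   defined true threshold.
#' @return A ggplot.
#' @export
plot_bias <- function(ocs) {
  df <- purrr::imap_dfr(ocs, function(oc, nm) {
    tibble::tibble(design = nm,
                   bias = oc$trials$t_hat - oc$scenario$true_threshold)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$design, .data$bias)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "bias in threshold estimate") +
    ggplot2::theme_minimal()
}
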