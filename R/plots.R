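#' Forest plot of DIF estimates and confidence intervals
#'
#' Plots per-item DIF estimates with their bootstrap confidence intervals,
#' colouring items detected by the Benjamini-Hochberg procedure.
#'
#' @param object A `dif_inference` tibble from [dif_infer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dif_inference <- function(object, ...) {
  df <- dplyr::mutate(object,
                      item = factor(.data$item, levels = rev(.data$item)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma_hat, y = .data$item,
                                   colour = .data$bh_reject)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.25) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "detected") +
    ggplot2::labs(x = "DIF effect (log odds ratio)", y = NULL,
                  title = "Anchor-free DIF inference",
                  subtitle = sprintf("%g%% intervals, B-H at alpha = %g",
                                     100 * attr(object, "level"),
                                     attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Averaged ROC curves of a simulation study
#'
#' @param object A `dif_study` from [run_study()] that includes P-value
#'   based methods.
#' @param ... Unused.
#' @return A ggplot object (one panel per setting).
#' @export
autoplot.dif_study <- function(object, ...) {
  if (is.null(object$roc)) abort("The study has no ROC curves to plot.")
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~setting) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "Averaged ROC curves") +
    ggplot2::theme_minimal()
}

#' Plot the L1 profile of a DIF configuration
#'
#' Visualises `h(c) = sum_j |gamma_j - a_j c|` over a range of location
#' shifts, marking the weighted-median minimizer. Useful for checking
#' whether a configuration satisfies the minimal-L1 condition (minimum at
#' `c = 0`).
#'
#' @inheritParams l1_profile
#' @param from,to Range of shifts; defaults bracket the ratio points.
#' @return A ggplot object.
#' @export
plot_l1_profile <- function(gamma, a, from = NULL, to = NULL) {
  r <- gamma[a != 0] / a[a != 0]
  from <- from %||% (min(r) - 1)
  to <- to %||% (max(r) + 1)
  cs <- seq(from, to, length.out = 400)
  cstar <- ml1_shift(gamma, a)
  df <- tibble::tibble(c = cs, h = l1_profile(gamma, a, cs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cstar, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "location shift c", y = "h(c)",
                  subtitle = sprintf("minimizer c* = %.4g", cstar)) +
    ggplot2::theme_minimal()
}
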