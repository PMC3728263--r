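# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential expression result
#'
#' @param x A `mirdisc_de` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.mirdisc_de <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a differential expression result
#'
#' @param x A `mirdisc_de` object.
#' @param alpha Significance level on the adjusted p-value.
#' @param ... Unused.
#' @return Tibble with the tested tissue, number of miRNAs tested and
#'   significant, test method and common dispersion.
#' @export
glance.mirdisc_de <- function(x, alpha = 0.05, ...) {
  tibble(tissue = x$tissue[1], n_tested = nrow(x),
         n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
         method = attr(x, "method"), dispersion = attr(x, "dispersion"))
}

#' Tidy a calibration result
#'
#' @param x A `mirdisc_calibration` object.
#' @param ... Unused.
#' @return The cutoff/SNR table.
#' @export
tidy.mirdisc_calibration <- function(x, ...) {
  x$table
}

#' One-row summary of a calibration result
#'
#' @param x A `mirdisc_calibration` object.
#' @param ... Unused.
#' @return Tibble with cutoff, SNR at the cutoff, target and rounds.
#' @export
glance.mirdisc_calibration <- function(x, ...) {
  tibble(cutoff = x$cutoff, snr_at_cutoff = x$snr_at_cutoff,
         target_snr = x$target_snr, n_rounds = x$n_rounds,
         reached_target = !x$warning)
}

#' Plot the signal-to-noise calibration curve
#'
#' SNR against score cutoff, with the target ratio and the chosen cutoff
#' marked.
#'
#' @param object A `mirdisc_calibration` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirdisc_calibration <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$cutoff, y = .data$snr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target_snr, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 3,
                        colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score cutoff", y = "signal-to-noise ratio",
                  title = sprintf("Cutoff %.2f at SNR %.1f (target %d:1)",
                                  object$cutoff, object$snr_at_cutoff,
                                  object$target_snr)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a one-versus-rest test
#'
#' @param object A `mirdisc_de` object.
#' @param alpha Significance level on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirdisc_de <- function(object, alpha = 0.05, ...) {
  d <- tidy(object) |>
    filter(!.data$fc_infinite) |>
    mutate(significant = .data$p_adj < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_adj),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 fold change (rest / tissue)",
                  y = "-log10 adjusted p",
                  title = paste("One-vs-rest:", object$tissue[1])) +
    ggplot2::theme_minimal()
}
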