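#' Plot sorted p-values against their ranks
#'
#' The Schweder--Spjotvoll diagnostic: one panel per design, one curve per
#' test, with the uniform diagonal as reference. Curves above the diagonal
#' indicate supra-uniform p-values (expected under monotone homogeneity with
#' informative items); curves hugging or below it indicate uniform or
#' anti-conservative behaviour.
#'
#' @param object An `acarp_pvalues` tibble from [pvalue_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acarp_pvalues
#' @export
autoplot.acarp_pvalues <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$p,
                                       colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$uniform_ref),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::facet_wrap(~design, scales = "free_x") +
    ggplot2::labs(x = "rank of p-value", y = "p-value", colour = "test") +
    ggplot2::theme_minimal()
}

#' Plot a rejection-rate grid
#'
#' Tile plot of rejection proportions, tests by designs, with the rates
#' printed in the cells.
#'
#' @param object An `acarp_rejection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acarp_rejection
#' @export
autoplot.acarp_rejection <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$design, y = .data$test,
                               fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rejection\nrate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot pairwise statistics
#'
#' Bar plot of the pairwise Z statistics (or MCCs) in canonical pair order,
#' coloured by sign; negative bars are the pairs carrying evidence against
#' monotone homogeneity.
#'
#' @param object An `acarp_pairstats` tibble.
#' @param kind `"z"` or `"mcc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acarp_pairstats
#' @export
autoplot.acarp_pairstats <- function(object, kind = c("z", "mcc"), ...) {
  kind <- match.arg(kind)
  df <- tidy(object)
  df$value <- df[[kind]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   fill = .data$value < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "pair index k", y = kind) +
    ggplot2::theme_minimal()
}
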