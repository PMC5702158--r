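#' Plot a signature evaluation against its null distributions
#'
#' Histograms of the random-signature and shuffled-dose null R-squared
#' distributions with the observed signature R-squared as a vertical line.
#'
#' @param object A `signature_eval` from [evaluate_signature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$r2, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::facet_wrap(~ .data$null, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = expression(R^2 ~ "on IWPC residual dose"), y = "count",
      title = sprintf("%s on %s", object$signature_label, object$cohort),
      subtitle = sprintf("observed R^2 = %.3f; p = %.3g (random), %.3g (shuffled)",
                         object$r2, object$p_random, object$p_shuffled)) +
    ggplot2::theme_minimal()
}

#' Plot stability-selection frequencies
#'
#' Selection frequency of every gene-tissue pair over the stability repeats,
#' with the strict-majority threshold marked; selected pairs are highlighted.
#'
#' @param object A `dose_signature` from [stability_select()].
#' @param top Show only the `top` most frequently selected pairs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_signature <- function(object, top = 30, ...) {
  df <- tidy(object) |>
    dplyr::arrange(dplyr::desc(.data$selection_freq)) |>
    head(top) |>
    dplyr::mutate(pair = factor(feature_key(.data$gene_id, .data$tissue),
                                levels = rev(feature_key(.data$gene_id,
                                                         .data$tissue))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selection_freq, y = .data$pair,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey75"),
                               name = "in signature") +
    ggplot2::labs(x = sprintf("selection frequency (%d repeats)",
                              object$repeats),
                  y = NULL) +
    ggplot2::theme_minimal()
}
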