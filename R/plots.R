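## ggplot2 views of the main result types.

#' Plot per-topic heritability enrichments
#'
#' Point estimates with approximate 95% intervals (`e_hat` +/- 1.96 `se`)
#' and the shrunken posterior means; excluded topics are greyed out.
#'
#' @param object A `scads_enrichment` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scads_enrichment
#' @export
autoplot.scads_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topic)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$e_hat,
                                          ymin = .data$e_hat - 1.96 * .data$se,
                                          ymax = .data$e_hat + 1.96 * .data$se,
                                          colour = .data$excluded)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$e_post), shape = 4,
                        size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "grey70")) +
    ggplot2::labs(y = "heritability enrichment",
                  x = NULL,
                  caption = "crosses: shrunken posterior means") +
    ggplot2::theme_minimal()
}

#' Plot per-cell disease scores
#'
#' Cells ranked by score, coloured by BH significance; non-significant
#' cells in grey.
#'
#' @param object A `scads_cell_scores` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scads_cell_scores
#' @export
autoplot.scads_cell_scores <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$score), ]
  df <- df[order(df$score), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "cells (ranked)", y = "disease-relevance score") +
    ggplot2::theme_minimal()
}

#' Plot the EM log-likelihood trace of a topic fit
#'
#' @param fit A `scads_topic_fit`.
#' @return A ggplot object.
#' @export
plot_loglik_trace <- function(fit) {
  df <- tibble(iteration = seq_along(fit$loglik_trace),
               loglik = fit$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "Poisson log-likelihood") +
    ggplot2::theme_minimal()
}
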