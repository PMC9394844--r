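## ggplot2 displays for boards, move distributions, Pareto fronts and the
## trade-off phase space.

#' Plot a board
#'
#' @param object A `kboard`.
#' @param probs Optional move-distribution or move-probability tibble
#'   (`row`, `col`, `prob`) overlaid as a fill.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kboard <- function(object, probs = NULL, ...) {
  g <- .board_geom(object)
  df <- tibble::tibble(row = g$rows, col = g$cols,
                       mark = c("", "X", "O")[object$marks + 1L])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row))
  if (!is.null(probs))
    p <- p + ggplot2::geom_tile(data = probs,
                                ggplot2::aes(fill = .data$prob)) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue")
  p +
    ggplot2::geom_tile(fill = NA, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 6) +
    ggplot2::scale_y_reverse(breaks = seq_len(object$size),
                             labels = object$size - seq_len(object$size) + 1L) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$size),
                                labels = letters[seq_len(object$size)],
                                position = "top") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Pareto analysis
#'
#' Accuracy against computation per shutter size, with 95% bootstrap CI bars
#' and the Pareto-front members highlighted.
#'
#' @param object A `pareto_result` from [pareto_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pareto_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$computation, y = .data$accuracy,
                                    colour = factor(.data$shutter))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$acc_low,
                                        ymax = .data$acc_high), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$comp_low,
                                         xmax = .data$comp_high), height = 0) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$on_front), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "computation (score evaluations)",
                  y = "P(found winning move)",
                  colour = "shutter", shape = "on Pareto front",
                  subtitle = if (object$trade_off)
                    "trade-off between shutter sizes" else
                    "no trade-off: one shutter dominates") +
    ggplot2::theme_minimal()
}

#' Plot a trade-off phase space
#'
#' Proportion of configurations with an accuracy/computation trade-off per
#' (board-complexity bin, noise level) cell.
#'
#' @param object A `phase_space` tibble from [phase_space()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_space <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$complexity_bin),
                                       y = factor(.data$sigma),
                                       fill = .data$prop_tradeoff)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$prop_tradeoff))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "board complexity bin (low to high)",
                  y = "score noise sigma",
                  fill = "P(trade-off)") +
    ggplot2::theme_minimal()
}
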