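#' Plot the group SL-score series with its fitted exponential curve
#'
#' Gray dots are the per-block group SL scores; the solid line is the fitted
#' exponential curve, the dashed horizontal line its saturation level A, and
#' the marked point the (x0 + tau, 0.632 * A) location where the curve
#' reaches 1 - 1/e of its amplitude.
#'
#' @param group_scores Tibble with `block` and `score` (see
#'   [group_sl_scores()]).
#' @param fit Exponential fit: an `lc_fit` or any list with `w1`, `w2`, `w3`.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(group_scores, fit) {
  stopifnot(all(c("block", "score") %in% names(group_scores)))
  A <- fit$w1; x0 <- fit$w2; tau <- fit$w3
  grid <- tibble::tibble(
    block = seq(min(group_scores$block), max(group_scores$block),
                length.out = 200)
  )
  grid$score <- lc_predict("exponential", c(A, x0, tau), grid$block)
  marker <- tibble::tibble(block = x0 + tau, score = A * (1 - exp(-1)))

  ggplot2::ggplot(group_scores, ggplot2::aes(x = .data$block, y = .data$score)) +
    ggplot2::geom_point(colour = "grey55") +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::geom_hline(yintercept = A, linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(data = marker, colour = "red", shape = 8, size = 3) +
    ggplot2::labs(
      x = "Block order",
      y = "SL score",
      title = "Group statistical-learning curve",
      subtitle = sprintf("A = %.2f, x0 = %.2f, tau = %.2f (63.2%% of A at block %.1f)",
                         A, x0, tau, x0 + tau)
    ) +
    ggplot2::theme_minimal()
}
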