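# ggplot2 views of the result objects.

#' Predicted-vs-measured scatter for an evaluation
#'
#' @param object An `abddg_eval` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abddg_eval
#' @export
autoplot.abddg_eval <- function(object, ...) {
  df <- object$predictions
  lab <- sprintf("Pearson r = %.2f, RMSE = %.2f kcal/mol",
                 object$pooled$pearson, object$pooled$rmse)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_true, y = .data$ddg_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::labs(
      x = expression(paste("measured ", Delta * Delta * G, " (kcal/mol)")),
      y = expression(paste("predicted ", Delta * Delta * G, " (kcal/mol)")),
      subtitle = lab,
      title = sprintf("Out-of-fold predictions (%s)", object$scheme)
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative class-pair counts of a signature
#'
#' @param sig A [csm_signature()] tibble.
#' @return A ggplot (tile heatmap, class pair x bin edge).
#' @export
plot_signature <- function(sig) {
  sig$pair <- paste(sig$class_a, sig$class_b, sep = ":")
  ggplot2::ggplot(sig, ggplot2::aes(x = factor(.data$edge), y = .data$pair,
                                    fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance bin upper edge (Å)", y = "pharmacophore pair",
                  fill = "cumulative\npairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Ranked design-scan candidates
#'
#' @param designs The list returned by [rank_designs()].
#' @param which `"increasing"` or `"decreasing"`.
#' @return A ggplot (rank vs predicted ddG).
#' @export
plot_designs <- function(designs, which = c("increasing", "decreasing")) {
  which <- match.arg(which)
  df <- designs[[which]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ddg_pred)) +
    ggplot2::geom_col(width = 0.8, fill = if (which == "increasing") "#2c7fb8" else "#d95f0e") +
    ggplot2::labs(x = "rank", y = expression(paste("predicted ", Delta * Delta * G, " (kcal/mol)")),
                  title = sprintf("Top %s-affinity designs", which)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
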