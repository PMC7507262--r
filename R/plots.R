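#' Plot screening scores against rank
#'
#' @param object A `screening_scores` tibble.
#' @param top_k Optional number of leading features to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screening_scores
#' @export
autoplot.screening_scores <- function(object, top_k = NULL, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$rank)
  df$highlight <- if (is.null(top_k)) FALSE else df$rank <= top_k
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$omega)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 0.8,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(
      x = "rank",
      y = if (identical(attr(object, "method"), "pcc")) "|Pearson correlation|"
          else expression(hat(omega)[k]),
      title = sprintf("Marginal screening scores (%s)", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot cross-validated predictions against observations
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot of averaged out-of-fold predictions vs observed
#'   responses with the identity line.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(
      title = sprintf("%s, d = %d: %d-fold CV x %d", object$method, object$d,
                      object$folds, object$repeats),
      subtitle = sprintf("PCC = %.3f, MSE = %.3f", object$pcc, object$mse),
      x = "observed response", y = "out-of-fold prediction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the d-tuning curve
#'
#' @param object A `d_selection`.
#' @param ... Unused.
#' @return A ggplot of cross-validated PCC against the number of selected
#'   features, with the chosen d marked.
#' @method autoplot d_selection
#' @export
autoplot.d_selection <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$d, y = .data$pcc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_d, linetype = 2,
                        colour = "red") +
    ggplot2::labs(
      title = sprintf("Choice of d (%s): best d = %d", object$method,
                      object$best_d),
      x = "number of selected features d", y = "cross-validated PCC"
    ) +
    ggplot2::theme_minimal()
}
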