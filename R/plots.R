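#' Plot the annual moult index
#'
#' Yearly normalised moult index (points) with a loess smooth, echoing the
#' usual presentation of a slow multi-decadal trend.
#'
#' @param object A `moult_index` from [annual_moult_index()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moult_index
#' @export
autoplot.moult_index <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$index)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Year", y = "Moult index (min-max normalised)") +
    ggplot2::theme_minimal()
}

#' Plot an AICc candidate comparison
#'
#' @param object A `model_selection` from [select_model()].
#' @param ... Unused.
#' @return A ggplot object: candidates ordered by ΔAICc, the selection
#'   threshold as a dashed line.
#' @method autoplot model_selection
#' @export
autoplot.model_selection <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- stats::reorder(d$label, d$delta_aicc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$delta_aicc,
                                  fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(Delta * "AICc")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot a single-predictor PGLS fit
#'
#' Species-level scatter with the GLS regression line; only defined for
#' fits with one predictor besides the intercept.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  mf <- object$model_frame
  if (ncol(mf) != 2) {
    rlang::abort("autoplot.pgls_fit is defined for single-predictor fits only.")
  }
  d <- tibble::tibble(x = mf[[2]], y = mf[[1]], species = object$species)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2],
                         colour = "firebrick") +
    ggplot2::labs(
      x = names(mf)[2], y = names(mf)[1],
      subtitle = sprintf("PGLS: r2 = %.2f, F%d,%d = %.2f, P = %.3f, lambda = %.2f",
                         object$r_squared, object$df["df1"], object$df["df2"],
                         object$f_statistic, object$p_value, object$lambda)) +
    ggplot2::theme_minimal()
}
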