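#' Plot a fitted QSPR model over its training data
#'
#' Scatter of property against descriptor with the fitted family curve.
#'
#' @param object a [fit_model()] result.
#' @param n_grid number of curve evaluation points.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qspr_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = n_grid))
  grid$y <- eval_family(object$family, object$a, object$b, grid$x,
                        powers = object$powers)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "steelblue4", size = 2) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = object$xname, y = object$yname,
                  title = sprintf("%s fit: %s ~ %s (r2 = %.3f)",
                                  object$family, object$yname, object$xname,
                                  object$r2)) +
    ggplot2::theme_minimal()
}

#' Residual diagnostic plot
#'
#' Residuals against fitted values with a zero reference line; random scatter
#' around zero supports the fitted family.
#'
#' @param fit a [fit_model()] result.
#' @param scale passed to [residual_table()].
#' @return a ggplot object.
#' @export
plot_residuals <- function(fit, scale = "model") {
  rt <- residual_table(fit, scale = scale)
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(colour = "steelblue4", size = 2) +
    ggplot2::labs(x = "fitted", y = "residual",
                  title = sprintf("Residuals: %s ~ %s (%s)",
                                  fit$yname, fit$xname, fit$family)) +
    ggplot2::theme_minimal()
}

#' Experimental-versus-calculated plot for a validation run
#'
#' @param records a [validation_table()] tibble.
#' @return a ggplot object.
#' @export
plot_validation <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$experimental, y = .data$calculated,
                               colour = .data$property)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "experimental", y = "calculated") +
    ggplot2::theme_minimal()
}
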