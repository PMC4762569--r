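## ggplot2 views of the tabular result types.

#' Plot a scattering curve
#'
#' Log-intensity versus momentum transfer, with an error ribbon when the
#' curve carries experimental errors.
#'
#' @param object a [saxs_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot saxs_curve
#' @export
autoplot.saxs_curve <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$s, y = .data$I))
  if ("err" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$I - .data$err, ymax = .data$I + .data$err),
      alpha = 0.3)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("s (%s)", curve_unit(object)),
                  y = "I(s)", title = "Scattering curve")
}

#' Plot a pair-distance distribution
#'
#' @param object a [saxs_pofr()].
#' @param ... unused.
#' @return a ggplot of p(r) with its error band, annotated with Dmax.
#' @method autoplot saxs_pofr
#' @export
autoplot.saxs_pofr <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p - .data$perr, ymax = .data$p + .data$perr),
      alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$dmax, linetype = "dashed") +
    ggplot2::labs(x = "r (length units)", y = "p(r)",
                  title = sprintf("Distance distribution (Rg = %.3g, Dmax = %.3g)",
                                  object$rg, object$dmax))
}

#' Plot a model fit against the data
#'
#' @param object a [saxs_fit()].
#' @param ... unused.
#' @return a ggplot with experimental points and the model curve.
#' @method autoplot saxs_fit
#' @export
autoplot.saxs_fit <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$Iexp), size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Ifit), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "s", y = "I(s)",
                  title = sprintf("Model fit (chi2 = %.3g)", fit_chi2(object)))
}

#' Guinier plot of a curve with its fitted low-angle line
#'
#' @param object a [guinier_fit()] result (see [guinier_rg()]).
#' @param ... unused.
#' @return a ggplot of ln I versus s^2 over the fitted window.
#' @method autoplot guinier_fit
#' @export
autoplot.guinier_fit <- function(object, ...) {
  mod <- object$fit
  d <- tibble::tibble(s2 = mod$model[[2]], lnI = mod$model[[1]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s2, y = .data$lnI)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = expression(s^2), y = "ln I(s)",
                  title = sprintf("Guinier plot: Rg = %.4g", object$rg))
}

#' @importFrom rlang .data
NULL
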