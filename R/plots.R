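#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a window scan
#'
#' BIC of every trial window against the left breakpoint midpoint,
#' with the zero line above which the mixture (inversion) model is
#' favoured.
#'
#' @param object an `inv_scan`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.inv_scan <- function(object, ...) {
  df <- tibble::tibble(pos_mb = object$left_mid / 1e6, bic = object$bic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_mb, y = .data$bic)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "left breakpoint midpoint (Mb)", y = "BIC",
                  title = sprintf("Inversion scan (window %.2f Mb, %s data)",
                                  attr(object, "window_size") / 1e6,
                                  attr(object, "kind")))
}

#' Plot a classification-accuracy profile
#'
#' Accuracy of inversion-status calls as a function of the BIC
#' threshold.
#'
#' @param object an `inv_accuracy_profile` from [accuracy_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.inv_accuracy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_B, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(t[B]), y = "classification accuracy")
}

#' @importFrom rlang .data
NULL
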