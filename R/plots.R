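# ggplot2 displays for the pipeline's result types.

#' @export
autoplot.varcomp <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Proportion of phenotypic variance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectral_blups <- function(object, ...) {
  ggplot2::ggplot(object$varcomp,
                  ggplot2::aes(x = .data$wavelength, y = .data$h2)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Wavelength (nm)", y = expression(H^2),
                  title = sprintf("Wavelength heritability, %s",
                                  object$environment)) +
    ggplot2::theme_minimal()
}

#' Boxplots of replicated predictive abilities
#'
#' @param pa Tibble from [run_cv_scenario()] (possibly pooled).
#' @param x Column mapped to the x axis (default `"fraction"`).
#' @param fill Column mapped to fill (default `"info"`).
#' @return A ggplot object.
#' @export
plot_pa <- function(pa, x = "fraction", fill = "info") {
  ggplot2::ggplot(pa, ggplot2::aes(x = .data[[x]], y = .data$pa,
                                   fill = .data[[fill]])) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = x, y = "Predictive ability (r)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kernel_fit <- function(object, ...) {
  d <- object$variances |> filter(.data$component != "residual")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$estimate - .data$std_dev,
      ymax = .data$estimate + .data$std_dev
    ), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Posterior variance (mean ± SD)") +
    ggplot2::theme_minimal()
}
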