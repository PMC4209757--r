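# ggplot2 quick-look methods for the result types.

#' @export
autoplot.speciation_distribution <- function(object, ...) {
  basis <- attr(object, "basis") %||% "metal"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pH, y = 100 * .data$fraction,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = sprintf("%% of total %s", basis), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.zq_curve <- function(object, what = c("zbar", "qbar"), ...) {
  what <- match.arg(what)
  d <- object[!object$masked, ]
  if (what == "zbar") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$pL, y = .data$zbar,
                                    colour = .data$ratio)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(y = expression(bar(Z)[M]), colour = "M:L") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$pH, y = .data$qbar,
                                    colour = .data$ratio)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(y = expression(bar(Q)[M]), colour = "M:L") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.pmi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log10_drug,
                                       y = .data$log10_pmi,
                                       colour = .data$metal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 total drug / mol dm-3", y = "log10 pmi",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.titration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v_cm3, y = .data$pH)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "titrant volume / cm3") +
    ggplot2::theme_minimal()
}

#' Formation-function plot across ratios
#'
#' Convenience wrapper binding several [zbar_curve()] results and plotting
#' Z-bar against pL split by metal-to-ligand ratio.
#'
#' @param zq_list List of `zq_curve` tibbles.
#' @return A ggplot object.
#' @export
plot_formation_function <- function(zq_list) {
  d <- dplyr::bind_rows(zq_list)
  class(d) <- c("zq_curve", class(d))
  autoplot(d, what = "zbar")
}
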