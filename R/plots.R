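# ggplot2 displays for the result types.

#' Plot a density profile
#'
#' @param object A `density_profile` from [slit_profile()] or
#'   [directional_scan()].
#' @param ... Unused.
#' @return A ggplot: density versus position, one line per species.
#' @export
autoplot.density_profile <- function(object, ...) {
  xvar <- if ("x" %in% names(object)) "x" else "s"
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$density,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (xvar == "x") "x across slit (r_c)" else "projected position (r_c)",
      y = expression(rho ~ (r[c]^{-3})), colour = "species"
    ) +
    ggplot2::theme_minimal()
}

#' Plot association-number distributions
#'
#' Number- and weight-fraction distributions over the association
#' number, with the unimer/low-associate minimum and the main-peak/tail
#' split marked.
#'
#' @param object A `dpd_distributions`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dpd_distributions <- function(object, ...) {
  d <- tidyr::pivot_longer(object$table, c("F_n", "F_w"),
                           names_to = "fraction", values_to = "value")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$a_s, .data$value,
                                       colour = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(A[S]), y = "fraction", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$split_As)) {
    p <- p + ggplot2::geom_vline(xintercept = object$split_As,
                                 linetype = "dotted")
  }
  p
}

#' Plot gyration size parameters versus association number
#'
#' @param object A `shape_summary` from [shape_vs_size()].
#' @param ... Unused.
#' @return A ggplot of `lambda_i^2` versus `A_S`, faceted by subset.
#' @export
autoplot.shape_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object,
                           c("lambda1_sq", "lambda2_sq", "lambda3_sq"),
                           names_to = "component", values_to = "lambda_sq")
  ggplot2::ggplot(d, ggplot2::aes(.data$a_s, .data$lambda_sq,
                                  colour = .data$component)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~subset, scales = "free_y") +
    ggplot2::labs(x = expression(A[S]), y = expression(lambda[i]^2)) +
    ggplot2::theme_minimal()
}
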