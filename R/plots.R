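#' Plot species populations from a kinetic Monte Carlo run
#'
#' @param object A `mech_kmc_result`.
#' @param ... Unused.
#' @return A ggplot: mean population versus time, one line per species.
#' @method autoplot mech_kmc_result
#' @export
autoplot.mech_kmc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$population,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean population",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot a branching-fraction scan
#'
#' @param object A `mech_branching_scan` from [branching_scan()].
#' @param ... Unused.
#' @return A ggplot: product fraction versus the scanned energy or
#'   temperature, one line per product.
#' @method autoplot mech_branching_scan
#' @export
autoplot.mech_branching_scan <- function(object, ...) {
  xlab <- if (object$mode[1] == "E") "excitation energy (kcal/mol)"
          else "temperature (K)"
  ggplot2::ggplot(object, ggplot2::aes(.data$grid, .data$fraction,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "branching fraction", colour = "product") +
    ggplot2::theme_minimal()
}

#' Plot initial-rate measurements behind a reaction-order fit
#'
#' @param object A `mech_order_fit` from [fit_reaction_orders()].
#' @param ... Unused.
#' @return A ggplot of `ln(rate)` versus `ln(concentration)` per varied
#'   species, with the fitted slope (the order) as the panel label.
#' @method autoplot mech_order_fit
#' @export
autoplot.mech_order_fit <- function(object, ...) {
  meas <- attr(object, "measurements")
  lab <- stats::setNames(
    sprintf("%s (order %.2f)", object$species, object$order),
    object$species)
  ggplot2::ggplot(dplyr::filter(meas, .data$rate > 0),
                  ggplot2::aes(log(.data$concentration), log(.data$rate))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~species,
                        labeller = ggplot2::as_labeller(lab),
                        scales = "free") +
    ggplot2::labs(x = "ln(initial concentration)", y = "ln(initial rate)") +
    ggplot2::theme_minimal()
}
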