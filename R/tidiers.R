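#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetic Monte Carlo result
#'
#' @param x A `mech_kmc_result`.
#' @param ... Unused.
#' @return A long tibble: `time`, `species`, `population` (replica means).
#' @method tidy mech_kmc_result
#' @export
tidy.mech_kmc_result <- function(x, ...) {
  tidyr::pivot_longer(x$populations, -"time", names_to = "species",
                      values_to = "population")
}

#' @rdname tidy.mech_kmc_result
#' @return `glance()`: a one-row tibble with `replicas`, `n_events`, `seed`,
#'   `n_species` and `t_max`.
#' @method glance mech_kmc_result
#' @export
glance.mech_kmc_result <- function(x, ...) {
  tibble::tibble(replicas = x$replicas, n_events = x$n_events,
                 seed = x$seed,
                 n_species = ncol(x$populations) - 1L,
                 t_max = max(x$times))
}

#' Tidy a spectral summary
#'
#' @param x A `mech_spectral_summary`.
#' @param ... Unused.
#' @return A tibble: `index`, `eigenvalue`.
#' @method tidy mech_spectral_summary
#' @export
tidy.mech_spectral_summary <- function(x, ...) {
  tibble::tibble(index = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues)
}

#' @rdname tidy.mech_spectral_summary
#' @return `glance()`: one row with `n_fragments`, `spectral_gap`,
#'   `weighted`, `zero_tol`.
#' @method glance mech_spectral_summary
#' @export
glance.mech_spectral_summary <- function(x, ...) {
  tibble::tibble(n_fragments = x$n_fragments,
                 spectral_gap = x$spectral_gap,
                 weighted = x$weighted, zero_tol = x$zero_tol)
}

#' Tidy a reaction-order fit
#'
#' @param x A `mech_order_fit`.
#' @param ... Unused.
#' @return The per-species order table (already tidy); `glance()` returns the
#'   per-point rate measurements behind the fit.
#' @method tidy mech_order_fit
#' @export
tidy.mech_order_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.mech_order_fit
#' @method glance mech_order_fit
#' @export
glance.mech_order_fit <- function(x, ...) {
  attr(x, "measurements")
}
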