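#' Configuration for a kinetic Monte Carlo run
#'
#' @param replicas Number of independent stochastic replicas (>= 1).
#' @param t_max Time horizon, s.
#' @param seed Master seed; every source of randomness in the run derives
#'   from it (one sub-seed per replica), so a fixed seed reproduces the run
#'   bit-exactly.
#' @param initial Named numeric vector of initial populations (molecule
#'   counts) per species. Default: one molecule of the network reference.
#' @param t_grid_n Number of points of the output time grid (default 50).
#' @return An object of class `mech_kmc_config`.
#' @export
kmc_config <- function(replicas = 1000, t_max = 1, seed = 1,
                       initial = NULL, t_grid_n = 50) {
  if (replicas < 1) stop("replicas must be >= 1", call. = FALSE)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  structure(list(replicas = as.integer(replicas), t_max = t_max,
                 seed = as.integer(seed), initial = initial,
                 t_grid_n = as.integer(t_grid_n)),
            class = "mech_kmc_config")
}

#' Solve the chemical master equation by kinetic Monte Carlo
#'
#' Gillespie's direct method: at each step the waiting time is
#' `tau = -ln(u) / k_tot` and the reaction channel is chosen with probability
#' proportional to its propensity (rate times the population of the source
#' species, times the partner population for pseudo-first-order bimolecular
#' channels). A replica ends when no channel is open (e.g. all molecules sit
#' in sink species) or at `t_max`. Species with no outgoing channel that are
#' not declared sinks are treated as sinks with a warning.
#'
#' @param network A [reaction_network()].
#' @param rates Channel rate table from [network_rates()] (all rates >= 0).
#' @param config A [kmc_config()].
#' @return An object of class `mech_kmc_result`: list with `times` (grid, s),
#'   `populations` (tibble, mean population per species on the grid),
#'   `branching` (tibble over sink species: `species`, `count`, `fraction`),
#'   `n_events`, `replicas`, `seed`. Use [tidy()], [glance()] and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' net <- make_toy_network("two_channel", k1 = 2, k2 = 1)
#' rates <- network_rates(net, T = 300)
#' res <- run_kmc(net, rates, kmc_config(replicas = 200, t_max = 20, seed = 7))
#' res$branching
#' @export
run_kmc <- function(network, rates, config = kmc_config()) {
  stopifnot(inherits(network, "mech_network"))
  if (any(rates$rate < 0) || any(!is.finite(rates$rate))) {
    stop("all channel rates must be finite and >= 0", call. = FALSE)
  }
  species <- names(network$wells)
  sinks <- species[purrr::map_lgl(network$wells, "sink")]
  participants <- unique(c(rates$from, rates$partner, rates$release))
  no_out <- setdiff(species, c(participants[!is.na(participants)], sinks))
  if (length(no_out)) {
    warning("species with no outgoing channel treated as sink(s): ",
            paste(no_out, collapse = ", "))
    sinks <- union(sinks, no_out)
  }
  initial <- config$initial %||%
    stats::setNames(1, network$reference)
  if (any(initial < 0)) stop("initial populations must be >= 0", call. = FALSE)
  n0 <- stats::setNames(numeric(length(species)), species)
  n0[names(initial)] <- initial
  active <- rates$rate > 0
  ch_from <- match(rates$from, species)[active]
  ch_to <- match(rates$to, species)[active]
  ch_partner <- match(rates$partner, species)[active]
  ch_release <- match(rates$release, species)[active]
  ch_rate <- rates$rate[active]
  t_grid <- seq(0, config$t_max, length.out = config$t_grid_n)

  pop_acc <- matrix(0, nrow = length(t_grid), ncol = length(species))
  sink_counts <- stats::setNames(numeric(length(species)), species)
  n_events <- 0L

  set.seed(config$seed)
  replica_seeds <- sample.int(.Machine$integer.max - 1L, config$replicas)
  for (r in seq_len(config$replicas)) {
    set.seed(replica_seeds[r])
    n <- n0
    t <- 0
    gi <- 1L  # next grid index to fill
    repeat {
      prop <- ch_rate * n[ch_from]
      has_p <- !is.na(ch_partner)
      if (any(has_p)) prop[has_p] <- prop[has_p] * n[ch_partner[has_p]]
      a0 <- sum(prop)
      if (a0 <= 0) break
      tau <- -log(stats::runif(1)) / a0
      t_next <- t + tau
      while (gi <= length(t_grid) && t_grid[gi] < t_next) {
        pop_acc[gi, ] <- pop_acc[gi, ] + n
        gi <- gi + 1L
      }
      if (t_next > config$t_max) break
      t <- t_next
      ch <- findInterval(stats::runif(1) * a0, cumsum(prop)) + 1L
      n[ch_from[ch]] <- n[ch_from[ch]] - 1
      n[ch_to[ch]] <- n[ch_to[ch]] + 1
      if (!is.na(ch_partner[ch])) {
        n[ch_partner[ch]] <- n[ch_partner[ch]] - 1
      }
      if (!is.na(ch_release[ch])) {
        n[ch_release[ch]] <- n[ch_release[ch]] + 1
      }
      n_events <- n_events + 1L
    }
    if (gi <= length(t_grid)) {
      pop_acc[gi:length(t_grid), ] <-
        pop_acc[gi:length(t_grid), ] + rep(n, each = length(t_grid) - gi + 1L)
    }
    in_sinks <- n[sinks]
    sink_counts[sinks] <- sink_counts[sinks] + in_sinks
  }

  colnames(pop_acc) <- species
  populations <- tibble::as_tibble(pop_acc / config$replicas)
  populations <- dplyr::bind_cols(tibble::tibble(time = t_grid), populations)
  total_sink <- sum(sink_counts[sinks])
  branching <- tibble::tibble(
    species = sinks,
    count = unname(sink_counts[sinks]),
    fraction = if (total_sink > 0) unname(sink_counts[sinks]) / total_sink
               else rep(NA_real_, length(sinks))
  )
  structure(
    list(times = t_grid, populations = populations, branching = branching,
         n_events = n_events, replicas = config$replicas,
         seed = config$seed),
    class = "mech_kmc_result"
  )
}

#' @export
print.mech_kmc_result <- function(x, ...) {
  cat("<mech_kmc_result> ", x$replicas, " replicas, ", x$n_events,
      " reaction events\n", sep = "")
  if (nrow(x$branching) && !all(is.na(x$branching$fraction))) {
    cat("branching over sinks:\n")
    print(x$branching)
  }
  invisible(x)
}

#' Deterministic reference solution of a linear master equation
#'
#' Integrates `dp/dt = K p` for a network whose channels are all
#' (pseudo-)first-order, as the independent oracle for [run_kmc()]. Channels
#' with a bimolecular partner are rejected: fold the partner concentration
#' into the rate first.
#'
#' @param network A [reaction_network()].
#' @param rates Channel rate table from [network_rates()].
#' @param initial Named numeric vector of initial populations.
#' @param t_grid Numeric vector of output times, s.
#' @return A tibble: `time`, one column per species (mean populations).
#' @export
ode_reference <- function(network, rates, initial, t_grid) {
  if (any(!is.na(rates$partner))) {
    stop("ode_reference requires a linear network: fold bimolecular ",
         "partners into pseudo-first-order rates first", call. = FALSE)
  }
  species <- names(network$wells)
  K <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  for (k in seq_len(nrow(rates))) {
    K[rates$to[k], rates$from[k]] <- K[rates$to[k], rates$from[k]] +
      rates$rate[k]
    K[rates$from[k], rates$from[k]] <- K[rates$from[k], rates$from[k]] -
      rates$rate[k]
    if (!is.na(rates$release[k])) {
      K[rates$release[k], rates$from[k]] <-
        K[rates$release[k], rates$from[k]] + rates$rate[k]
    }
  }
  p0 <- stats::setNames(numeric(length(species)), species)
  p0[names(initial)] <- initial
  sol <- deSolve::ode(y = p0, times = t_grid,
                      func = function(t, y, parms) list(parms %*% y),
                      parms = K)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out
}

#' Branching fractions across an energy or temperature grid
#'
#' Recomputes the channel rates and reruns the kinetic Monte Carlo at each
#' grid point (with an independent seeded stream per point, derived from the
#' master seed) and tabulates the product branching fractions, the stochastic
#' analogue of a product-yield-versus-excitation-energy curve.
#'
#' @param network A [reaction_network()].
#' @param config A [kmc_config()].
#' @param grid Numeric vector of energies (kcal/mol) or temperatures (K).
#' @param mode `"E"` (microcanonical, default) or `"T"` (canonical).
#' @param grain Beyer-Swinehart grain for microcanonical rates.
#' @return A tibble of class `mech_branching_scan`: `grid` (the E or T
#'   value), `mode`, `species`, `fraction`.
#' @export
branching_scan <- function(network, config, grid, mode = c("E", "T"),
                           grain = 10) {
  mode <- match.arg(mode)
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  out <- purrr::map_dfr(seq_along(grid), function(i) {
    rates <- if (mode == "E") {
      network_rates(network, E = grid[i], grain = grain)
    } else {
      network_rates(network, T = grid[i])
    }
    cfg <- config
    cfg$seed <- config$seed + i
    res <- run_kmc(network, rates, cfg)
    dplyr::mutate(res$branching, grid = grid[i], mode = mode,
                  .before = 1)
  })
  class(out) <- c("mech_branching_scan", class(out))
  out
}

#' Write KMC results to delimited text and JSON
#'
#' @param result A `mech_kmc_result`.
#' @param prefix Output path prefix; writes `<prefix>_populations.tsv`,
#'   `<prefix>_branching.tsv` and `<prefix>.json`.
#' @return The three paths, invisibly.
#' @export
write_kmc_result <- function(result, prefix) {
  p_pop <- paste0(prefix, "_populations.tsv")
  p_br <- paste0(prefix, "_branching.tsv")
  p_js <- paste0(prefix, ".json")
  utils::write.table(result$populations, p_pop, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$branching, p_br, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(replicas = result$replicas, seed = result$seed,
         n_events = result$n_events, branching = result$branching),
    p_js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(p_pop, p_br, p_js))
}
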