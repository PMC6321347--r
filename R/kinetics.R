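#' Reaction path degeneracy from optical-isomer counts
#'
#' The path degeneracy multiplying every rate constant is the ratio of the
#' optical-isomer count of the transition state to that of the reactant,
#' optionally combined with rotational symmetry numbers:
#' `sigma = (m_ts / m_reactant) * (symm_reactant / symm_ts)`. With the default
#' symmetry numbers of 1 this is the plain optical-isomer ratio.
#'
#' @param m_reactant,m_ts Optical-isomer counts (integers >= 1).
#' @param symm_reactant,symm_ts Rotational symmetry numbers (default 1).
#' @return Positive numeric degeneracy.
#' @examples
#' path_degeneracy(1, 2)  # 2
#' @export
path_degeneracy <- function(m_reactant, m_ts, symm_reactant = 1, symm_ts = 1) {
  vals <- c(m_reactant, m_ts, symm_reactant, symm_ts)
  if (any(!is.finite(vals)) || any(vals < 1)) {
    stop("optical-isomer counts and symmetry numbers must be >= 1",
         call. = FALSE)
  }
  (m_ts / m_reactant) * (symm_reactant / symm_ts)
}

#' Canonical (Eyring) transition-state-theory rate constant
#'
#' `k(T) = sigma * (kB T / h) * (R T / p0)^dn * exp(-dG / (R T))` with the
#' standard pressure `p0 = 1` bar and `dn = 0` for unimolecular, `dn = 1` for
#' bimolecular reactions. Unimolecular rates are returned in 1/s; bimolecular
#' rates carry the standard-state volume factor `R T / p0` converted to
#' cm^3 molecule^-1 s^-1.
#'
#' @param dG_ddag Free energy of activation, kcal/mol.
#' @param T Temperature, K.
#' @param sigma Reaction path degeneracy (default 1), see
#'   [path_degeneracy()].
#' @param delta_n 0 (unimolecular) or 1 (bimolecular).
#' @return Numeric rate constant (1/s, or cm^3 molecule^-1 s^-1 when
#'   `delta_n = 1`).
#' @examples
#' tst_rate(0, 298.15)               # kB*T/h ~ 6.21e12 1/s
#' tst_rate(10, 423, sigma = 2)
#' @export
tst_rate <- function(dG_ddag, T, sigma = 1, delta_n = 0) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  if (!delta_n %in% c(0, 1)) stop("delta_n must be 0 or 1", call. = FALSE)
  cn <- mech_constants
  k <- sigma * (cn$kB_J * T / cn$h_Js) * exp(-dG_ddag / (cn$R_kcal * T))
  if (delta_n == 1) {
    # RT/p0 at 1 bar in m^3/mol -> cm^3/molecule
    vol_cm3 <- cn$R_J * T / 1e5 * 1e6 / cn$NA_mol
    k <- k * vol_cm3
  }
  k
}

#' Beyer-Swinehart direct count of harmonic vibrational states
#'
#' Counts harmonic state energies `sum_k n_k nu_k` (measured from the
#' zero-point level) on an energy grid of width `grain` by the standard
#' Beyer-Swinehart convolution. Frequencies are rounded to the nearest grain
#' multiple (at least one grain).
#'
#' @param freqs Harmonic frequencies, cm^-1 (all > 0).
#' @param E_max Top of the energy grid, cm^-1.
#' @param grain Energy bin width, cm^-1 (default 10).
#' @return An object of class `mech_state_count`: list with `grain`, `E_max`,
#'   `counts` (states per bin), `rho` (density of states per cm^-1 per bin)
#'   and `W` (cumulative sum of states). Query it with [state_count_W()] and
#'   [state_count_rho()].
#' @examples
#' sc <- beyer_swinehart(100, E_max = 400, grain = 10)
#' state_count_W(sc, 350)  # 4: levels 0, 100, 200, 300
#' @export
beyer_swinehart <- function(freqs, E_max, grain = 10) {
  if (!length(freqs) || any(freqs <= 0)) {
    stop("freqs must be non-empty and positive", call. = FALSE)
  }
  if (E_max < 0) stop("E_max must be non-negative", call. = FALSE)
  if (grain <= 0) stop("grain must be positive", call. = FALSE)
  nbins <- floor(E_max / grain) + 1L
  counts <- numeric(nbins)
  counts[1] <- 1  # the ground state
  for (nu in freqs) {
    r <- max(1L, as.integer(round(nu / grain)))
    if (r < nbins) {
      for (i in seq.int(r + 1L, nbins)) {
        counts[i] <- counts[i] + counts[i - r]
      }
    }
  }
  structure(
    list(grain = grain, E_max = E_max, counts = counts,
         rho = counts / grain, W = cumsum(counts)),
    class = "mech_state_count"
  )
}

#' @export
print.mech_state_count <- function(x, ...) {
  cat("<mech_state_count> grain ", x$grain, " cm^-1, E_max ", x$E_max,
      " cm^-1, W(E_max) = ", format(x$W[length(x$W)], big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Query a Beyer-Swinehart state count
#'
#' [state_count_W()] returns the sum of states up to energy `E` (cm^-1, from
#' the zero-point level); [state_count_rho()] the density of states
#' (states/cm^-1) in the bin containing `E`. Energies below zero give 0.
#'
#' @param sc A [beyer_swinehart()] result.
#' @param E Energy, cm^-1.
#' @return Numeric.
#' @export
state_count_W <- function(sc, E) {
  vapply(E, function(e) {
    if (e < 0) return(0)
    b <- min(floor(e / sc$grain) + 1, length(sc$W))
    sc$W[b]
  }, numeric(1))
}

#' @rdname state_count_W
#' @export
state_count_rho <- function(sc, E) {
  vapply(E, function(e) {
    if (e < 0) return(0)
    b <- min(floor(e / sc$grain) + 1, length(sc$rho))
    sc$rho[b]
  }, numeric(1))
}

#' Microcanonical RRKM rate constant
#'
#' `k(E) = sigma * W_TS(E - E_TS) / (h * rho_well(E - E_well))`, with the sum
#' of states at the transition state and the density of states at the
#' reactant well both obtained by Beyer-Swinehart direct count from each
#' species' own zero-point level. All energies are ZPE-inclusive and relative
#' to the common network reference; the internal conversion uses
#' 1 kcal/mol = 349.755 cm^-1. The rate is zero below the barrier.
#'
#' @param well A [well()] (reactant).
#' @param ts A [ts_record()] (transition state).
#' @param E_total Total energy, kcal/mol, relative to the network reference.
#' @param sigma Path degeneracy; default `ts$m_opt / well$m_opt`.
#' @param grain Beyer-Swinehart grain, cm^-1 (default 10).
#' @return Numeric rate constant, 1/s.
#' @export
rrkm_rate <- function(well, ts, E_total, sigma = NULL, grain = 10) {
  if (is.null(sigma)) sigma <- path_degeneracy(well$m_opt, ts$m_opt)
  E_w <- E_total - well$energy
  if (E_w <= 0) {
    stop("well '", well$label, "' is energetically inaccessible at E_total = ",
         E_total, " kcal/mol", call. = FALSE)
  }
  E_ts <- E_total - ts$energy
  if (E_ts < 0) return(0)
  E_w_cm <- kcal_to_wavenumber(E_w)
  E_ts_cm <- kcal_to_wavenumber(E_ts)
  sc_w <- beyer_swinehart(well$freqs, E_max = E_w_cm + grain, grain = grain)
  sc_ts <- beyer_swinehart(ts$freqs, E_max = max(E_ts_cm, 0) + grain,
                           grain = grain)
  rho <- state_count_rho(sc_w, E_w_cm)
  if (rho <= 0) {
    stop("density of states vanishes at E = ", signif(E_w_cm, 6),
         " cm^-1 in well '", well$label, "'; use a larger grain",
         call. = FALSE)
  }
  # k = sigma * W / (h * rho) with rho per cm^-1 collapses to sigma * c * W / rho
  sigma * mech_constants$c_cm * state_count_W(sc_ts, E_ts_cm) / rho
}

#' Eckart tunneling correction
#'
#' Thermally averaged transmission coefficient through an asymmetric Eckart
#' barrier matched to the forward barrier, reverse barrier and the magnitude
#' of the imaginary frequency at the saddle point. The transmission
#' probability uses the standard closed form and the thermal average is done
#' by adaptive quadrature over a Boltzmann energy distribution (relative
#' tolerance 1e-6). The correction tends to 1 in the classical limit
#' (vanishing imaginary frequency or high temperature).
#'
#' @param dE_forward,dE_reverse Forward/reverse barrier heights, kcal/mol
#'   (both > 0).
#' @param imag_freq Magnitude of the imaginary frequency, cm^-1.
#' @param T Temperature, K.
#' @return Multiplicative correction factor `kappa(T)`.
#' @examples
#' eckart_correction(10, 10, 1000, 300)
#' @export
eckart_correction <- function(dE_forward, dE_reverse, imag_freq, T) {
  if (dE_forward <= 0 || dE_reverse <= 0) {
    stop("barrier heights must be positive", call. = FALSE)
  }
  if (imag_freq < 0) stop("imag_freq must be non-negative", call. = FALSE)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  if (imag_freq == 0) return(1)
  V1 <- kcal_to_wavenumber(dE_forward)
  V2 <- kcal_to_wavenumber(dE_reverse)
  nu <- imag_freq
  a1 <- 2 * pi * V1 / nu
  a2 <- 2 * pi * V2 / nu
  den <- 1 / sqrt(a1) + 1 / sqrt(a2)
  Dd <- a1 * a2 - pi^2 / 4
  # log(cosh(x)) without overflow
  log_cosh <- function(x) {
    ax <- abs(x)
    ifelse(ax > 30, ax - log(2), log(cosh(x)))
  }
  # log(cosh(x) + C) where C = cosh(2 sqrt(Dd)) (Dd >= 0, via its log) or
  # cos(2 sqrt(-Dd)) in [-1, 1] (Dd < 0)
  if (Dd >= 0) {
    logC <- log_cosh(2 * sqrt(Dd))
    log_cosh_plus_C <- function(x) {
      lc <- log_cosh(x)
      m <- pmax(lc, logC)
      m + log(exp(lc - m) + exp(logC - m))
    }
  } else {
    C <- cos(2 * sqrt(-Dd))
    log_cosh_plus_C <- function(x) {
      lc <- log_cosh(x)
      lc + log1p(C * exp(-lc))
    }
  }
  prob <- function(E) {
    # E measured from the reactant asymptote, cm^-1
    xi <- E / V1
    arg_b <- (xi - 1) * a1 + a2
    p <- numeric(length(E))
    ok <- arg_b > 0 & E > 0
    if (any(ok)) {
      two_pi_a <- 2 * sqrt(a1 * xi[ok]) / den
      two_pi_b <- 2 * sqrt(arg_b[ok]) / den
      dL <- log_cosh_plus_C(two_pi_a - two_pi_b) -
        log_cosh_plus_C(two_pi_a + two_pi_b)
      p[ok] <- pmax(-expm1(dL), 0)
    }
    p
  }
  kT <- T / mech_constants$c2_cmK  # kB T in cm^-1
  integrand <- function(E) prob(E) * exp(-(E - V1) / kT) / kT
  lo <- max(0, V1 - V2)
  # split at the barrier top: integrand is kinked there
  i1 <- stats::integrate(integrand, lo, V1, rel.tol = 1e-6,
                         subdivisions = 400L)$value
  i2 <- stats::integrate(integrand, V1, V1 + 60 * kT, rel.tol = 1e-6,
                         subdivisions = 400L)$value
  i1 + i2
}
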