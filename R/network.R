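#' Construct a reaction-network well (minimum)
#'
#' @param label Species label (unique within the network).
#' @param energy ZPE-inclusive energy relative to the network reference,
#'   kcal/mol.
#' @param freqs Harmonic frequencies, cm^-1 (all > 0).
#' @param m_opt Number of optical isomers (>= 1).
#' @param sink Logical; sinks terminate kinetic Monte Carlo walkers.
#' @return An object of class `mech_well`.
#' @export
well <- function(label, energy, freqs, m_opt = 1, sink = FALSE) {
  if (any(freqs <= 0)) stop("well '", label, "': freqs must be > 0", call. = FALSE)
  if (m_opt < 1) stop("well '", label, "': m_opt must be >= 1", call. = FALSE)
  structure(list(label = label, energy = energy, freqs = freqs,
                 m_opt = m_opt, sink = isTRUE(sink)),
            class = "mech_well")
}

#' Construct a transition-state record
#'
#' A first-order saddle point connecting two wells, carried as a ZPE-inclusive
#' energy, its 3N-7 real harmonic frequencies (the imaginary mode excluded,
#' its magnitude optionally kept for tunneling) and the labels of the two
#' wells it connects. Submerged barriers (TS below a connected well) are
#' allowed. For benchmark networks with analytically known kinetics, explicit
#' per-direction rates may be given and bypass the statistical-rate formulas;
#' a `release` species turns the forward step into
#' `from -> to + release` (such steps are treated as irreversible).
#'
#' @param label TS label.
#' @param energy ZPE-inclusive energy relative to the network reference,
#'   kcal/mol.
#' @param freqs Real harmonic frequencies, cm^-1.
#' @param connects Character vector of the two connected well labels
#'   `c(from, to)`.
#' @param m_opt Optical-isomer count (>= 1).
#' @param imag_freq Magnitude of the imaginary frequency, cm^-1 (optional,
#'   for Eckart tunneling).
#' @param dG_fwd,dG_rev Optional free energies of activation per direction,
#'   kcal/mol (override the harmonic estimate at canonical evaluation).
#' @param rate_fwd,rate_rev Optional explicit first-order (or
#'   pseudo-first-order base) rates, 1/s.
#' @param release Optional species released by the forward step.
#' @return An object of class `mech_ts`.
#' @export
ts_record <- function(label, energy, freqs, connects, m_opt = 1,
                      imag_freq = NULL, dG_fwd = NULL, dG_rev = NULL,
                      rate_fwd = NULL, rate_rev = NULL, release = NULL) {
  if (length(connects) != 2) {
    stop("ts '", label, "': connects must name exactly two wells", call. = FALSE)
  }
  if (any(freqs <= 0)) stop("ts '", label, "': freqs must be > 0 (exclude the imaginary mode)",
                            call. = FALSE)
  if (m_opt < 1) stop("ts '", label, "': m_opt must be >= 1", call. = FALSE)
  structure(list(label = label, energy = energy, freqs = freqs,
                 connects = connects, m_opt = m_opt,
                 imag_freq = imag_freq, dG_fwd = dG_fwd, dG_rev = dG_rev,
                 rate_fwd = rate_fwd, rate_rev = rate_rev, release = release),
            class = "mech_ts")
}

#' Assemble a reaction network
#'
#' Wells are the nodes, transition states the edges of the network on which
#' the chemical master equation is solved. Validation checks label
#' uniqueness, that every TS connects existing wells, and that bimolecular
#' declarations reference existing transition states and partner species.
#'
#' @param wells List of [well()] objects.
#' @param transition_states List of [ts_record()] objects.
#' @param bimolecular Optional list of lists `list(ts =, partner =)`
#'   declaring that the forward direction of a TS consumes one molecule of
#'   the partner species (pseudo-first-order treatment in KMC).
#' @param reference Label of the reference species (defaults to the first
#'   well).
#' @return An object of class `mech_network`.
#' @export
reaction_network <- function(wells, transition_states, bimolecular = NULL,
                             reference = NULL) {
  labels <- purrr::map_chr(wells, "label")
  if (anyDuplicated(labels)) stop("duplicate well labels", call. = FALSE)
  ts_labels <- purrr::map_chr(transition_states, "label")
  if (anyDuplicated(ts_labels)) stop("duplicate TS labels", call. = FALSE)
  for (ts in transition_states) {
    missing <- setdiff(ts$connects, labels)
    if (length(missing)) {
      stop("ts '", ts$label, "' connects unknown well(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!is.null(ts$release) && !ts$release %in% labels) {
      stop("ts '", ts$label, "' releases unknown species '", ts$release, "'",
           call. = FALSE)
    }
  }
  bimolecular <- bimolecular %||% list()
  for (bm in bimolecular) {
    if (!bm$ts %in% ts_labels) {
      stop("bimolecular declaration references unknown TS '", bm$ts, "'",
           call. = FALSE)
    }
    if (!bm$partner %in% labels) {
      stop("bimolecular declaration for '", bm$ts,
           "' references unknown partner '", bm$partner, "'", call. = FALSE)
    }
  }
  reference <- reference %||% labels[1]
  if (!reference %in% labels) stop("unknown reference species", call. = FALSE)
  names(wells) <- labels
  names(transition_states) <- ts_labels
  structure(list(wells = wells, transition_states = transition_states,
                 bimolecular = bimolecular, reference = reference),
            class = "mech_network")
}

#' @export
print.mech_network <- function(x, ...) {
  cat("<mech_network> ", length(x$wells), " wells, ",
      length(x$transition_states), " transition states",
      if (length(x$bimolecular)) paste0(", ", length(x$bimolecular),
                                        " bimolecular channel(s)"),
      "; reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Read and write the mechkit network JSON schema
#'
#' Top-level object: `schema` (`"mechkit-network/1"`), `reference`,
#' `wells` (label, energy_kcal, freqs_cm, m_opt, sink), `transition_states`
#' (label, energy_kcal, freqs_cm, m_opt, connects, plus optional
#' imag_freq_cm, dG_fwd_kcal, dG_rev_kcal, rate_fwd_s, rate_rev_s, release)
#' and optional `bimolecular` (ts, partner). Validation errors name the
#' offending entry.
#'
#' @param path JSON file path.
#' @param network A [reaction_network()] (for the writer).
#' @return [read_network()]: a `mech_network`. [write_network()]: `path`,
#'   invisibly.
#' @name network_io
#' @export
read_network <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$wells) || is.null(js$transition_states)) {
    stop("'", path, "': network JSON must contain 'wells' and ",
         "'transition_states'", call. = FALSE)
  }
  wells <- purrr::imap(js$wells, function(w, k) {
    need <- setdiff(c("label", "energy_kcal", "freqs_cm"), names(w))
    if (length(need)) {
      stop("'", path, "': wells[", k, "] is missing field(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    well(w$label, w$energy_kcal, unlist(w$freqs_cm),
         m_opt = w$m_opt %||% 1, sink = w$sink %||% FALSE)
  })
  tss <- purrr::imap(js$transition_states, function(ts, k) {
    need <- setdiff(c("label", "energy_kcal", "freqs_cm", "connects"),
                    names(ts))
    if (length(need)) {
      stop("'", path, "': transition_states[", k, "] is missing field(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    ts_record(ts$label, ts$energy_kcal, unlist(ts$freqs_cm),
              unlist(ts$connects), m_opt = ts$m_opt %||% 1,
              imag_freq = ts$imag_freq_cm, dG_fwd = ts$dG_fwd_kcal,
              dG_rev = ts$dG_rev_kcal, rate_fwd = ts$rate_fwd_s,
              rate_rev = ts$rate_rev_s, release = ts$release)
  })
  bm <- purrr::map(js$bimolecular %||% list(), function(b) {
    list(ts = b$ts, partner = b$partner)
  })
  reaction_network(wells, tss, bimolecular = bm, reference = js$reference)
}

#' @rdname network_io
#' @export
write_network <- function(network, path) {
  js <- list(
    schema = "mechkit-network/1",
    reference = network$reference,
    wells = purrr::map(network$wells, function(w) {
      list(label = w$label, energy_kcal = w$energy, freqs_cm = w$freqs,
           m_opt = w$m_opt, sink = w$sink)
    }),
    transition_states = purrr::map(network$transition_states, function(ts) {
      drop_null(list(label = ts$label, energy_kcal = ts$energy,
                     freqs_cm = ts$freqs, m_opt = ts$m_opt,
                     connects = ts$connects, imag_freq_cm = ts$imag_freq,
                     dG_fwd_kcal = ts$dG_fwd, dG_rev_kcal = ts$dG_rev,
                     rate_fwd_s = ts$rate_fwd, rate_rev_s = ts$rate_rev,
                     release = ts$release))
    }),
    bimolecular = network$bimolecular
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

# directed channel table: one row per (from -> to) step the KMC can take
network_channels <- function(network) {
  bm_partner <- stats::setNames(
    purrr::map_chr(network$bimolecular, "partner"),
    purrr::map_chr(network$bimolecular, "ts")
  )
  rows <- purrr::map_dfr(network$transition_states, function(tsr) {
    a <- tsr$connects[1]
    b <- tsr$connects[2]
    partner <- unname(bm_partner[tsr$label])
    if (is.null(partner) || length(partner) == 0) partner <- NA_character_
    rel <- tsr$release %||% NA_character_
    fwd <- tibble::tibble(ts = tsr$label, from = a, to = b,
                          direction = "fwd", partner = partner,
                          release = rel)
    explicit <- !is.null(tsr$rate_fwd) || !is.null(tsr$rate_rev)
    has_rev <- is.null(tsr$release) && (!explicit || !is.null(tsr$rate_rev))
    if (has_rev) {
      rev <- tibble::tibble(ts = tsr$label, from = b, to = a,
                            direction = "rev", partner = NA_character_,
                            release = partner)
      fwd <- dplyr::bind_rows(fwd, rev)
    }
    fwd
  })
  # sinks have no outgoing channels
  sinks <- purrr::map_chr(purrr::keep(network$wells, "sink"), "label")
  dplyr::filter(rows, !.data$from %in% sinks)
}

#' Rate constants for every network channel
#'
#' Evaluates a first-order (or pseudo-first-order base) rate for each
#' directed channel of the network, either canonically at temperature `T`
#' (Eyring TST, [tst_rate()]) or microcanonically at total energy `E` (RRKM,
#' [rrkm_rate()]). Explicit rates stored on a transition state pass through
#' unchanged. Canonical activation free energies use stored `dG_fwd`/`dG_rev`
#' when present, otherwise the ZPE-inclusive energy difference plus the
#' harmonic vibrational entropy from the species' partition functions.
#' Channels out of wells lying above the total energy get rate 0 in
#' microcanonical mode.
#'
#' @param network A [reaction_network()].
#' @param T Temperature, K (canonical mode).
#' @param E Total energy, kcal/mol relative to the reference (microcanonical
#'   mode). Exactly one of `T`, `E` must be given.
#' @param grain Beyer-Swinehart grain, cm^-1.
#' @param tunneling `"none"` or `"eckart"` (canonical mode only; applied to
#'   transition states that carry an imaginary frequency).
#' @return A tibble with one row per channel: `ts`, `from`, `to`,
#'   `direction`, `partner`, `release`, `sigma`, `rate` (1/s).
#' @export
network_rates <- function(network, T = NULL, E = NULL, grain = 10,
                          tunneling = c("none", "eckart")) {
  tunneling <- match.arg(tunneling)
  if (is.null(T) == is.null(E)) {
    stop("give exactly one of T (canonical) or E (microcanonical)",
         call. = FALSE)
  }
  ch <- network_channels(network)
  if (!is.null(E) && any(!is.na(ch$partner))) {
    stop("bimolecular channels are not supported in microcanonical mode",
         call. = FALSE)
  }
  ch$sigma <- NA_real_
  ch$rate <- NA_real_
  for (k in seq_len(nrow(ch))) {
    tsr <- network$transition_states[[ch$ts[k]]]
    from <- network$wells[[ch$from[k]]]
    fwd <- ch$direction[k] == "fwd"
    explicit <- if (fwd) tsr$rate_fwd else tsr$rate_rev
    sigma <- path_degeneracy(from$m_opt, tsr$m_opt)
    ch$sigma[k] <- sigma
    if (!is.null(explicit)) {
      ch$rate[k] <- explicit
    } else if (!is.null(T)) {
      dG <- if (fwd) tsr$dG_fwd else tsr$dG_rev
      if (is.null(dG)) {
        dG <- (tsr$energy - from$energy) -
          mech_constants$R_kcal * T *
            (log_qvib(tsr$freqs, T) - log_qvib(from$freqs, T))
      }
      kk <- tst_rate(dG, T, sigma = sigma,
                     delta_n = as.integer(!is.na(ch$partner[k])))
      if (tunneling == "eckart" && !is.null(tsr$imag_freq)) {
        other <- network$wells[[setdiff(tsr$connects, from$label)[1]]]
        dE_f <- tsr$energy - from$energy
        dE_r <- tsr$energy - other$energy
        if (dE_f > 0 && dE_r > 0) {
          kk <- kk * eckart_correction(dE_f, dE_r, tsr$imag_freq, T)
        }
      }
      ch$rate[k] <- kk
    } else {
      if (E - from$energy <= 0) {
        ch$rate[k] <- 0
      } else {
        ch$rate[k] <- rrkm_rate(from, tsr, E, sigma = sigma, grain = grain)
      }
    }
  }
  ch
}

# log harmonic vibrational partition function (zero of energy at the ZPE)
log_qvib <- function(freqs, T) {
  u <- mech_constants$c2_cmK * freqs / T
  -sum(log1p(-exp(-u)))
}
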