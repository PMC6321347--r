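#' Script a synthetic trajectory with known bond events
#'
#' Defines a trajectory in which selected atom pairs follow a linear distance
#' interpolation across a frame window (crossing the bond threshold at an
#' analytically known frame) while all other atoms jitter with seeded uniform
#' noise, emulating vibrational motion. This stands in for molecular dynamics
#' so the event-detection machinery can be tested against exact ground truth.
#'
#' @param base_geometry A [geometry()] giving elements and rest positions.
#' @param events A list of event specs, each
#'   `list(pair = c(i, j), start_frame =, end_frame =, start_dist =,
#'   end_dist =)` (distances in Angstrom straddling the pair's bond
#'   threshold; `j` is displaced along the i-j axis, so each atom may appear
#'   in at most one scripted event).
#' @param n_frames Total frames.
#' @param vibration_amplitude Uniform per-coordinate jitter half-width,
#'   Angstrom (must stay below the threshold margin of every unscripted
#'   pair).
#' @param seed Seed for the jitter.
#' @param scale Bond-detection scale factor (defines the thresholds).
#' @return An object of class `mech_event_script`.
#' @export
event_script <- function(base_geometry, events, n_frames,
                         vibration_amplitude = 0.02, seed = 1, scale = 1.2) {
  stopifnot(inherits(base_geometry, "mech_geometry"))
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (vibration_amplitude < 0) stop("negative vibration amplitude", call. = FALSE)
  r_ref <- scale * outer(base_geometry$r_cov, base_geometry$r_cov, `+`)
  active <- integer(0)
  for (ev in events) {
    i <- ev$pair[1]; j <- ev$pair[2]
    if (i >= j) stop("event pair must have i < j", call. = FALSE)
    if (ev$start_frame < 2 || ev$end_frame > n_frames ||
        ev$start_frame >= ev$end_frame) {
      stop("event window [", ev$start_frame, ", ", ev$end_frame,
           "] invalid for ", n_frames, " frames", call. = FALSE)
    }
    thr <- r_ref[i, j]
    if ((ev$start_dist < thr) == (ev$end_dist < thr)) {
      stop("event (", i, ",", j, "): start/end distances must straddle the ",
           "bond threshold ", signif(thr, 4), " Angstrom", call. = FALSE)
    }
    if (any(c(i, j) %in% active)) {
      stop("atom reused across scripted events", call. = FALSE)
    }
    active <- c(active, i, j)
  }
  # jitter must not flip any unscripted pair: check the threshold margin
  d0 <- distance_matrix(base_geometry)
  n <- n_atoms(base_geometry)
  margin_bound <- 2 * sqrt(3) * vibration_amplitude
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (i %in% active || j %in% active) next
      if (abs(d0[i, j] - r_ref[i, j]) <= margin_bound) {
        stop("jitter amplitude ", vibration_amplitude,
             " can flip unscripted pair (", i, ",", j, ")", call. = FALSE)
      }
    }
  }
  structure(list(base_geometry = base_geometry, events = events,
                 n_frames = as.integer(n_frames),
                 vibration_amplitude = vibration_amplitude,
                 seed = as.integer(seed), scale = scale, r_ref = r_ref),
            class = "mech_event_script")
}

#' Generate the trajectory and ground truth of an event script
#'
#' Scripted pair distances follow the linear interpolation of their window;
#' every unscripted atom receives seeded uniform jitter. The ground-truth
#' table lists, for each scripted event, the exact frame at which the pair
#' distance crosses the bond threshold, computed from the interpolation
#' arithmetic (not from the generated frames).
#'
#' @param script An [event_script()].
#' @return A list with `trajectory` (a [trajectory()]) and `truth` (tibble:
#'   `frame`, `i`, `j`, `kind`).
#' @export
make_trajectory <- function(script) {
  stopifnot(inherits(script, "mech_event_script"))
  base <- script$base_geometry
  n <- n_atoms(base)
  active <- unlist(purrr::map(script$events, "pair"))
  set.seed(script$seed)
  frames <- vector("list", script$n_frames)
  for (f in seq_len(script$n_frames)) {
    xyz <- base$coords
    if (script$vibration_amplitude > 0) {
      jit <- matrix(stats::runif(3 * n, -script$vibration_amplitude,
                                 script$vibration_amplitude), ncol = 3)
      jit[active, ] <- 0
      xyz <- xyz + jit
    }
    for (ev in script$events) {
      i <- ev$pair[1]; j <- ev$pair[2]
      d <- scripted_distance(ev, f)
      u <- base$coords[j, ] - base$coords[i, ]
      u <- u / sqrt(sum(u^2))
      xyz[j, ] <- xyz[i, ] + u * d
    }
    frames[[f]] <- geometry(base$symbols, xyz, label = paste("frame", f))
  }
  truth <- purrr::map_dfr(script$events, function(ev) {
    i <- ev$pair[1]; j <- ev$pair[2]
    thr <- script$r_ref[i, j]
    L <- ev$end_frame - ev$start_frame
    if (ev$start_dist < thr) {
      # bond breaks: first frame with d >= thr
      q <- L * (thr - ev$start_dist) / (ev$end_dist - ev$start_dist)
      frame <- ev$start_frame + ceiling(q)
      kind <- "broken"
    } else {
      # bond forms: first frame with d < thr (strict)
      q <- L * (ev$start_dist - thr) / (ev$start_dist - ev$end_dist)
      frame <- ev$start_frame + floor(q) + 1L
      kind <- "formed"
    }
    tibble::tibble(frame = as.integer(frame), i = i, j = j, kind = kind)
  })
  if (!nrow(truth)) {
    truth <- tibble::tibble(frame = integer(), i = integer(), j = integer(),
                            kind = character())
  }
  truth <- dplyr::arrange(truth, .data$frame, .data$i, .data$j)
  list(trajectory = trajectory(frames), truth = truth)
}

scripted_distance <- function(ev, f) {
  if (f < ev$start_frame) return(ev$start_dist)
  if (f > ev$end_frame) return(ev$end_dist)
  ev$start_dist + (f - ev$start_frame) / (ev$end_frame - ev$start_frame) *
    (ev$end_dist - ev$start_dist)
}

#' Toy reaction networks with analytically known kinetics
#'
#' Ready-made benchmark networks:
#' \describe{
#'   \item{two_channel}{`A -> B` (rate `k1`) and `A -> C` (rate `k2`), both
#'     sinks; branching is exactly `k1/(k1+k2)` : `k2/(k1+k2)`.}
#'   \item{sequential}{`A -> B -> C` with rates `k1`, `k2`; for `k1 = k2 = k`
#'     the intermediate follows `p_B(t) = k t exp(-k t)`.}
#'   \item{catalytic_cycle}{`cat + CO <-> catCO` (dead-end, rates `kf_co`,
#'     `kr_co`), `cat + A -> catA` (rate `k_capture`, rate-limiting),
#'     `catA + B -> cat + P` (rate `k_turnover`): elementary order 1 in A,
#'     near 0 in B, negative in CO (catalyst sequestration).}
#'   \item{vcn_like}{a 3-transition-state, 2-intermediate unimolecular chain
#'     `R -> I1 -> I2 -> P` with ZPE-inclusive energies and frequency sets,
#'     for microcanonical (RRKM) exercises.}
#' }
#' The first three carry explicit per-direction rates, so the analytic
#' kinetics hold independently of temperature; `vcn_like` carries energies
#' and frequencies only.
#'
#' @param kind One of `"two_channel"`, `"sequential"`, `"catalytic_cycle"`,
#'   `"vcn_like"`.
#' @param k1,k2 Rates (1/s) for the first two kinds.
#' @param kf_co,kr_co,k_capture,k_turnover Rates for the catalytic cycle
#'   (pseudo-first-order bases, per molecule pair).
#' @param barriers Energies (kcal/mol) of the three transition states of
#'   `vcn_like`.
#' @return A [reaction_network()].
#' @examples
#' make_toy_network("two_channel", k1 = 2, k2 = 1)
#' @export
make_toy_network <- function(kind = c("two_channel", "sequential",
                                      "catalytic_cycle", "vcn_like"),
                             k1 = 2, k2 = 1, kf_co = 0.01, kr_co = 5,
                             k_capture = 0.001, k_turnover = 0.01,
                             barriers = c(60, 65, 70)) {
  kind <- match.arg(kind)
  fr <- function(n) round(seq(320, 3050, length.out = n))
  switch(kind,
    two_channel = reaction_network(
      wells = list(well("A", 0, fr(6)),
                   well("B", -20, fr(6), sink = TRUE),
                   well("C", -25, fr(6), sink = TRUE)),
      transition_states = list(
        ts_record("TS1", 30, fr(5), c("A", "B"), rate_fwd = k1),
        ts_record("TS2", 31, fr(5), c("A", "C"), rate_fwd = k2))
    ),
    sequential = reaction_network(
      wells = list(well("A", 0, fr(6)),
                   well("B", -10, fr(6)),
                   well("C", -30, fr(6), sink = TRUE)),
      transition_states = list(
        ts_record("TS1", 25, fr(5), c("A", "B"), rate_fwd = k1),
        ts_record("TS2", 20, fr(5), c("B", "C"), rate_fwd = k2))
    ),
    catalytic_cycle = reaction_network(
      wells = list(well("cat", 0, fr(9)), well("CO", 0, fr(1)),
                   well("A", 0, fr(6)), well("B", 0, fr(6)),
                   well("catCO", -15, fr(12)), well("catA", -10, fr(15)),
                   well("P", -35, fr(9), sink = TRUE)),
      transition_states = list(
        ts_record("TS_bind", 2, fr(11), c("cat", "catCO"),
                  rate_fwd = kf_co, rate_rev = kr_co),
        ts_record("TS_capture", 5, fr(14), c("cat", "catA"),
                  rate_fwd = k_capture),
        ts_record("TS_turnover", -2, fr(20), c("catA", "cat"),
                  rate_fwd = k_turnover, release = "P")),
      bimolecular = list(list(ts = "TS_bind", partner = "CO"),
                         list(ts = "TS_capture", partner = "A"),
                         list(ts = "TS_turnover", partner = "B")),
      reference = "cat"
    ),
    vcn_like = reaction_network(
      wells = list(well("R", 0, fr(15)),
                   well("I1", 40, fr(15)),
                   well("I2", 45, fr(15)),
                   well("P", 20, fr(15), sink = TRUE)),
      transition_states = list(
        ts_record("TS1", barriers[1], fr(14), c("R", "I1"), imag_freq = 1200),
        ts_record("TS2", barriers[2], fr(14), c("I1", "I2"), imag_freq = 900),
        ts_record("TS3", barriers[3], fr(14), c("I2", "P"), imag_freq = 1500))
    )
  )
}
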