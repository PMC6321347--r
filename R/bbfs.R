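#' Detect bond breaking/formation events along a trajectory
#'
#' The binary adjacency matrix is monitored frame by frame; a persistent flip
#' of one element is reported as a bond event. Short-lived flips that revert
#' within `debounce` frames are treated as vibrational chatter and discarded.
#' A flipped state that survives to the final frame is kept even if the
#' trajectory ends sooner than `debounce` frames after it (it never reverts).
#'
#' @param traj A [trajectory()].
#' @param scale Bond-detection scale factor (see [build_connectivity()]).
#' @param debounce Minimum persistence, in frames, for a flip to count
#'   (default 5).
#' @return A tibble with one row per event: `frame` (1-based index of the
#'   first frame showing the new state), `i`, `j` (atom indices, `i < j`) and
#'   `kind` (`"formed"` or `"broken"`), sorted by frame.
#' @export
detect_events <- function(traj, scale = 1.2, debounce = 5) {
  stopifnot(inherits(traj, "mech_trajectory"))
  ps <- pair_states(traj, scale)
  out <- list()
  for (p in seq_len(nrow(ps$pairs))) {
    serie <- ps$states[, p]
    if (all(serie == serie[1])) next
    r <- rle(serie)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    current <- r$values[1]
    for (k in seq_along(r$values)[-1]) {
      terminal <- ends[k] == length(serie)
      if (r$lengths[k] < debounce && !terminal) next  # chatter
      if (r$values[k] != current) {
        out[[length(out) + 1L]] <- tibble::tibble(
          frame = starts[k], i = ps$pairs[p, 1], j = ps$pairs[p, 2],
          kind = if (r$values[k] == 1) "formed" else "broken"
        )
        current <- r$values[k]
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(frame = integer(), i = integer(), j = integer(),
                          kind = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$i, .data$j)
}

# per-pair bonded/unbonded time series: F x P matrix plus the pair index table
pair_states <- function(traj, scale) {
  n <- n_atoms(traj$frames[[1]])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  states <- matrix(0L, nrow = n_frames(traj), ncol = nrow(pairs))
  for (f in seq_len(n_frames(traj))) {
    A <- build_connectivity(traj$frames[[f]], scale)$A
    states[f, ] <- A[pairs]
  }
  list(states = states, pairs = pairs)
}

#' Group bond events into reaction windows
#'
#' Events separated by at most `gap` frames belong to one group, so that
#' multi-bond processes (concerted breakings/formations) are treated as a
#' single reaction.
#'
#' @param events Event tibble from [detect_events()] (sorted by frame).
#' @param gap Maximum frame separation within a group (default 10).
#' @return The event tibble with an integer `group` column (groups ordered by
#'   first frame).
#' @export
group_events <- function(events, gap = 10) {
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, group = integer()))
  }
  events <- dplyr::arrange(events, .data$frame, .data$i, .data$j)
  breaks <- c(0, cumsum(diff(events$frame) > gap))
  dplyr::mutate(events, group = as.integer(breaks + 1L))
}

#' Extract transition-state candidate geometries from grouped events
#'
#' For each event group the frame at the temporal midpoint of the group's
#' window is taken as the candidate geometry (a structure with partly
#' formed/broken bonds). The connectivity just before and just after the
#' window (chatter-filtered) gives the reactant and product graphs; groups
#' whose flips cancel out (reactant and product connectivity identical) are
#' dropped as null reactions. Candidates whose window touches the trajectory
#' boundary are kept but flagged.
#'
#' @param traj A [trajectory()].
#' @param grouped_events Output of [group_events()].
#' @inheritParams detect_events
#' @return A list of `mech_ts_candidate` objects, each a list with `window`
#'   (first/last event frame), `frame_mid`, `geometry`, `events` (tibble),
#'   `active_atoms`, `reactant_graph`, `product_graph` and `flagged`.
#' @export
extract_candidates <- function(traj, grouped_events, scale = 1.2) {
  stopifnot(inherits(traj, "mech_trajectory"))
  if (nrow(grouped_events) == 0) return(list())
  nf <- n_frames(traj)
  A_state <- build_connectivity(traj$frames[[1]], scale)$A
  template <- build_connectivity(traj$frames[[1]], scale)
  out <- list()
  for (g in sort(unique(grouped_events$group))) {
    ev <- dplyr::filter(grouped_events, .data$group == g)
    first <- min(ev$frame)
    last <- max(ev$frame)
    A_before <- A_state
    A_after <- apply_events(A_before, ev)
    A_state <- A_after
    if (identical(A_before, A_after)) next  # null reaction
    mid <- (first + last) %/% 2
    cand <- structure(
      list(window = c(first = first, last = last), frame_mid = mid,
           geometry = traj$frames[[mid]], events = ev,
           active_atoms = sort(unique(c(ev$i, ev$j))),
           reactant_graph = graph_with_A(template, A_before),
           product_graph = graph_with_A(template, A_after),
           flagged = first <= 2 || last >= nf - 1),
      class = "mech_ts_candidate"
    )
    stopifnot(identical(apply_events(cand$reactant_graph$A, cand$events),
                        cand$product_graph$A))
    out[[length(out) + 1L]] <- cand
  }
  out
}

# flip the adjacency elements named by an event table
apply_events <- function(A, events) {
  for (k in seq_len(nrow(events))) {
    v <- if (events$kind[k] == "formed") 1 else 0
    A[events$i[k], events$j[k]] <- v
    A[events$j[k], events$i[k]] <- v
  }
  A
}

graph_with_A <- function(template, A) {
  template$A <- A
  template
}

#' @export
print.mech_ts_candidate <- function(x, ...) {
  cat("<mech_ts_candidate> window [", x$window[1], ", ", x$window[2],
      "], ", nrow(x$events), " event(s), active atoms {",
      paste(x$active_atoms, collapse = ", "), "}",
      if (x$flagged) " [boundary]", "\n", sep = "")
  invisible(x)
}

#' Summarize a list of transition-state candidates
#'
#' @param candidates List of `mech_ts_candidate` objects.
#' @return A tibble with one row per candidate: window, midpoint frame,
#'   event count, active atom count and boundary flag.
#' @export
candidate_summary <- function(candidates) {
  purrr::map_dfr(seq_along(candidates), function(k) {
    cd <- candidates[[k]]
    tibble::tibble(candidate = k, first = cd$window[["first"]],
                   last = cd$window[["last"]], frame_mid = cd$frame_mid,
                   n_events = nrow(cd$events),
                   n_active = length(cd$active_atoms), flagged = cd$flagged)
  })
}
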