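# Shared fixture builders and independent oracles. Everything is generated in
# code; callers set the RNG seed.

# random cloud of light atoms in a box; clustered enough to give a mix of
# bonded and fragmented structures
random_geometry <- function(n = NULL) {
  n <- n %||% sample(2:12, 1)
  symbols <- sample(c("H", "C", "N", "O"), n, replace = TRUE)
  side <- 1.6 * n^(1 / 3)
  geometry(symbols, matrix(stats::runif(3 * n, 0, side), ncol = 3))
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n = NULL, p = 0.25) {
  n <- n %||% sample(2:15, 1)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# independent component count through igraph (traversal-based oracle)
igraph_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  igraph::components(g)$no
}

# brute-force enumeration oracle for harmonic state counting:
# number of occupation vectors n with sum(n * freqs) <= E
enumerate_states <- function(freqs, E) {
  if (E < 0) return(0)
  if (!length(freqs)) return(1)
  nu <- freqs[1]
  total <- 0
  for (n1 in 0:floor(E / nu)) {
    total <- total + enumerate_states(freqs[-1], E - n1 * nu)
  }
  total
}

# scripted multi-event fixture: each event gets its own isolated atom pair,
# so crossing frames are exactly predictable; returns script + expectations
random_event_script <- function(n_events = NULL, n_frames = 120,
                                amplitude = 0.01) {
  n_events <- n_events %||% sample(1:3, 1)
  symbols <- character(0)
  coords <- NULL
  events <- list()
  pt <- periodic_table()
  for (k in seq_len(n_events)) {
    pair_sym <- sample(c("H", "C", "O", "N"), 2, replace = TRUE)
    r1 <- pt$r_cov[match(pair_sym[1], pt$symbol)]
    r2 <- pt$r_cov[match(pair_sym[2], pt$symbol)]
    thr <- 1.2 * (r1 + r2)
    breaking <- stats::runif(1) < 0.5
    if (breaking) {
      start_dist <- stats::runif(1, 0.55, 0.85) * thr
      end_dist <- stats::runif(1, 1.6, 3.0) * thr
    } else {
      start_dist <- stats::runif(1, 1.6, 3.0) * thr
      end_dist <- stats::runif(1, 0.5, 0.8) * thr
    }
    base_x <- 60 * (k - 1)  # pairs far apart: no cross-pair bonds
    i <- length(symbols) + 1L
    symbols <- c(symbols, pair_sym)
    coords <- rbind(coords,
                    c(base_x, 0, 0),
                    c(base_x + start_dist, 0, 0))
    w0 <- sample(seq(10, n_frames - 40, by = 1), 1)
    events[[k]] <- list(pair = c(i, i + 1L),
                        start_frame = w0,
                        end_frame = w0 + sample(10:25, 1),
                        start_dist = start_dist, end_dist = end_dist)
  }
  event_script(geometry(symbols, coords), events, n_frames = n_frames,
               vibration_amplitude = amplitude,
               seed = sample.int(1e6, 1))
}

# candidate wrapper for screening tests when only a geometry matters
as_candidate <- function(geom, reactant_A = NULL, product_A = NULL,
                         scale = 1.2) {
  cg <- build_connectivity(geom, scale)
  structure(
    list(window = c(first = 1, last = 1), frame_mid = 1, geometry = geom,
         events = tibble::tibble(), active_atoms = integer(),
         reactant_graph = graph_with_matrix(cg, reactant_A %||% cg$A),
         product_graph = graph_with_matrix(cg, product_A %||% cg$A),
         flagged = FALSE),
    class = "mech_ts_candidate"
  )
}

graph_with_matrix <- function(template, A) {
  template$A <- A
  template
}

`%||%` <- rlang::`%||%`

test_path_extdata <- function(f) {
  system.file("extdata", f, package = "mechkit", mustWork = TRUE)
}
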