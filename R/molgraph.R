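#' Build the binary connectivity graph of a geometry
#'
#' Two atoms are bonded when their distance is below a reference length taken
#' as `scale` times the sum of their covalent radii; the default `scale = 1.2`
#' is the usual 20%-over-covalent-radii criterion. The result is a binary
#' symmetric adjacency matrix with zero diagonal.
#'
#' @param geom A [geometry()].
#' @param scale Multiplier on the covalent-radius sum (> 1 recommended;
#'   default 1.2).
#' @return An object of class `mech_conn_graph`: list with `A` (binary N x N
#'   matrix), `r_ref` (reference distances, Angstrom), `scale`, `symbols`, `Z`.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' build_connectivity(h2)$A
#' @export
build_connectivity <- function(geom, scale = 1.2) {
  stopifnot(inherits(geom, "mech_geometry"))
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  n <- n_atoms(geom)
  r_ref <- scale * outer(geom$r_cov, geom$r_cov, `+`)
  diag(r_ref) <- 0
  d <- unname(distance_matrix(geom))
  A <- (d < r_ref) * 1
  diag(A) <- 0
  structure(
    list(A = A, r_ref = r_ref, scale = scale,
         symbols = geom$symbols, Z = geom$Z),
    class = "mech_conn_graph"
  )
}

#' Build the weighted adjacency graph of a geometry
#'
#' Off-diagonal entries are the smooth bond-order surrogate
#' `(1 - x^n) / (1 - x^m)` with `x = r_ij / r_ref_ij`. For the default
#' exponents `(n, m) = (6, 12)` this simplifies to the closed form
#' `1 / (1 + x^6)`, which is used everywhere (it is continuous through the
#' removable singularity at `x = 1`). For other exponent pairs the removable
#' singularity is filled with the algebraic limit `n/m`.
#'
#' @inheritParams build_connectivity
#' @param n_exp Numerator exponent (default 6).
#' @param m_exp Denominator exponent (default 12).
#' @return An object of class `mech_weighted_graph`: list with `W` (weights in
#'   `[0, 1]`), `A` (the binary graph at the same scale, used for component
#'   analysis), `r_ref`, `n_exp`, `m_exp`, `symbols`, `Z`.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.744, 0, 0)))
#' build_weighted(h2)$W[1, 2]  # exactly 0.5 at r = r_ref
#' @export
build_weighted <- function(geom, n_exp = 6, m_exp = 12, scale = 1.2) {
  cg <- build_connectivity(geom, scale)
  d <- unname(distance_matrix(geom))
  off <- upper.tri(d)
  if (any(d[off] == 0)) stop("coincident atoms (zero interatomic distance)",
                             call. = FALSE)
  x <- d / cg$r_ref
  diag(x) <- 0
  W <- weighted_adjacency_value(x, n_exp, m_exp)
  diag(W) <- 0
  structure(
    list(W = W, A = cg$A, r_ref = cg$r_ref, n_exp = n_exp, m_exp = m_exp,
         scale = scale, symbols = geom$symbols, Z = geom$Z),
    class = "mech_weighted_graph"
  )
}

#' Weighted-adjacency profile as a function of reduced distance
#'
#' Evaluates the pair weight at reduced distance `x = r / r_ref`. Exposed so
#' the functional form can be inspected and tested directly.
#'
#' @param x Reduced distance(s), `r / r_ref`.
#' @param n_exp,m_exp Exponents as in [build_weighted()].
#' @return Numeric vector of weights.
#' @export
weighted_adjacency_value <- function(x, n_exp = 6, m_exp = 12) {
  if (n_exp <= 0 || m_exp <= 0) stop("exponents must be positive", call. = FALSE)
  if (m_exp == 2 * n_exp) {
    return(1 / (1 + x^n_exp))
  }
  w <- (1 - x^n_exp) / (1 - x^m_exp)
  # removable singularity at x = 1: algebraic limit n/m
  w[abs(x - 1) < 1e-12] <- n_exp / m_exp
  w
}

adjacency_of <- function(graph) {
  if (inherits(graph, "mech_conn_graph")) graph$A
  else if (inherits(graph, "mech_weighted_graph")) graph$W
  else if (is.matrix(graph)) graph
  else stop("expected a connectivity or weighted graph", call. = FALSE)
}

#' Atomic-number-labeled adjacency matrix
#'
#' Copies the (binary or weighted) adjacency off-diagonal and places
#' `1 + Z_i / 10` on the diagonal, so that the eigenvalue spectrum is
#' invariant only under permutations of like atoms. This is the descriptor
#' used for structure deduplication: unlike SPRINT coordinates it
#' distinguishes structures in which two non-equivalent atoms swap positions.
#'
#' @param graph A `mech_conn_graph` or `mech_weighted_graph`.
#' @return An object of class `mech_labeled_graph`: list with `AZ` (matrix)
#'   and `weighted` (logical).
#' @examples
#' ch4 <- geometry("C", matrix(0, 1, 3))
#' build_labeled(build_connectivity(ch4))$AZ  # carbon diagonal: 1.6
#' @export
build_labeled <- function(graph) {
  weighted <- inherits(graph, "mech_weighted_graph")
  M <- adjacency_of(graph)
  Z <- graph$Z
  if (is.null(Z) || length(Z) != nrow(M)) {
    stop("graph dimension does not match its atom list", call. = FALSE)
  }
  diag(M) <- 1 + Z / 10
  structure(list(AZ = M, weighted = weighted), class = "mech_labeled_graph")
}

#' Sorted eigenvalue spectrum of a labeled adjacency matrix
#' @param lg A `mech_labeled_graph` (or the matrix itself).
#' @return Numeric vector, ascending.
#' @export
labeled_spectrum <- function(lg) {
  M <- if (inherits(lg, "mech_labeled_graph")) lg$AZ else lg
  sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Laplacian spectrum, fragment count and spectral gap
#'
#' Forms the graph Laplacian `L = D - A` (degree matrix minus adjacency; for a
#' weighted graph the degree is the row sum of weights) and diagonalizes it.
#' For an unweighted graph the multiplicity of the zero eigenvalue equals the
#' number of connected fragments; for a weighted graph weights never vanish
#' exactly, so eigenvalues below an upper threshold (`zero_tol`) are counted
#' as fragmentation modes. The spectral gap -- the smallest eigenvalue above
#' the threshold -- is small for weakly bound (van der Waals) assemblies.
#'
#' @param graph A `mech_conn_graph` or `mech_weighted_graph` (a bare symmetric
#'   matrix is also accepted and treated as unweighted).
#' @param zero_tol Eigenvalues below this count as zero. Default `1e-6` for
#'   unweighted graphs, `1e-4` for weighted ones.
#' @return An object of class `mech_spectral_summary`: list with
#'   `eigenvalues` (ascending), `n_fragments`, `spectral_gap` (`NA` if every
#'   eigenvalue is below tolerance), `weighted`, `zero_tol`.
#' @examples
#' h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' laplacian_spectrum(build_connectivity(h2))
#' @export
laplacian_spectrum <- function(graph, zero_tol = NULL) {
  weighted <- inherits(graph, "mech_weighted_graph")
  M <- adjacency_of(graph)
  if (!isSymmetric(unname(M), tol = 1e-10)) {
    stop("adjacency matrix must be symmetric", call. = FALSE)
  }
  if (is.null(zero_tol)) zero_tol <- if (weighted) 1e-4 else 1e-6
  L <- diag(rowSums(M), nrow = nrow(M)) - M
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  n_frag <- sum(ev < zero_tol)
  nonzero <- ev[ev >= zero_tol]
  structure(
    list(eigenvalues = ev,
         n_fragments = max(n_frag, 1L),
         spectral_gap = if (length(nonzero)) nonzero[1] else NA_real_,
         weighted = weighted, zero_tol = zero_tol),
    class = "mech_spectral_summary"
  )
}

#' @export
print.mech_spectral_summary <- function(x, ...) {
  cat("<mech_spectral_summary> ", length(x$eigenvalues), " eigenvalues, ",
      x$n_fragments, " fragment(s), gap ",
      format(x$spectral_gap, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Count molecular fragments of a geometry
#'
#' Fragment count from the multiplicity of (near-)zero Laplacian eigenvalues
#' of the binary connectivity graph, with per-atom fragment labels from a
#' breadth-first traversal of the same graph. The two routes agree by
#' construction of the Laplacian; both are exposed so they can be
#' cross-checked.
#'
#' @inheritParams build_connectivity
#' @param zero_tol Zero tolerance for Laplacian eigenvalues.
#' @return List with `n_fragments` (integer) and `labels` (integer vector,
#'   fragments numbered by first atom index).
#' @export
count_fragments <- function(geom, scale = 1.2, zero_tol = 1e-6) {
  cg <- build_connectivity(geom, scale)
  spec <- laplacian_spectrum(cg, zero_tol)
  labels <- graph_components(cg$A)
  if (max(labels) != spec$n_fragments) {
    warning("Laplacian zero count (", spec$n_fragments,
            ") and traversal component count (", max(labels),
            ") disagree; returning the Laplacian count")
  }
  list(n_fragments = spec$n_fragments, labels = labels)
}

# connected components by BFS over a (0/1 or weighted-nonzero) adjacency
graph_components <- function(A) {
  n <- nrow(A)
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] != 0 & labels == 0L)
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

#' SPRINT coordinates of a weighted molecular graph
#'
#' Per-atom spectral descriptors built from the principal eigenpair of the
#' weighted adjacency matrix: `s_i = sqrt(N) * lambda_max * v_i`, with `v` the
#' non-negative unit principal eigenvector (Perron-Frobenius). They are
#' invariant under rotation, translation and atom permutation, which makes
#' them useful for spotting recurring structures along trajectories. For a
#' fragmented system the descriptor is computed per connected component (where
#' the Perron-Frobenius guarantee applies) and concatenated.
#'
#' @param wgraph A `mech_weighted_graph`.
#' @param w_min Pair weights below this are treated as absent when splitting
#'   the graph into components (default `1e-4`, the same scale as the
#'   weighted fragmentation threshold).
#' @return A tibble with columns `atom` (original index), `element` and
#'   `sprint`, sorted by element then descriptor value (so like-atom
#'   permutations yield identical tables up to the `atom` column).
#' @export
sprint_coordinates <- function(wgraph, w_min = 1e-4) {
  stopifnot(inherits(wgraph, "mech_weighted_graph"))
  n <- nrow(wgraph$W)
  if (n < 1) stop("empty graph", call. = FALSE)
  comp <- graph_components((wgraph$W > w_min) * 1)
  s <- numeric(n)
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    if (length(idx) == 1) { s[idx] <- 0; next }
    sub <- wgraph$W[idx, idx, drop = FALSE]
    ed <- eigen(sub, symmetric = TRUE)
    v <- ed$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v <- abs(v)  # Perron vector is non-negative; clean numerical noise
    s[idx] <- sqrt(length(idx)) * ed$values[1] * v
  }
  out <- tibble::tibble(atom = seq_len(n), element = wgraph$symbols,
                        sprint = s)
  dplyr::arrange(out, .data$element, .data$sprint)
}
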