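#' Remove redundant transition-state candidates
#'
#' Two candidates are duplicates when the sorted eigenvalue spectra of their
#' atomic-number-labeled weighted adjacency matrices (see [build_labeled()])
#' agree element-wise within `tol`. The spectrum is invariant under rotation,
#' translation and like-atom permutation, but changes when non-equivalent
#' atoms swap positions (the diagonal labels travel with the atoms while the
#' distance-based weights stay with the sites), which is exactly what
#' distinguishes genuinely different structures from re-encounters of the
#' same one. The first
#' candidate (by input order, i.e. trajectory order) of each duplicate set is
#' kept.
#'
#' @param candidates List of `mech_ts_candidate` objects (or of
#'   [geometry()] objects) sharing one atom composition.
#' @param tol Per-eigenvalue absolute tolerance (default `1e-3`).
#' @param scale Bond-detection scale factor.
#' @return The de-duplicated sublist, with an attribute `"signature_index"`
#'   giving, for every input candidate, the index of the kept representative.
#' @export
dedup <- function(candidates, tol = 1e-3, scale = 1.2) {
  if (!length(candidates)) return(candidates)
  geoms <- purrr::map(candidates, candidate_geometry)
  comp <- purrr::map(geoms, function(g) sort(g$symbols))
  if (!all(purrr::map_lgl(comp, identical, comp[[1]]))) {
    stop("candidates differ in atom composition", call. = FALSE)
  }
  spectra <- purrr::map(geoms, function(g) {
    labeled_spectrum(build_labeled(build_weighted(g, scale = scale)))
  })
  rep_of <- integer(length(candidates))
  keep <- integer(0)
  for (k in seq_along(spectra)) {
    hit <- 0L
    for (r in keep) {
      if (max(abs(spectra[[k]] - spectra[[r]])) <= tol) { hit <- r; break }
    }
    if (hit == 0L) { keep <- c(keep, k); hit <- k }
    rep_of[k] <- hit
  }
  out <- candidates[keep]
  attr(out, "signature_index") <- rep_of
  out
}

candidate_geometry <- function(x) {
  if (inherits(x, "mech_ts_candidate")) x$geometry
  else if (inherits(x, "mech_geometry")) x
  else stop("expected a TS candidate or a geometry", call. = FALSE)
}

#' Prescreen fragmented and van der Waals candidates
#'
#' Discards candidates whose weighted Laplacian spectrum indicates more than
#' one fragment (eigenvalues below `lambda1w_max` beyond the trivial zero) or
#' a spectral gap below `gap_min` -- the signature of weakly bound van der
#' Waals assemblies, which are usually irrelevant to the kinetics.
#'
#' @inheritParams dedup
#' @param lambda1w_max Upper threshold under which a weighted Laplacian
#'   eigenvalue counts as a fragmentation mode (default `1e-4`).
#' @param gap_min Minimum weighted spectral gap for a candidate to be kept
#'   (default `0.1`; van der Waals contacts at 1.7 or more times the bond
#'   reference distance give pair weights below 0.05, covalent bonds give
#'   about 0.5 or more).
#' @return A list with `kept` and `discarded` (sublists of the input) and
#'   `decisions`, a tibble with per-candidate `n_fragments`, `spectral_gap`
#'   and the `kept` flag.
#' @export
prescreen_fragmented <- function(candidates, lambda1w_max = 1e-4,
                                 gap_min = 0.1, scale = 1.2) {
  dec <- purrr::map_dfr(seq_along(candidates), function(k) {
    g <- candidate_geometry(candidates[[k]])
    sp <- laplacian_spectrum(build_weighted(g, scale = scale),
                             zero_tol = lambda1w_max)
    tibble::tibble(candidate = k, n_fragments = sp$n_fragments,
                   spectral_gap = sp$spectral_gap,
                   kept = sp$n_fragments <= 1 &&
                     !is.na(sp$spectral_gap) && sp$spectral_gap >= gap_min)
  })
  if (!length(candidates)) {
    dec <- tibble::tibble(candidate = integer(), n_fragments = integer(),
                          spectral_gap = double(), kept = logical())
  }
  list(kept = candidates[dec$kept], discarded = candidates[!dec$kept],
       decisions = dec)
}

#' Cluster transition-state candidates by averaged adjacency spectrum
#'
#' The signature of a candidate is the sorted eigenvalue spectrum of the
#' labeled average `(A_reactant + A_product) / 2` of its reactant and product
#' adjacency matrices -- a transition-state connectivity fingerprint in which
#' forming/breaking bonds contribute 1/2. Candidates whose signatures agree
#' element-wise within `tol` fall in one cluster; the member closest (in
#' Euclidean signature distance) to the cluster mean is chosen as the
#' representative, so only one structure per distinct reaction needs
#' downstream refinement. Ties go to the earliest candidate.
#'
#' @param candidates List of `mech_ts_candidate` objects carrying
#'   `reactant_graph` and `product_graph`.
#' @param tol Per-eigenvalue absolute tolerance (default `1e-3`).
#' @return A list of `mech_candidate_cluster` objects: `members` (input
#'   indices), `representative` (input index) and `signature` (mean sorted
#'   spectrum).
#' @export
cluster_candidates <- function(candidates, tol = 1e-3) {
  if (!length(candidates)) return(list())
  sigs <- purrr::map(candidates, function(cd) {
    if (is.null(cd$reactant_graph) || is.null(cd$product_graph)) {
      stop("candidates must carry reactant and product graphs", call. = FALSE)
    }
    M <- (cd$reactant_graph$A + cd$product_graph$A) / 2
    diag(M) <- 1 + cd$reactant_graph$Z / 10
    labeled_spectrum(M)
  })
  cluster_of <- integer(length(sigs))
  refs <- list()
  for (k in seq_along(sigs)) {
    hit <- 0L
    for (c_id in seq_along(refs)) {
      if (max(abs(sigs[[k]] - refs[[c_id]])) <= tol) { hit <- c_id; break }
    }
    if (hit == 0L) { refs[[length(refs) + 1L]] <- sigs[[k]]; hit <- length(refs) }
    cluster_of[k] <- hit
  }
  purrr::map(seq_along(refs), function(c_id) {
    members <- which(cluster_of == c_id)
    centroid <- Reduce(`+`, sigs[members]) / length(members)
    d <- purrr::map_dbl(sigs[members], function(s) sqrt(sum((s - centroid)^2)))
    structure(
      list(members = members, representative = members[which.min(d)],
           signature = centroid),
      class = "mech_candidate_cluster"
    )
  })
}

#' @export
print.mech_candidate_cluster <- function(x, ...) {
  cat("<mech_candidate_cluster> ", length(x$members), " member(s), ",
      "representative #", x$representative, "\n", sep = "")
  invisible(x)
}
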