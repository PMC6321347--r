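#' Covalent radii and atomic numbers
#'
#' Bundled single-bond covalent radii (Cordero-type consensus values, in
#' Angstrom) for elements commonly met in gas-phase mechanism studies,
#' including the first two transition series. The bond criterion compares an
#' interatomic distance against `scale * (r_i + r_j)` built from this table.
#'
#' @return A tibble with columns `symbol`, `Z` (atomic number) and `r_cov`
#'   (covalent radius, Angstrom).
#' @examples
#' periodic_table()
#' @export
periodic_table <- function() {
  tibble::tibble(
    symbol = c(
      "H", "He",
      "Li", "Be", "B", "C", "N", "O", "F", "Ne",
      "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
      "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
      "Ga", "Ge", "As", "Se", "Br", "Kr",
      "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
      "In", "Sn", "Sb", "Te", "I", "Xe",
      "Cs", "Ba", "Pt", "Au", "Hg", "Pb"
    ),
    Z = c(
      1L, 2L,
      3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
      11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L,
      19L, 20L, 21L, 22L, 23L, 24L, 25L, 26L, 27L, 28L, 29L, 30L,
      31L, 32L, 33L, 34L, 35L, 36L,
      37L, 38L, 39L, 40L, 41L, 42L, 43L, 44L, 45L, 46L, 47L, 48L,
      49L, 50L, 51L, 52L, 53L, 54L,
      55L, 56L, 78L, 79L, 80L, 82L
    ),
    r_cov = c(
      0.31, 0.28,
      1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
      1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06,
      2.03, 1.76, 1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
      1.22, 1.20, 1.19, 1.20, 1.20, 1.16,
      2.20, 1.95, 1.90, 1.75, 1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44,
      1.42, 1.39, 1.39, 1.38, 1.39, 1.40,
      2.44, 2.15, 1.36, 1.36, 1.32, 1.46
    )
  )
}

# symbol -> row of the periodic table; errors name the offending symbol
lookup_elements <- function(symbols) {
  pt <- periodic_table()
  idx <- match(symbols, pt$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pt[idx, ]
}
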