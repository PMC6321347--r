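#' Create a molecular geometry
#'
#' A geometry is an ordered set of atoms with Cartesian coordinates in
#' Angstrom. Element symbols are validated against the bundled
#' [periodic_table()] so every atom carries an atomic number and covalent
#' radius.
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param label Optional free-text label.
#' @return An object of class `mech_geometry`: a list with `symbols`, `Z`,
#'   `r_cov`, `coords` (N x 3 matrix) and `label`.
#' @examples
#' h2o <- geometry(c("O", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0)))
#' h2o
#' @export
geometry <- function(symbols, coords, label = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) < 1) stop("geometry needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(symbols)) {
    stop("coords must have one row per atom (", length(symbols), " atoms, ",
         nrow(coords), " rows)", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  el <- lookup_elements(symbols)
  structure(
    list(symbols = as.character(symbols), Z = el$Z, r_cov = el$r_cov,
         coords = coords, label = as.character(label)[1]),
    class = "mech_geometry"
  )
}

#' @export
print.mech_geometry <- function(x, ...) {
  cat("<mech_geometry> ", length(x$symbols), " atoms",
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat("  ", paste(x$symbols, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom A [geometry()].
#' @return Integer atom count.
#' @export
n_atoms <- function(geom) length(geom$symbols)

#' Pairwise distance matrix of a geometry
#' @param geom A [geometry()].
#' @return N x N symmetric matrix of Euclidean distances (Angstrom).
#' @export
distance_matrix <- function(geom) {
  as.matrix(stats::dist(geom$coords))
}

#' Read and write XYZ geometry files
#'
#' Standard XYZ dialect: line 1 the atom count, line 2 a comment, then one
#' `symbol x y z` line per atom. [read_xyz()] returns the first frame of a
#' file; [read_trajectory()] reads all frames of a multi-frame file and
#' validates that atom count and element order are constant.
#'
#' @param path File path.
#' @param geom A [geometry()] (for the writer).
#' @param traj A [trajectory()] (for the writer).
#' @param digits Coordinate decimals written (default 6).
#' @return [read_xyz()]: a `mech_geometry`. [read_trajectory()]: a
#'   `mech_trajectory`.
#' @name xyz_io
NULL

parse_xyz_frames <- function(lines, path) {
  lines <- sub("\\s+$", "", lines)
  frames <- list()
  i <- 1L
  nframe <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    nframe <- nframe + 1L
    if (is.na(n) || n < 1) {
      stop("frame ", nframe, " of '", path, "': invalid atom count line: '",
           lines[i], "'", call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("frame ", nframe, " of '", path, "' is truncated", call. = FALSE)
    }
    label <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4)) {
      stop("frame ", nframe, " of '", path, "': malformed atom line",
           call. = FALSE)
    }
    symbols <- vapply(toks, `[`, "", 1L)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(coords)) {
      stop("frame ", nframe, " of '", path, "': non-numeric coordinates",
           call. = FALSE)
    }
    frames[[nframe]] <- geometry(symbols, coords, label = label)
    i <- i + 2L + n
  }
  if (nframe == 0L) stop("no frames found in '", path, "'", call. = FALSE)
  frames
}

#' @rdname xyz_io
#' @export
read_xyz <- function(path) {
  parse_xyz_frames(readLines(path), path)[[1L]]
}

#' @rdname xyz_io
#' @export
write_xyz <- function(geom, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  write_xyz_frame(geom, con, digits)
  invisible(path)
}

write_xyz_frame <- function(geom, con, digits) {
  writeLines(as.character(n_atoms(geom)), con)
  writeLines(geom$label, con)
  writeLines(sprintf(paste0("%-3s % .", digits, "f % .", digits, "f % .",
                            digits, "f"),
                     geom$symbols, geom$coords[, 1], geom$coords[, 2],
                     geom$coords[, 3]), con)
}

#' Create a trajectory from a list of geometries
#'
#' @param frames List of [geometry()] objects sharing atom count and element
#'   sequence.
#' @param dt Optional time step between frames (fs), stored as metadata.
#' @return An object of class `mech_trajectory`.
#' @export
trajectory <- function(frames, dt = NA_real_) {
  if (length(frames) < 2) stop("a trajectory needs at least 2 frames", call. = FALSE)
  ref <- frames[[1]]$symbols
  for (k in seq_along(frames)) {
    if (!identical(frames[[k]]$symbols, ref)) {
      stop("frame ", k, " has a different atom count or element order",
           call. = FALSE)
    }
  }
  structure(list(frames = frames, dt = dt), class = "mech_trajectory")
}

#' @export
print.mech_trajectory <- function(x, ...) {
  cat("<mech_trajectory> ", length(x$frames), " frames x ",
      n_atoms(x$frames[[1]]), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname xyz_io
#' @export
read_trajectory <- function(path) {
  trajectory(parse_xyz_frames(readLines(path), path))
}

#' @rdname xyz_io
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) write_xyz_frame(f, con, digits)
  invisible(path)
}
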