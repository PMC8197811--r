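#' Construct a molecular geometry
#'
#' A geometry is an ordered list of atoms with Cartesian coordinates in
#' Angstrom. Atom indices are 1-based everywhere in this package, following
#' the convention of XYZ files and quantum-chemistry programs.
#'
#' @param elements Character vector of chemical symbols, one per atom.
#' @param coords Numeric matrix with one row per atom and three columns
#'   (x, y, z), in Angstrom.
#' @param comment Single comment string carried on the second line of an XYZ
#'   file; may hold `key=value` annotations such as `energy=15.4`.
#' @return An object of class `"xyz_geometry"`.
#' @examples
#' g <- geometry(c("O", "C"), rbind(c(0, 0, 0), c(0, 0, 2.04)))
#' bond_length(g, 1, 2)
#' @export
geometry <- function(elements, coords, comment = "") {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    stop("a geometry needs at least one atom", call. = FALSE)
  if (any(!nzchar(elements)) || anyNA(elements))
    stop("element symbols must be non-empty", call. = FALSE)
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching length(elements)",
         call. = FALSE)
  if (any(!is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  structure(
    list(elements = elements,
         coords = unname(coords),
         comment = as.character(comment)[1L]),
    class = "xyz_geometry"
  )
}

#' @export
print.xyz_geometry <- function(x, ...) {
  cat(sprintf("<xyz_geometry: %d atoms>\n", length(x$elements)))
  if (nzchar(x$comment)) cat("  comment:", x$comment, "\n")
  n <- min(length(x$elements), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %3d %-2s %10.6f %10.6f %10.6f\n", i, x$elements[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  if (length(x$elements) > n) cat("  ...\n")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g An `"xyz_geometry"`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) {
  stopifnot(inherits(g, "xyz_geometry"))
  length(g$elements)
}

#' Read a geometry from a standard XYZ file
#'
#' Standard XYZ layout: first line atom count, second line free-text comment,
#' then one `element x y z` row per atom (coordinates in Angstrom).
#'
#' @param path Path to an XYZ file.
#' @return An `"xyz_geometry"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    stop("XYZ file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("XYZ parse error in '", path, "': need at least 3 lines (count, ",
         "comment, one atom row)", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error in '", path, "' line 1: atom count '",
         trimws(lines[1L]), "' is not a positive integer", call. = FALSE)
  if (length(lines) < 2L + n)
    stop("XYZ parse error in '", path, "': count line says ", n,
         " atoms but only ", length(lines) - 2L, " atom rows present",
         call. = FALSE)
  comment <- lines[2L]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error in '", path, "' line ", ln,
           ": expected 'element x y z'", call. = FALSE)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error in '", path, "' line ", ln,
           ": non-numeric coordinate", call. = FALSE)
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  geometry(elements, coords, comment = comment)
}

#' Write a geometry to a standard XYZ file
#'
#' Coordinates are written with 6 decimal places, so write/read round trips
#' are stable to 1e-6 Angstrom and output bytes are reproducible.
#'
#' @param g An `"xyz_geometry"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(g, path) {
  stopifnot(inherits(g, "xyz_geometry"))
  rows <- sprintf("%-2s %14.6f %14.6f %14.6f", g$elements,
                  g$coords[, 1], g$coords[, 2], g$coords[, 3])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(as.character(length(g$elements)), g$comment, rows),
             con = con, sep = "\n")
  invisible(path)
}

#' Distance between two atoms
#'
#' Euclidean distance between atoms `i` and `j` of a geometry, in Angstrom.
#' Symmetric in its index arguments.
#'
#' @param g An `"xyz_geometry"`.
#' @param i,j 1-based atom indices, `i != j`.
#' @return Bond length in Angstrom.
#' @export
bond_length <- function(g, i, j) {
  stopifnot(inherits(g, "xyz_geometry"))
  n <- length(g$elements)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 1L || j < 1L || i > n || j > n)
    stop("atom index out of range [1, ", n, "]: got (", i, ", ", j, ")",
         call. = FALSE)
  if (i == j)
    stop("bond_length requires two distinct atoms", call. = FALSE)
  sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
}
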