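# Atom sets: reading XYZR / PQR / PDB(+radius table), construction and
# coordinate perturbation.

#' Construct an atom set
#'
#' @param x,y,z Atom center coordinates (Angstrom).
#' @param radius Atom radii (Angstrom, > 0).
#' @param provenance Optional character note (file of origin, radius rule).
#' @return A `data.frame` of class `atom_set` with columns `x, y, z, radius`.
#' @export
atom_set <- function(x, y, z, radius, provenance = "constructed") {
  a <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  radius = as.numeric(radius))
  if (nrow(a) < 1L) stop("an atom set needs at least one atom")
  if (any(!is.finite(as.matrix(a)))) stop("non-finite atom coordinates/radii")
  if (any(a$radius <= 0)) stop("atom radii must be positive")
  attr(a, "provenance") <- provenance
  class(a) <- c("atom_set", "data.frame")
  a
}

atom_centers <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# default element radii used for plain PDB input (Bondi van der Waals set)
default_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, FE = 1.40, ZN = 1.39,
    MG = 1.73, CA = 2.00, "NA" = 2.27, K = 2.75)
}

#' Read an atom set from file
#'
#' Supported formats: `xyzr` (whitespace `x y z r` per line), `pqr`
#' (whitespace PDB dialect; the charge column is ignored, the radius kept)
#' and `pdb` (wwPDB columns; radii assigned per element from
#' `radius_table`).  Malformed records and non-positive radii raise an error
#' naming the offending line or atom names.
#'
#' @param path Input file.
#' @param format One of `"xyzr"`, `"pqr"`, `"pdb"`.
#' @param radius_table Named vector mapping element symbols (upper case) to
#'   radii, used for `format = "pdb"`; defaults to a Bondi-type table.
#' @return An [atom_set()].
#' @export
read_atoms <- function(path, format = c("xyzr", "pqr", "pdb"),
                       radius_table = default_radius_table()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyzr") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no atoms in ", path)
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- which(vapply(fields, length, 1L) < 4L)
    if (length(bad))
      stop("malformed xyzr record at line ", bad[1L], " of ", path)
    m <- t(vapply(fields, function(f) as.numeric(f[1:4]), numeric(4L)))
    if (any(!is.finite(m)))
      stop("non-numeric xyzr record at line ",
           which(!is.finite(rowSums(m)))[1L], " of ", path)
    if (any(m[, 4L] <= 0))
      stop("non-positive radius at line ", which(m[, 4L] <= 0)[1L])
    return(atom_set(m[, 1L], m[, 2L], m[, 3L], m[, 4L],
                    provenance = paste0("xyzr:", path)))
  }
  if (format == "pqr") {
    p <- bio3d::read.pqr(path)
    at <- p$atom
    # bio3d maps the PQR charge to "o" and the radius to "b"
    r <- suppressWarnings(as.numeric(at$b))
    if (all(is.na(r))) stop("no radius column parsed from ", path)
    if (any(!is.finite(r) | r <= 0))
      stop("non-positive or missing radius for atom serial(s): ",
           paste(utils::head(at$eleno[!is.finite(r) | r <= 0]), collapse = ", "))
    return(atom_set(at$x, at$y, at$z, r, provenance = paste0("pqr:", path)))
  }
  # pdb + radius table
  p <- bio3d::read.pdb(path)
  at <- p$atom
  elem <- toupper(trimws(at$elesy))
  miss <- !nzchar(elem)
  elem[miss] <- toupper(substr(trimws(at$elety[miss]), 1L, 1L))
  r <- radius_table[elem]
  if (any(is.na(r))) {
    un <- unique(at$elety[is.na(r)])
    stop("no radius rule for atom name(s): ", paste(un, collapse = ", "))
  }
  atom_set(at$x, at$y, at$z, as.numeric(r),
           provenance = paste0("pdb:", path))
}

#' Write an atom set to an XYZR file
#'
#' @param atoms An [atom_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyzr <- function(atoms, path) {
  m <- cbind(atom_centers(atoms), atoms$radius)
  utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Randomly perturb atom positions
#'
#' Each coordinate is shifted by an independent uniform draw in
#' `[-magnitude, magnitude]`; deterministic for a fixed seed.  The default
#' magnitude, `1e-4` Angstrom, is the largest digit that is not significant
#' in PDB coordinates (three decimals) and is used to break cospherical /
#' coplanar degeneracies before the weighted Delaunay triangulation.
#'
#' @param atoms An [atom_set()].
#' @param magnitude Maximum absolute shift per coordinate (Angstrom, >= 0).
#' @param seed Integer seed.
#' @return A perturbed [atom_set()].
#' @export
perturb_atoms <- function(atoms, magnitude = 1e-4, seed = 1L) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(atoms)
  n <- nrow(atoms)
  shifts <- with_seed(seed, function()
    matrix(stats::runif(3L * n, -magnitude, magnitude), ncol = 3L))
  out <- atoms
  out$x <- atoms$x + shifts[, 1L]
  out$y <- atoms$y + shifts[, 2L]
  out$z <- atoms$z + shifts[, 3L]
  out
}
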