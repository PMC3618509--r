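# Gaussian ("blobby") surface: isosurface of a sum of atom-centered
# Gaussian kernels
#
#     field(x) = sum_i exp( B * ( |x - c_i|^2 / R_i^2 - 1 ) ),    B < 0,
#
# at iso-value 1.  With this kernel an isolated atom's isosurface is
# exactly its van der Waals sphere (the exponent vanishes at |x - c| = R),
# which anchors the definition to a testable reference.  Contributions
# beyond `cutoff` are dropped, atom-centered, for speed.

#' Build a Gaussian scalar-field surface
#'
#' @param atoms An [atom_set()].
#' @param grid A [make_grid()] lattice enclosing all atoms plus the cutoff.
#' @param blobbyness Negative exponent parameter `B` controlling surface
#'   roughness (default `-2.5`).
#' @param iso Iso-value of the surface (default `1`).
#' @param cutoff Per-atom truncation radius in Angstrom (default `6`).
#' @return A `field_surface` whose crossings are found by bracketing the
#'   trilinear interpolant and bisecting to `1e-9`.
#' @export
build_gaussian <- function(atoms, grid, blobbyness = -2.5, iso = 1,
                           cutoff = 6) {
  stopifnot(inherits(atoms, "atom_set"), blobbyness < 0,
            cutoff > max(atoms$radius))
  nv <- grid$nv
  xs <- grid$origin[1L] + (seq_len(nv[1L]) - 1L) * grid$h
  ys <- grid$origin[2L] + (seq_len(nv[2L]) - 1L) * grid$h
  zs <- grid$origin[3L] + (seq_len(nv[3L]) - 1L) * grid$h
  field <- array(0, dim = nv)
  B <- blobbyness
  for (i in seq_len(nrow(atoms))) {
    ci <- c(atoms$x[i], atoms$y[i], atoms$z[i]); Ri <- atoms$radius[i]
    ix <- which(abs(xs - ci[1L]) <= cutoff)
    iy <- which(abs(ys - ci[2L]) <= cutoff)
    iz <- which(abs(zs - ci[3L]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - ci[1L])^2
    dy2 <- (ys[iy] - ci[2L])^2
    dz2 <- (zs[iz] - ci[3L])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    contrib <- exp(B * (d2 / Ri^2 - 1))
    contrib[d2 > cutoff^2] <- 0
    field[ix, iy, iz] <- field[ix, iy, iz] + contrib
  }
  structure(list(grid = grid, field = field, iso = iso,
                 params = list(blobbyness = B, iso = iso, cutoff = cutoff),
                 atoms = atoms, definition = "gaussian"),
            class = c("field_surface", "surface_model"))
}

#' Evaluate a Gaussian field directly (closed form, no grid)
#'
#' @param atoms An [atom_set()].
#' @param points n x 3 matrix of evaluation points.
#' @param blobbyness Negative exponent parameter.
#' @param cutoff Truncation radius; `Inf` disables truncation.
#' @return Numeric field values.
#' @export
gaussian_field <- function(atoms, points, blobbyness = -2.5, cutoff = Inf) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  val <- numeric(nrow(pts))
  for (i in seq_len(nrow(atoms))) {
    d2 <- (pts[, 1L] - atoms$x[i])^2 + (pts[, 2L] - atoms$y[i])^2 +
      (pts[, 3L] - atoms$z[i])^2
    v <- exp(blobbyness * (d2 / atoms$radius[i]^2 - 1))
    v[d2 > cutoff^2] <- 0
    val <- val + v
  }
  val
}

# trilinear interpolation of the stored field; points outside the lattice
# evaluate to 0 (outside the surface for iso >= any positive value).
field_interp <- function(surface, pts) {
  g <- surface$grid; nv <- g$nv; h <- g$h
  u <- sweep(pts, 2L, g$origin) / h
  i0 <- floor(u)
  fr <- u - i0
  i0 <- i0 + 1                     # 1-based cell origin
  out <- rep(0, nrow(pts))
  ok <- i0[, 1L] >= 1 & i0[, 2L] >= 1 & i0[, 3L] >= 1 &
    i0[, 1L] <= nv[1L] - 1 & i0[, 2L] <= nv[2L] - 1 & i0[, 3L] <= nv[3L] - 1
  if (!any(ok)) return(out)
  ii <- i0[ok, , drop = FALSE]; ff <- fr[ok, , drop = FALSE]
  f <- surface$field
  idx <- function(dx, dy, dz)
    f[cbind(ii[, 1L] + dx, ii[, 2L] + dy, ii[, 3L] + dz)]
  v <- idx(0, 0, 0) * (1 - ff[, 1L]) * (1 - ff[, 2L]) * (1 - ff[, 3L]) +
    idx(1, 0, 0) * ff[, 1L] * (1 - ff[, 2L]) * (1 - ff[, 3L]) +
    idx(0, 1, 0) * (1 - ff[, 1L]) * ff[, 2L] * (1 - ff[, 3L]) +
    idx(0, 0, 1) * (1 - ff[, 1L]) * (1 - ff[, 2L]) * ff[, 3L] +
    idx(1, 1, 0) * ff[, 1L] * ff[, 2L] * (1 - ff[, 3L]) +
    idx(1, 0, 1) * ff[, 1L] * (1 - ff[, 2L]) * ff[, 3L] +
    idx(0, 1, 1) * (1 - ff[, 1L]) * ff[, 2L] * ff[, 3L] +
    idx(1, 1, 1) * ff[, 1L] * ff[, 2L] * ff[, 3L]
  out[ok] <- v
  out
}

field_gradient <- function(surface, pts, eps = 1e-5) {
  g <- matrix(0, nrow(pts), 3L)
  for (d in 1:3) {
    e <- rep(0, 3L); e[d] <- eps
    g[, d] <- (field_interp(surface, sweep(pts, 2L, e, `+`)) -
                 field_interp(surface, sweep(pts, 2L, e, `-`))) / (2 * eps)
  }
  g
}

#' @export
surface_bboxes.field_surface <- function(surface) {
  g <- surface$grid
  matrix(c(g$origin, g$origin + (g$nv - 1L) * g$h), 1L)
}

#' @export
surface_ray_hits.field_surface <- function(surface, origin, dir, t_max,
                                           candidates = NULL) {
  h <- surface$grid$h
  step <- h / 8
  ts <- seq(0, t_max, by = step)
  if (ts[length(ts)] < t_max) ts <- c(ts, t_max)
  pts <- outer(ts, dir) + rep(origin, each = length(ts))
  v <- field_interp(surface, pts) - surface$iso
  sgn <- sign(v)
  sw <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (!length(sw)) return(finalize_hits(numeric(0), matrix(0, 0, 3), integer(0)))
  roots <- vapply(sw, function(i) {
    lo <- ts[i]; hi <- ts[i + 1L]
    flo <- v[i]
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      fm <- field_interp(surface, matrix(origin + mid * dir, 1L)) -
        surface$iso
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1L))
  hp <- outer(roots, dir) + rep(origin, each = length(roots))
  gr <- field_gradient(surface, hp)
  # field decreases outward: outward normal is -gradient
  gr <- -gr / pmax(sqrt(rowSums(gr * gr)), 1e-300)
  finalize_hits(roots, gr, rep(1L, length(roots)))
}

#' @export
surface_residual.field_surface <- function(surface, points, patch = NULL) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  f <- field_interp(surface, pts) - surface$iso
  g <- field_gradient(surface, pts)
  abs(f) / pmax(sqrt(rowSums(g * g)), 1e-12)
}

#' @export
print.field_surface <- function(x, ...) {
  cat(sprintf("<gaussian surface: %s field, iso %.3g, B = %.3g>\n",
              paste(dim(x$field), collapse = "x"), x$iso,
              x$params$blobbyness))
  invisible(x)
}
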