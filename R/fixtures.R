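# Analytic fixtures: atom sets and meshes with closed-form (or stated
# quadrature / Monte-Carlo) ground truth, so every pipeline stage can be
# tested without external data.

new_fixture <- function(atoms = NULL, mesh = NULL, truth = list(),
                        seed = NA_integer_) {
  structure(list(atoms = atoms, mesh = mesh, truth = truth, seed = seed),
            class = "surf_fixture")
}

#' @export
print.surf_fixture <- function(x, ...) {
  what <- if (!is.null(x$atoms)) sprintf("%d atoms", nrow(x$atoms)) else
    sprintf("mesh %d vertices", nrow(x$mesh$vertices))
  cat(sprintf("<fixture: %s; truth: %s>\n", what,
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

#' Single-atom fixture
#'
#' @param R Atom radius (Angstrom).
#' @return Fixture with exact sphere area `4 pi R^2` and volume
#'   `4/3 pi R^3` (the SES of an isolated atom is its van der Waals
#'   sphere for any probe).
#' @export
gen_sphere_atom <- function(R = 1) {
  stopifnot(R > 0)
  new_fixture(atoms = atom_set(0, 0, 0, R),
              truth = list(area = 4 * pi * R^2,
                           volume = 4 / 3 * pi * R^3, genus = 0L,
                           cavities = 0L))
}

#' Two-atom fixture with union and rolling-probe ground truth
#'
#' Van der Waals union area/volume are closed form (spherical caps and the
#' lens); for overlapping inflated spheres the solvent-excluded area and
#' volume are computed by an axisymmetric surface-of-revolution quadrature
#' (`n_quad` nodes) over the two exposed caps and the probe arc.
#'
#' @param R1,R2 Atom radii.
#' @param d Center distance (along x).
#' @param probe_radius Probe radius used for the SES truth.
#' @param n_quad Quadrature nodes.
#' @return Fixture with `vdw_area`, `vdw_volume`, and (when the probe
#'   bridges the atoms) `ses_area`, `ses_volume`.
#' @export
gen_two_atoms <- function(R1 = 1, R2 = 1, d = 2.5, probe_radius = 1.4,
                          n_quad = 1e5) {
  stopifnot(R1 > 0, R2 > 0, d >= 0)
  atoms <- atom_set(c(0, d), c(0, 0), c(0, 0), c(R1, R2))
  truth <- list(genus = 0L, cavities = 0L)
  if (d >= R1 + R2) {
    truth$vdw_area <- 4 * pi * (R1^2 + R2^2)
    truth$vdw_volume <- 4 / 3 * pi * (R1^3 + R2^3)
  } else {
    xp <- (d^2 + R1^2 - R2^2) / (2 * d)
    truth$vdw_area <- 2 * pi * R1 * (R1 + xp) + 2 * pi * R2 * (R2 + d - xp)
    lens <- pi * (R1 + R2 - d)^2 *
      (d^2 + 2 * d * (R1 + R2) - 3 * (R1 - R2)^2) / (12 * d)
    truth$vdw_volume <- 4 / 3 * pi * (R1^3 + R2^3) - lens
  }
  rp <- probe_radius
  if (rp > 0 && d < R1 + R2 + 2 * rp && d > 1e-9) {
    q <- ses_two_sphere_quadrature(R1, R2, d, rp, n_quad)
    truth$ses_area <- q$area
    truth$ses_volume <- q$volume
  } else if (rp > 0) {
    truth$ses_area <- 4 * pi * (R1^2 + R2^2)
    truth$ses_volume <- 4 / 3 * pi * (R1^3 + R2^3)
  }
  new_fixture(atoms = atoms, truth = truth)
}

# axisymmetric SES of two bridged spheres: exposed caps + probe arc
ses_two_sphere_quadrature <- function(R1, R2, d, rp, n = 1e5) {
  Ri1 <- R1 + rp; Ri2 <- R2 + rp
  xt <- (d^2 + Ri1^2 - Ri2^2) / (2 * d)
  rt2 <- Ri1^2 - xt^2
  stopifnot(rt2 > 0)
  rt <- sqrt(rt2)
  P <- c(xt, rt)                       # probe center in the (x, rho) plane
  # contact angles of the probe arc: toward each atom center
  phi1 <- atan2(0 - P[2L], 0 - P[1L])          # direction to c1 = (0,0)
  phi2 <- atan2(0 - P[2L], d - P[1L])          # direction to c2 = (d,0)
  # contact points and cap opening angles (from the +x axis at each center)
  cp1 <- c(0, 0) + R1 * (P - c(0, 0)) / Ri1
  cp2 <- c(d, 0) + R2 * (P - c(d, 0)) / Ri2
  alpha1 <- atan2(cp1[2L], cp1[1L] - 0)        # in [0, pi]
  alpha2 <- atan2(cp2[2L], cp2[1L] - d)
  # areas of the exposed zones (closed form)
  cap1 <- 2 * pi * R1^2 * (1 + cos(alpha1))
  cap2 <- 2 * pi * R2^2 * (1 - cos(alpha2))    # zone from alpha2 to 0
  # probe arc band, numeric quadrature in the arc angle
  ph <- seq(phi1, phi2, length.out = n)
  rho <- P[2L] + rp * sin(ph)
  band <- sum(2 * pi * pmax(rho, 0) * rp * abs(diff(ph)[1L])) -
    pi * (pmax(rho[1L], 0) + pmax(rho[n], 0)) * rp * abs(diff(ph)[1L])
  area <- cap1 + cap2 + band
  # volume of revolution of the profile
  xs1 <- seq(-R1, cp1[1L], length.out = n)
  f1 <- pmax(R1^2 - xs1^2, 0)
  xs2 <- seq(cp2[1L], d + R2, length.out = n)
  f2 <- pmax(R2^2 - (xs2 - d)^2, 0)
  xsn <- seq(cp1[1L], cp2[1L], length.out = n)
  fn <- pmax(rt - sqrt(pmax(rp^2 - (xsn - xt)^2, 0)), 0)^2
  trap <- function(x, y) sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
  volume <- pi * (trap(xs1, f1) + trap(xs2, f2) + trap(xsn, fn))
  list(area = area, volume = volume)
}

#' Linear chain of equal atoms
#'
#' Centers along x with spacing `2 * R * (1 - overlap)`; consecutive
#' spheres overlap, non-consecutive do not (enforced).  Union area and
#' volume are closed form by pairwise inclusion-exclusion.
#'
#' @param n Number of atoms (>= 2).
#' @param R Atom radius.
#' @param overlap Fractional overlap in (0, 0.5).
#' @return Fixture with `vdw_area` and `vdw_volume`.
#' @export
gen_linear_chain <- function(n = 4, R = 1, overlap = 0.25) {
  stopifnot(n >= 2, R > 0, overlap > 0, overlap < 0.5)
  sp <- 2 * R * (1 - overlap)
  atoms <- atom_set((seq_len(n) - 1L) * sp, rep(0, n), rep(0, n),
                    rep(R, n))
  pair <- gen_two_atoms(R, R, sp, probe_radius = 0)
  area <- n * 4 * pi * R^2 -
    (n - 1L) * (2 * 4 * pi * R^2 - pair$truth$vdw_area)
  vol <- n * 4 / 3 * pi * R^3 -
    (n - 1L) * (2 * 4 / 3 * pi * R^3 - pair$truth$vdw_volume)
  new_fixture(atoms = atoms,
              truth = list(vdw_area = area, vdw_volume = vol, genus = 0L))
}

#' Fullerene cage fixture (60 cospherical atoms)
#'
#' Truncated-icosahedron vertex coordinates scaled so every atom center
#' lies exactly at `cage_radius` from the origin: a cosphericity stress
#' test for the degeneracy-breaking perturbation.  With the default radii
#' the solvent-excluded surface encloses exactly one internal cavity.
#'
#' @param cage_radius Distance of every atom from the center (default
#'   3.55 Angstrom).
#' @param atom_radius Carbon radius (default 1.9 Angstrom, the common
#'   EDTSurf-style carbon value).
#' @return Fixture with `cavities = 1`.
#' @export
gen_c60 <- function(cage_radius = 3.55, atom_radius = 1.9) {
  stopifnot(cage_radius > atom_radius)
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    expand_signs(c(0, 1, 3 * phi)),
    expand_signs(c(1, 2 + phi, 2 * phi)),
    expand_signs(c(phi, 2, 2 * phi + 1)))
  pts <- rbind(base,
               base[, c(2L, 3L, 1L)],
               base[, c(3L, 1L, 2L)])
  pts <- unique(round(pts, 12L))
  stopifnot(nrow(pts) == 60L)
  pts <- pts / sqrt(sum(pts[1L, ]^2)) * cage_radius
  new_fixture(atoms = atom_set(pts[, 1L], pts[, 2L], pts[, 3L],
                               rep(atom_radius, 60L)),
              truth = list(cavities = 1L, cage_radius = cage_radius))
}

expand_signs <- function(v) {
  nz <- which(v != 0)
  sgn <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(nz))))
  out <- matrix(rep(v, each = nrow(sgn)), nrow(sgn))
  out[, nz] <- out[, nz] * sgn
  out
}

#' Hollow shell fixture: a watertight ball shell with one internal void
#'
#' Atoms on a Fibonacci lattice over a sphere of radius `shell_radius`;
#' neighbouring atoms must overlap (`max nearest-neighbour spacing <
#' 2 * atom_radius`) so the shell is watertight, which is verified both
#' geometrically and by a coarse cast-and-floodfill pre-check before the
#' fixture is emitted.  The inner void volume truth is a Monte-Carlo
#' membership estimate with `mc_points` samples.
#'
#' @param n_atoms Number of shell atoms.
#' @param shell_radius Radius of the atom-center sphere.
#' @param atom_radius Atom radius.
#' @param seed Seed for the Monte-Carlo volume estimate.
#' @param mc_points Monte-Carlo sample count.
#' @param verify Run the coarse parity/cavity pre-check.
#' @return Fixture with `cavities = 1` and `void_volume`.
#' @export
gen_hollow_shell <- function(n_atoms = 80, shell_radius = 3,
                             atom_radius = 0.9, seed = 1L,
                             mc_points = 2e5, verify = TRUE) {
  pts <- fibonacci_sphere(n_atoms) * shell_radius
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  if (max(nn) >= 2 * atom_radius)
    stop("shell is not watertight: max nearest-neighbour spacing ",
         sprintf("%.3f", max(nn)), " >= 2 * atom_radius = ",
         2 * atom_radius)
  atoms <- atom_set(pts[, 1L], pts[, 2L], pts[, 3L],
                    rep(atom_radius, n_atoms))
  # Monte-Carlo inner-void volume: points inside the center sphere and
  # outside every atom ball
  frac <- with_seed(derive_seed(seed, 31L), function() {
    u <- matrix(stats::runif(3 * mc_points, -1, 1), ncol = 3L)
    u <- u[rowSums(u^2) <= 1, , drop = FALSE] * shell_radius
    void <- rep(TRUE, nrow(u))
    for (i in seq_len(n_atoms)) {
      d2 <- (u[, 1L] - pts[i, 1L])^2 + (u[, 2L] - pts[i, 2L])^2 +
        (u[, 3L] - pts[i, 3L])^2
      void <- void & d2 > atom_radius^2
    }
    mean(void)
  })
  void_volume <- frac * 4 / 3 * pi * shell_radius^3
  fx <- new_fixture(atoms = atoms,
                    truth = list(cavities = 1L, void_volume = void_volume),
                    seed = seed)
  if (verify) {
    surf <- build_vdw(atoms, seed = seed)
    g <- make_grid(atoms, scale = 2, perfil = 90)
    st <- cast_grid_rays(surf, g, seed = seed)
    cav <- detect_cavities(st)
    if (length(cav$cavities) != 1L)
      stop("shell pre-check failed: expected 1 cavity, found ",
           length(cav$cavities))
  }
  fx
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1L)
  cbind(r * cos(th), r * sin(th), z)
}

#' Random atom cluster for stress tests
#'
#' @param n Number of atoms.
#' @param box Half-side of the sampling cube.
#' @param r_range Radius range `c(min, max)`.
#' @param seed Seed (deterministic fixture).
#' @return Fixture (no analytic truth).
#' @export
gen_random_cluster <- function(n = 20, box = 5, r_range = c(1, 2),
                               seed = 1L) {
  m <- with_seed(derive_seed(seed, 77L), function()
    cbind(matrix(stats::runif(3 * n, -box, box), ncol = 3L),
          stats::runif(n, r_range[1L], r_range[2L])))
  new_fixture(atoms = atom_set(m[, 1L], m[, 2L], m[, 3L], m[, 4L]),
              seed = seed)
}

#' Closed torus mesh fixture
#'
#' @param R,r Major and minor radii (truths: area `4 pi^2 R r`, volume
#'   `2 pi^2 R r^2`, genus 1).
#' @param nu,nv Tessellation resolution (>= 3 each).
#' @return Fixture carrying a closed `mesh_surface`.
#' @export
gen_torus_mesh <- function(R = 2, r = 0.7, nu = 48, nv = 24) {
  stopifnot(nu >= 3, nv >= 3)
  iu <- (seq_len(nu) - 1L) * 2 * pi / nu
  iv <- (seq_len(nv) - 1L) * 2 * pi / nv
  V <- matrix(0, nu * nv, 3L)
  for (b in seq_len(nv)) {
    rho <- R + r * cos(iv[b]); z <- r * sin(iv[b])
    rows <- (b - 1L) * nu + seq_len(nu)
    V[rows, ] <- cbind(rho * cos(iu), rho * sin(iu), z)
  }
  tri <- NULL
  vid <- function(a, b) ((b - 1L) %% nv) * nu + ((a - 1L) %% nu) + 1L
  for (b in seq_len(nv)) for (a in seq_len(nu)) {
    tri <- rbind(tri,
                 c(vid(a, b), vid(a + 1L, b), vid(a + 1L, b + 1L)),
                 c(vid(a, b), vid(a + 1L, b + 1L), vid(a, b + 1L)))
  }
  new_fixture(mesh = mesh_surface(V, tri),
              truth = list(area = 4 * pi^2 * R * r,
                           volume = 2 * pi^2 * R * r^2, genus = 1L))
}

#' Axis-aligned box mesh fixture
#'
#' @param a,b,c Side lengths; the box is centered at the origin.
#' @return Fixture with exact area and volume truths.
#' @export
gen_box_mesh <- function(a = 2, b = 2, c = 2) {
  hx <- a / 2; hy <- b / 2; hz <- c / 2
  V <- as.matrix(expand.grid(x = c(-hx, hx), y = c(-hy, hy),
                             z = c(-hz, hz)))
  # vertices indexed 1..8 with x fastest
  quad <- function(i, j, k, l) rbind(c(i, j, k), c(i, k, l))
  tri <- rbind(
    quad(1L, 3L, 4L, 2L),   # z = -hz
    quad(5L, 6L, 8L, 7L),   # z = +hz
    quad(1L, 2L, 6L, 5L),   # y = -hy
    quad(3L, 7L, 8L, 4L),   # y = +hy
    quad(1L, 5L, 7L, 3L),   # x = -hx
    quad(2L, 4L, 8L, 6L))   # x = +hx
  new_fixture(mesh = mesh_surface(V, tri),
              truth = list(area = 2 * (a * b + b * c + a * c),
                           volume = a * b * c, genus = 0L))
}

#' Degenerate mesh fixture for the parity protocol
#'
#' An axis-aligned box whose faces are designed to be coplanar with grid
#' lattice planes, with one edge split through a midpoint vertex displaced
#' off-plane by `sliver` (default `1e-9` Angstrom), producing two
#' near-degenerate sliver triangles.  Rays running inside a face plane or
#' through the sliver hit the checksum anomaly and must be cured by the
#' jittered re-casting protocol.
#'
#' @param a Side length (the box is centered at the origin).
#' @param sliver Off-plane displacement of the split vertex.
#' @return Fixture with exact `area` and `volume` truths.
#' @export
gen_degenerate_mesh <- function(a = 2, sliver = 1e-9) {
  base <- gen_box_mesh(a, a, a)
  V <- base$mesh$vertices
  tri <- base$mesh$triangles
  # split the edge shared by triangles (1,3,4) and (3,8,4) through a
  # slightly lifted midpoint
  m <- (V[3L, ] + V[4L, ]) / 2 + c(0, 0, sliver)
  V <- rbind(V, m)
  mi <- nrow(V)
  is_tri <- function(t, ref) all(sort(t) == sort(ref))
  keep <- !apply(tri, 1L, function(t)
    is_tri(t, c(1L, 3L, 4L)) || is_tri(t, c(3L, 8L, 4L)))
  tri <- rbind(tri[keep, , drop = FALSE],
               c(1L, 3L, mi), c(1L, mi, 4L),
               c(3L, 8L, mi), c(8L, 4L, mi))
  new_fixture(mesh = mesh_surface(V, tri),
              truth = list(area = 6 * a^2, volume = a^3, genus = 0L))
}
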