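# Solvent-excluded, van der Waals and solvent-accessible surfaces as
# trimmed analytic patch sets.
#
# The SES is built with the alpha-shape recipe: atom radii are inflated by
# the probe radius, positions are perturbed to break degeneracies, and the
# regular (weighted) triangulation of the inflated balls supplies the
# candidate simplices.  Exposed atoms contribute convex sphere patches,
# triangulation edges whose inflated spheres overlap contribute rolling-
# probe torus patches, and triangulation triangles with an exposed probe
# position contribute concave probe-sphere patches.  Trims select exactly
# the exposed part of each patch:
#   * convex patch of atom i: the contact point maps radially to the probe
#     center on the inflated (SAS) sphere; requiring that center to lie
#     outside every other inflated sphere is, after the radial map, an
#     ordinary sphere-outside trim;
#   * torus patch: the foot probe center must be exposed and the point must
#     lie on the probe arc between the two atom contact points;
#   * probe patch: the spherical triangle spanned by the three contact
#     directions, clipped against nearby probe spheres where two probes
#     overlap (the self-intersection cure).

#' Build the solvent-excluded surface (SES) of an atom set
#'
#' @param atoms An [atom_set()].
#' @param probe_radius Probe (water) radius in Angstrom; `0` gives the van
#'   der Waals surface.
#' @param perturb_magnitude Degeneracy-breaking perturbation (Angstrom).
#' @param seed Integer seed for the perturbation.
#' @param max_retries Re-perturbation attempts on degenerate input.
#' @return A `patch_surface`.
#' @examples
#' s <- build_ses(gen_sphere_atom(2)$atoms, probe_radius = 1.4)
#' @export
build_ses <- function(atoms, probe_radius = 1.4, perturb_magnitude = 1e-4,
                      seed = 1L, max_retries = 5L) {
  stopifnot(inherits(atoms, "atom_set"), probe_radius >= 0)
  for (try in 0:max_retries) {
    at <- perturb_atoms(atoms, perturb_magnitude,
                        derive_seed(seed, 101L, try))
    res <- tryCatch(ses_patches(at, probe_radius),
                    surfray_degenerate = function(e) e)
    if (!inherits(res, "condition")) return(res)
  }
  stop("degenerate atom configuration survived ", max_retries,
       " re-perturbations: ", conditionMessage(res))
}

#' @rdname build_ses
#' @export
build_vdw <- function(atoms, perturb_magnitude = 1e-4, seed = 1L,
                      max_retries = 5L) {
  s <- build_ses(atoms, probe_radius = 0,
                 perturb_magnitude = perturb_magnitude, seed = seed,
                 max_retries = max_retries)
  s$definition <- "vdw"
  s
}

#' @rdname build_ses
#' @export
build_sas <- function(atoms, probe_radius = 1.4, perturb_magnitude = 1e-4,
                      seed = 1L, max_retries = 5L) {
  infl <- atoms
  infl$radius <- atoms$radius + probe_radius
  s <- build_ses(infl, probe_radius = 0,
                 perturb_magnitude = perturb_magnitude, seed = seed,
                 max_retries = max_retries)
  s$definition <- "sas"
  s$params$probe_radius <- probe_radius
  s
}

ses_patches <- function(atoms, rp) {
  C <- atom_centers(atoms)
  R <- atoms$radius
  M <- nrow(C)
  Ri <- R + rp                      # inflated (SAS) radii
  rt <- regular_triangulation(C, Ri^2)

  # inflated-overlap neighbour lists
  D <- as.matrix(stats::dist(C))
  nbr <- lapply(seq_len(M), function(i)
    setdiff(which(D[i, ] < Ri[i] + Ri - 1e-12), i))

  # convex atom patches: trim spheres are the radial preimages of the
  # neighbour SAS spheres
  sp_center <- C
  sp_radius <- R
  sp_orient <- rep(1, M)
  sp_trims <- vector("list", M)
  for (i in seq_len(M)) {
    js <- nbr[[i]]
    if (!length(js)) { sp_trims[[i]] <- list(); next }
    kk <- Ri[i] / R[i]
    tc <- sweep(C[js, , drop = FALSE] - rep(C[i, ], each = length(js)),
                1L, kk, `/`) + rep(C[i, ], each = length(js))
    sp_trims[[i]] <- list(trim_spheres_out(cbind(tc, Ri[js] / kk)))
  }

  to_center <- NULL; to_axis <- NULL; to_R <- NULL; to_r <- NULL
  to_trims <- list()
  pr_center <- NULL; pr_tri <- list(); pr_planes <- list()

  if (rp > 1e-9 && nrow(rt$edges)) {
    for (e in seq_len(nrow(rt$edges))) {
      i <- rt$edges[e, 1L]; j <- rt$edges[e, 2L]
      d <- D[i, j]
      if (d >= Ri[i] + Ri[j] - 1e-12) next          # no SAS overlap
      u <- (C[j, ] - C[i, ]) / d
      x <- (d^2 + Ri[i]^2 - Ri[j]^2) / (2 * d)
      rt2 <- Ri[i]^2 - x^2
      if (rt2 <= 1e-12) next
      ct <- C[i, ] + x * u
      rtt <- sqrt(rt2)
      ks <- setdiff(union(nbr[[i]], nbr[[j]]), c(i, j))
      ks <- ks[sqrt(rowSums(sweep(C[ks, , drop = FALSE], 2L, ct)^2)) <
                 Ri[ks] + rtt]
      nbmat <- if (length(ks)) cbind(C[ks, , drop = FALSE], Ri[ks]) else
        matrix(0, 0L, 4L)
      # skip tori whose probe circle is everywhere buried under neighbour
      # SAS spheres (they contribute no exposed saddle)
      if (nrow(nbmat)) {
        b1 <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        b1 <- unitize(b1 - sum(b1 * u) * u)
        b2 <- c(u[2L] * b1[3L] - u[3L] * b1[2L],
                u[3L] * b1[1L] - u[1L] * b1[3L],
                u[1L] * b1[2L] - u[2L] * b1[1L])
        th <- seq(0, 2 * pi, length.out = 25L)[-25L]
        circ <- sweep(rtt * (outer(cos(th), b1) + outer(sin(th), b2)),
                      2L, ct, `+`)
        buried <- rep(FALSE, nrow(circ))
        for (kk2 in seq_len(nrow(nbmat))) {
          d2 <- (circ[, 1L] - nbmat[kk2, 1L])^2 +
            (circ[, 2L] - nbmat[kk2, 2L])^2 +
            (circ[, 3L] - nbmat[kk2, 3L])^2
          buried <- buried | d2 < (nbmat[kk2, 4L] - 1e-7)^2
        }
        if (all(buried)) next
      }
      to_center <- rbind(to_center, ct)
      to_axis <- rbind(to_axis, u)
      to_R <- c(to_R, rtt)
      to_r <- c(to_r, rp)
      to_trims[[length(to_trims) + 1L]] <-
        list(trim_torus_arc(ct, u, rtt, C[i, ], C[j, ], nbmat))
    }
  }

  if (rp > 1e-9 && nrow(rt$tris)) {
    for (f in seq_len(nrow(rt$tris))) {
      tri <- rt$tris[f, ]
      pp <- probe_positions(C[tri, ], Ri[tri])
      if (is.null(pp)) next
      for (p in list(pp$p1, pp$p2)) {
        others <- setdiff(seq_len(M), tri)
        if (length(others)) {
          d2 <- rowSums(sweep(C[others, , drop = FALSE], 2L, p)^2)
          if (any(d2 < (Ri[others] - 1e-9)^2)) next   # buried probe
        }
        planes <- probe_triangle_trims(p, C[tri, ])
        pr_center <- rbind(pr_center, p)
        pr_tri[[length(pr_tri) + 1L]] <- tri
        pr_planes[[length(pr_planes) + 1L]] <- planes
      }
    }
  }

  # probe-probe clipping: where two fixed probes overlap, each probe patch
  # is clipped by the other probe ball (boundary of the union of probes)
  npr <- if (is.null(pr_center)) 0L else nrow(pr_center)
  pr_trims <- vector("list", npr)
  if (npr) {
    pd <- as.matrix(stats::dist(pr_center))
    for (a in seq_len(npr)) {
      close <- setdiff(which(pd[a, ] < 2 * rp - 1e-12), a)
      tr <- pr_planes[[a]]
      if (length(close))
        tr <- c(tr, list(trim_spheres_out(
          cbind(pr_center[close, , drop = FALSE], rp))))
      pr_trims[[a]] <- tr
    }
  }

  spheres <- list(
    center = rbind(sp_center, pr_center),
    radius = c(sp_radius, rep(rp, npr)),
    orient = c(sp_orient, rep(-1, npr)),
    trims = c(sp_trims, pr_trims))
  tori <- if (is.null(to_center)) NULL else
    list(center = to_center, axis = to_axis, R = to_R, r = to_r,
         orient = rep(-1, length(to_R)), trims = to_trims)
  new_patch_surface(spheres, tori, NULL, atoms,
                    list(probe_radius = rp),
                    if (rp > 0) "ses" else "vdw")
}

# the two candidate probe centers tangent to three spheres (trilateration);
# NULL when the probe cannot touch all three at once.
probe_positions <- function(C3, r3) {
  ex <- C3[2L, ] - C3[1L, ]
  d <- vnorm(ex); ex <- ex / d
  v13 <- C3[3L, ] - C3[1L, ]
  ii <- sum(ex * v13)
  ey <- v13 - ii * ex
  jj <- vnorm(ey)
  if (jj < 1e-12) return(NULL)
  ey <- ey / jj
  ez <- c(ex[2L] * ey[3L] - ex[3L] * ey[2L],
          ex[3L] * ey[1L] - ex[1L] * ey[3L],
          ex[1L] * ey[2L] - ex[2L] * ey[1L])
  xx <- (r3[1L]^2 - r3[2L]^2 + d^2) / (2 * d)
  yy <- (r3[1L]^2 - r3[3L]^2 + ii^2 + jj^2 - 2 * ii * xx) / (2 * jj)
  z2 <- r3[1L]^2 - xx^2 - yy^2
  if (z2 <= 1e-12) return(NULL)
  zz <- sqrt(z2)
  base <- C3[1L, ] + xx * ex + yy * ey
  list(p1 = base + zz * ez, p2 = base - zz * ez)
}

# spherical-triangle trims of a concave probe patch: three planes through
# the probe center, each containing two contact directions, keeping the
# side of the third.
probe_triangle_trims <- function(p, C3) {
  a <- list(C3[1L, ] - p, C3[2L, ] - p, C3[3L, ] - p)
  planes <- list()
  idx <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (q in idx) {
    n <- c(a[[q[1L]]][2L] * a[[q[2L]]][3L] - a[[q[1L]]][3L] * a[[q[2L]]][2L],
           a[[q[1L]]][3L] * a[[q[2L]]][1L] - a[[q[1L]]][1L] * a[[q[2L]]][3L],
           a[[q[1L]]][1L] * a[[q[2L]]][2L] - a[[q[1L]]][2L] * a[[q[2L]]][1L])
    if (sum(n * a[[q[3L]]]) < 0) n <- -n
    # keep (x - p) . n >= 0  <=>  (-n) . x <= (-n) . p
    planes[[length(planes) + 1L]] <- trim_halfspace(-n, sum(-n * p))
  }
  planes
}
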