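# SurfaceModel contract: every surface (analytic patch set, scalar field,
# triangle mesh) can report its sorted ray intersections with outward
# normals, its per-patch bounding boxes, and a residual measuring how far a
# point is from the surface.

new_patch_surface <- function(spheres, tori, quadrics, atoms, params,
                              definition) {
  ns <- nrow(spheres$center %||% matrix(0, 0L, 3L))
  nt <- if (is.null(tori)) 0L else nrow(tori$center)
  nq <- if (is.null(quadrics)) 0L else nrow(quadrics$z)
  structure(list(spheres = spheres, tori = tori, quadrics = quadrics,
                 n_patches = ns + nt + nq,
                 atoms = atoms, params = params, definition = definition),
            class = c("patch_surface", "surface_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patch_surface <- function(x, ...) {
  ns <- nrow(x$spheres$center %||% matrix(0, 0, 3))
  nt <- if (is.null(x$tori)) 0L else nrow(x$tori$center)
  nq <- if (is.null(x$quadrics)) 0L else nrow(x$quadrics$z)
  cat(sprintf("<%s surface: %d sphere, %d torus, %d quadric patches>\n",
              x$definition, ns, nt, nq))
  invisible(x)
}

#' Axis-aligned bounding boxes of all surface patches
#'
#' @param surface A surface model.
#' @return Numeric matrix with one row per patch and columns
#'   `xmin, ymin, zmin, xmax, ymax, zmax`.
#' @export
surface_bboxes <- function(surface) UseMethod("surface_bboxes")

#' @export
surface_bboxes.patch_surface <- function(surface) {
  bb <- NULL
  s <- surface$spheres
  if (!is.null(s) && nrow(s$center)) {
    bb <- cbind(s$center - s$radius, s$center + s$radius)
  }
  to <- surface$tori
  if (!is.null(to) && nrow(to$center)) {
    ext <- to$R + to$r
    bb <- rbind(bb, cbind(to$center - ext, to$center + ext))
  }
  q <- surface$quadrics
  if (!is.null(q) && nrow(q$z)) {
    bb <- rbind(bb, q$bbox)
  }
  bb
}

#' Sorted ray/surface intersections with outward normals
#'
#' The single contract every surface model satisfies.  Hits are sorted by
#' the ray parameter; normals point from the material (solute) side to the
#' outside.  Near-coincident hits reported by two adjacent patches for the
#' same geometric crossing (same location, same normal direction) are
#' collapsed to one.
#'
#' @param surface A surface model (patch set, scalar field, or mesh).
#' @param origin,dir,t_max Ray start, unit direction, and length.
#' @param candidates Optional integer vector of patch indices to test (from
#'   an acceleration structure); `NULL` tests every patch.
#' @return `data.frame(t, nx, ny, nz, patch)` sorted by `t`.
#' @export
surface_ray_hits <- function(surface, origin, dir, t_max, candidates = NULL)
  UseMethod("surface_ray_hits")

#' @export
surface_ray_hits.patch_surface <- function(surface, origin, dir, t_max,
                                           candidates = NULL) {
  s <- surface$spheres; to <- surface$tori; q <- surface$quadrics
  ns <- if (is.null(s)) 0L else nrow(s$center)
  nt <- if (is.null(to)) 0L else nrow(to$center)
  nq <- if (is.null(q)) 0L else nrow(q$z)
  if (is.null(candidates)) candidates <- seq_len(ns + nt + nq)
  out_t <- numeric(0); out_n <- matrix(0, 0L, 3L); out_p <- integer(0)

  sph <- candidates[candidates <= ns]
  if (length(sph)) {
    h <- ray_spheres_batch(origin, dir, s$center[sph, , drop = FALSE],
                           s$radius[sph], t_max)
    if (nrow(h)) {
      pid <- sph[h$idx]
      pts <- outer(h$t, dir) + rep(origin, each = nrow(h))
      keep <- rep(TRUE, nrow(h))
      for (pu in unique(pid)) {
        rows <- which(pid == pu)
        tr <- s$trims[[pu]]
        if (length(tr))
          keep[rows] <- point_in_trim(pts[rows, , drop = FALSE], tr)
      }
      if (any(keep)) {
        rows <- which(keep)
        nrm <- (pts[rows, , drop = FALSE] -
                  s$center[pid[rows], , drop = FALSE]) / s$radius[pid[rows]]
        nrm <- nrm * s$orient[pid[rows]]
        out_t <- c(out_t, h$t[rows])
        out_n <- rbind(out_n, nrm)
        out_p <- c(out_p, pid[rows])
      }
    }
  }

  tor <- candidates[candidates > ns & candidates <= ns + nt] - ns
  if (length(tor)) {
    # prune tori whose tube the ray line cannot reach
    m <- to$center[tor, , drop = FALSE] -
      rep(origin, each = length(tor))                   # c - o
    md <- as.numeric(m %*% dir)
    dist2 <- rowSums(m * m) - md^2                      # line-center dist^2
    tor <- tor[dist2 <= (to$R[tor] + to$r[tor])^2]
  }
  if (length(tor)) {
    # monic quartic coefficients, vectorised across candidate tori
    m <- to$center[tor, , drop = FALSE] - rep(origin, each = length(tor))
    m <- -m                                             # o - c
    md <- as.numeric(m %*% dir)
    mm <- rowSums(m * m)
    ma <- rowSums(m * to$axis[tor, , drop = FALSE])
    da <- as.numeric(to$axis[tor, , drop = FALSE] %*% dir)
    R2 <- to$R[tor]^2
    a1 <- 2 * md; a0 <- mm + R2 - to$r[tor]^2
    b2 <- 1 - da^2; b1 <- 2 * (md - ma * da); b0 <- mm - ma^2
    coef <- cbind(a0^2 - 4 * R2 * b0,
                  2 * a1 * a0 - 4 * R2 * b1,
                  a1^2 + 2 * a0 - 4 * R2 * b2,
                  2 * a1,
                  1)
    rt <- quartic_roots_batch(coef, 0, t_max)
    if (nrow(rt)) {
      for (iu in unique(rt$row)) {
        i <- tor[iu]
        roots <- rt$t[rt$row == iu]
        pts <- outer(roots, dir) + rep(origin, each = length(roots))
        keep <- point_in_trim(pts, to$trims[[i]])
        if (!any(keep)) next
        pts <- pts[keep, , drop = FALSE]
        g <- torus_gradient(pts, to$center[i, ], to$axis[i, ],
                            to$R[i], to$r[i])
        g <- g / pmax(sqrt(rowSums(g * g)), 1e-300) * to$orient[i]
        out_t <- c(out_t, roots[keep])
        out_n <- rbind(out_n, g)
        out_p <- c(out_p, ns + i)
      }
    }
  }

  qu <- candidates[candidates > ns + nt] - ns - nt
  for (i in qu) {
    roots <- quadric_ray_roots(origin, dir, q$M[[i]], q$z[i, ], q$k[i], t_max)
    if (!length(roots)) next
    pts <- outer(roots, dir) + rep(origin, each = length(roots))
    keep <- point_in_trim(pts, q$trims[[i]])
    if (!any(keep)) next
    pts <- pts[keep, , drop = FALSE]
    y <- sweep(pts, 2L, q$z[i, ])
    g <- 2 * y %*% q$M[[i]]
    g <- g / pmax(sqrt(rowSums(g * g)), 1e-300)
    out_t <- c(out_t, roots[keep])
    out_n <- rbind(out_n, g)
    out_p <- c(out_p, ns + nt + i)
  }

  finalize_hits(out_t, out_n, out_p)
}

# sort by t and collapse duplicate reports of the same crossing (adjacent
# patches meeting along a trim boundary): nearly equal t AND aligned normals.
finalize_hits <- function(t, n, p, dedup_tol = 1e-7) {
  if (!length(t))
    return(data.frame(t = numeric(0), nx = numeric(0), ny = numeric(0),
                      nz = numeric(0), patch = integer(0)))
  o <- order(t)
  t <- t[o]; n <- n[o, , drop = FALSE]; p <- p[o]
  keep <- rep(TRUE, length(t))
  if (length(t) > 1L)
    for (i in 2:length(t)) {
      if (!keep[i - 1L]) next
      if (t[i] - t[i - 1L] < dedup_tol &&
          sum(n[i, ] * n[i - 1L, ]) > 0.5) keep[i] <- FALSE
    }
  data.frame(t = t[keep], nx = n[keep, 1L], ny = n[keep, 2L],
             nz = n[keep, 3L], patch = p[keep])
}

#' Distance-like residual of points from the surface
#'
#' For analytic patch sets this is the minimum over patches of a
#' first-order geometric distance to the untrimmed patch (exact for
#' spheres and tori, `|f|/|grad f|` for quadrics); for scalar fields,
#' `|field - iso| / |grad|`; for meshes, the distance to the nearest
#' triangle.  Used to verify that triangulation vertices lie on the
#' surface.
#'
#' @param surface A surface model.
#' @param points n x 3 matrix.
#' @param patch Optional integer vector: evaluate against that patch only.
#' @return Numeric vector of per-point residuals (Angstrom).
#' @export
surface_residual <- function(surface, points, patch = NULL)
  UseMethod("surface_residual")

#' @export
surface_residual.patch_surface <- function(surface, points, patch = NULL) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  s <- surface$spheres; to <- surface$tori; q <- surface$quadrics
  ns <- if (is.null(s)) 0L else nrow(s$center)
  nt <- if (is.null(to)) 0L else nrow(to$center)
  nq <- if (is.null(q)) 0L else nrow(q$z)
  res_patch <- function(i, pts) {
    if (i <= ns) {
      abs(sqrt(rowSums(sweep(pts, 2L, s$center[i, ])^2)) - s$radius[i])
    } else if (i <= ns + nt) {
      j <- i - ns
      v <- sweep(pts, 2L, to$center[j, ])
      va <- as.numeric(v %*% to$axis[j, ])
      rad <- v - outer(va, to$axis[j, ])
      rho <- sqrt(rowSums(rad * rad))
      abs(sqrt((rho - to$R[j])^2 + va^2) - to$r[j])
    } else {
      j <- i - ns - nt
      y <- sweep(pts, 2L, q$z[j, ])
      f <- rowSums((y %*% q$M[[j]]) * y) - q$k[j]
      g <- 2 * y %*% q$M[[j]]
      abs(f) / pmax(sqrt(rowSums(g * g)), 1e-12)
    }
  }
  if (!is.null(patch)) {
    stopifnot(length(patch) == nrow(pts))
    out <- numeric(nrow(pts))
    for (pu in unique(patch)) {
      rows <- which(patch == pu)
      out[rows] <- res_patch(pu, pts[rows, , drop = FALSE])
    }
    return(out)
  }
  res <- matrix(Inf, nrow(pts), 1L)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(ns + nt + nq)) best <- pmin(best, res_patch(i, pts))
  best
}
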