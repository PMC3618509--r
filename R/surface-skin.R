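# Skin surface of a weighted point set (weights w_i = r_i^2) with shrink
# factor s in (0, 1].
#
# The regular triangulation of the weighted atoms induces the mixed
# complex: for a Delaunay simplex X of dimension k with dual power face
# nu_X, the mixed cell is the Minkowski combination (1-s)*X (+) s*nu_X
# (so that s = 1 leaves the full power cells and the union of balls).
# Within the cell of a k-simplex with orthocenter z and squared orthoradius
# R2 the surface is the quadric
#
#     |y_V|^2 / s - |y_D|^2 / (1 - s) = R2,      y = x - z,
#
# with y_D the component parallel to the simplex and y_V the orthogonal
# (Voronoi) component: a sphere of radius sqrt(s)*r_i in vertex cells, a
# sphere of squared radius (1-s)*(-R2) bounding an interstitial void in
# tetrahedron cells, and hyperboloids of revolution in edge and triangle
# cells.  Cells are convex; their half-space trims run between mixed cells
# of incident simplices: for a coface Y (resp. face W) of X the separating
# plane passes through (1-s)*z_X + s*z_Y (resp. (1-s)*z_W + s*z_X) with the
# in-simplex altitude direction as normal.
#
# At s = 1 every non-tetrahedral mixed cell is degenerate and the skin
# reduces to the boundary of the union of the input balls, which is what
# the builder returns in that limit.

#' Build the skin surface of an atom set
#'
#' @param atoms An [atom_set()].
#' @param shrink Shrink factor `s` in `(0, 1]`; `s = 1` is the
#'   union-of-balls boundary.
#' @param perturb_magnitude,seed,max_retries Degeneracy handling as in
#'   [build_ses()].
#' @return A `patch_surface` of trimmed spheres and quadrics.
#' @export
build_skin <- function(atoms, shrink = 0.45, perturb_magnitude = 1e-4,
                       seed = 1L, max_retries = 5L) {
  stopifnot(inherits(atoms, "atom_set"), shrink > 0, shrink <= 1)
  for (try in 0:max_retries) {
    at <- perturb_atoms(atoms, perturb_magnitude,
                        derive_seed(seed, 202L, try))
    res <- tryCatch(skin_patches(at, shrink),
                    surfray_degenerate = function(e) e)
    if (!inherits(res, "condition")) return(res)
  }
  stop("degenerate atom configuration survived ", max_retries,
       " re-perturbations: ", conditionMessage(res))
}

skin_patches <- function(atoms, s) {
  C <- atom_centers(atoms)
  R <- atoms$radius
  M <- nrow(C)

  if (s > 1 - 1e-9) {      # union-of-balls limit
    D <- as.matrix(stats::dist(C))
    trims <- lapply(seq_len(M), function(i) {
      js <- setdiff(which(D[i, ] < R[i] + R - 1e-12), i)
      if (!length(js)) list() else
        list(trim_spheres_out(cbind(C[js, , drop = FALSE], R[js])))
    })
    return(new_patch_surface(
      list(center = C, radius = R, orient = rep(1, M), trims = trims),
      NULL, NULL, atoms, list(shrink = 1), "skin"))
  }

  w <- R^2
  rt <- regular_triangulation(C, w)
  inc <- rt_incidence(rt)

  # orthocenters of every simplex
  oc_vert <- lapply(seq_len(M), function(i) list(z = C[i, ], R2 = w[i]))
  oc_edge <- lapply(seq_len(nrow(rt$edges)), function(e)
    orthocenter(C[rt$edges[e, ], , drop = FALSE], w[rt$edges[e, ]]))
  oc_tri <- lapply(seq_len(nrow(rt$tris)), function(f)
    orthocenter(C[rt$tris[f, ], , drop = FALSE], w[rt$tris[f, ]]))
  oc_tet <- lapply(seq_len(nrow(rt$tets)), function(t)
    orthocenter(C[rt$tets[t, ], , drop = FALSE], w[rt$tets[t, ]]))

  # altitude-direction half-space between simplex X and its coface/face
  # partner; the plane passes through (1-s) z_lower + s z_upper.
  altitude_normal <- function(base_pts, v_pt) {
    u <- v_pt - base_pts[1L, ]
    if (nrow(base_pts) > 1L) {
      Ub <- t(base_pts[-1L, , drop = FALSE]) - base_pts[1L, ]
      qr_ <- qr(Ub)
      u <- u - Ub %*% qr.coef(qr_, u)
      u <- as.numeric(u)
    }
    nn <- vnorm(u)
    if (nn < 1e-12) stop(degenerate_error("degenerate altitude"))
    u / nn
  }

  sph_c <- NULL; sph_r <- NULL; sph_o <- NULL; sph_tr <- list()
  qd_M <- list(); qd_z <- NULL; qd_k <- NULL; qd_tr <- list(); qd_bb <- NULL
  qd_meta <- list()

  add_sphere <- function(center, radius, orient, trims) {
    sph_c <<- rbind(sph_c, center)
    sph_r <<- c(sph_r, radius)
    sph_o <<- c(sph_o, orient)
    sph_tr[[length(sph_tr) + 1L]] <<- trims
  }

  # vertex cells: sphere radius sqrt(s) r_i, trims toward each coface edge
  for (i in rt$verts) {
    trims <- list()
    for (e in inc$vert2edge[[i]] %||% integer(0)) {
      vjs <- setdiff(rt$edges[e, ], i)
      n <- altitude_normal(C[i, , drop = FALSE], C[vjs, ])
      anchor <- (1 - s) * C[i, ] + s * oc_edge[[e]]$z
      trims[[length(trims) + 1L]] <- trim_halfspace(n, sum(n * anchor))
    }
    add_sphere(C[i, ], sqrt(s) * R[i], 1, trims)
  }

  # tetrahedron cells: interstitial void spheres where R2 < 0
  if (nrow(rt$tets)) {
    tet_tris <- function(tet)
      rbind(tet[c(1L, 2L, 3L)], tet[c(1L, 2L, 4L)], tet[c(1L, 3L, 4L)],
            tet[c(2L, 3L, 4L)])
    rk <- simplex_key(rt$tris)
    for (t in seq_len(nrow(rt$tets))) {
      oc <- oc_tet[[t]]
      if (oc$R2 >= -1e-12) next
      tet <- rt$tets[t, ]
      trims <- list()
      faces <- tet_tris(tet)
      fids <- match(simplex_key(canon_rows(faces)), rk)
      for (q in seq_len(4L)) {
        W <- faces[q, ]; v <- setdiff(tet, W)
        n <- altitude_normal(C[W, , drop = FALSE], C[v, ])
        anchor <- (1 - s) * oc_tri[[fids[q]]]$z + s * oc$z
        # keep n . x >= n . anchor  ->  (-n) . x <= (-n) . anchor
        trims[[length(trims) + 1L]] <- trim_halfspace(-n, -sum(n * anchor))
      }
      add_sphere(oc$z, sqrt((1 - s) * (-oc$R2)), -1, trims)
    }
  }

  # edge cells: hyperboloids of revolution about the edge
  if (nrow(rt$edges)) {
    for (e in seq_len(nrow(rt$edges))) {
      oc <- oc_edge[[e]]
      a <- rt$edges[e, 1L]; b <- rt$edges[e, 2L]
      u <- unitize(C[b, ] - C[a, ])
      P <- outer(u, u)
      Mq <- (1 - s) * (diag(3L) - P) - s * P
      kq <- s * (1 - s) * oc$R2
      trims <- list(); tvals <- numeric(0)
      for (vtx in c(a, b)) {        # faces: the two vertex cells
        n <- altitude_normal(C[vtx, , drop = FALSE],
                             C[setdiff(c(a, b), vtx), ])
        anchor <- (1 - s) * C[vtx, ] + s * oc$z
        trims[[length(trims) + 1L]] <- trim_halfspace(-n, -sum(n * anchor))
        tvals <- c(tvals, sum(u * (anchor - oc$z)))
      }
      for (f in inc$edge2tri[[e]] %||% integer(0)) {   # cofaces
        v <- setdiff(rt$tris[f, ], c(a, b))
        n <- altitude_normal(C[c(a, b), , drop = FALSE], C[v, ])
        anchor <- (1 - s) * oc$z + s * oc_tri[[f]]$z
        trims[[length(trims) + 1L]] <- trim_halfspace(n, sum(n * anchor))
      }
      tmax <- max(abs(tvals))
      rho <- sqrt(max(0, s * (oc$R2 + tmax^2 / (1 - s))))
      half <- tmax + rho
      qd_M[[length(qd_M) + 1L]] <- Mq
      qd_z <- rbind(qd_z, oc$z)
      qd_k <- c(qd_k, kq)
      qd_tr[[length(qd_tr) + 1L]] <- trims
      qd_bb <- rbind(qd_bb, c(oc$z - half, oc$z + half))
      qd_meta[[length(qd_meta) + 1L]] <-
        list(kdim = 1L, axis = u, s = s, R2 = oc$R2, extent = tmax)
    }
  }

  # triangle cells: hyperboloids of revolution about the triangle normal
  if (nrow(rt$tris)) {
    ek <- simplex_key(rt$edges)
    for (f in seq_len(nrow(rt$tris))) {
      oc <- oc_tri[[f]]
      tri <- rt$tris[f, ]
      e1 <- C[tri[2L], ] - C[tri[1L], ]; e2 <- C[tri[3L], ] - C[tri[1L], ]
      nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
               e1[3L] * e2[1L] - e1[1L] * e2[3L],
               e1[1L] * e2[2L] - e1[2L] * e2[1L])
      nrm <- unitize(nrm)
      P <- outer(nrm, nrm)
      Mq <- (1 - s) * P - s * (diag(3L) - P)
      kq <- s * (1 - s) * oc$R2
      trims <- list(); anchors <- NULL
      edges_of <- rbind(tri[c(1L, 2L)], tri[c(1L, 3L)], tri[c(2L, 3L)])
      eids <- match(simplex_key(canon_rows(edges_of)), ek)
      for (q in seq_len(3L)) {      # faces: edge cells
        W <- edges_of[q, ]; v <- setdiff(tri, W)
        n <- altitude_normal(C[W, , drop = FALSE], C[v, ])
        anchor <- (1 - s) * oc_edge[[eids[q]]]$z + s * oc$z
        trims[[length(trims) + 1L]] <- trim_halfspace(-n, -sum(n * anchor))
        anchors <- rbind(anchors, anchor)
      }
      for (t in inc$tri2tet[[f]] %||% integer(0)) {    # cofaces: tet cells
        v <- setdiff(rt$tets[t, ], tri)
        n <- altitude_normal(C[tri, , drop = FALSE], C[v, ])
        anchor <- (1 - s) * oc$z + s * oc_tet[[t]]$z
        trims[[length(trims) + 1L]] <- trim_halfspace(n, sum(n * anchor))
      }
      # in-plane extent from the three face planes, conservative
      rho_d <- skin_tri_extent(oc$z, nrm, trims[1:3])
      vmax <- sqrt(max(0, s * (oc$R2 + rho_d^2 / (1 - s))))
      half <- rho_d + vmax
      qd_M[[length(qd_M) + 1L]] <- Mq
      qd_z <- rbind(qd_z, oc$z)
      qd_k <- c(qd_k, kq)
      qd_tr[[length(qd_tr) + 1L]] <- trims
      qd_bb <- rbind(qd_bb, c(oc$z - half, oc$z + half))
      qd_meta[[length(qd_meta) + 1L]] <-
        list(kdim = 2L, axis = nrm, s = s, R2 = oc$R2, extent = rho_d)
    }
  }

  spheres <- list(center = sph_c, radius = sph_r, orient = sph_o,
                  trims = sph_tr)
  quadrics <- if (length(qd_M))
    list(M = qd_M, z = qd_z, k = qd_k, trims = qd_tr, bbox = qd_bb,
         meta = qd_meta)
  new_patch_surface(spheres, NULL, quadrics, atoms,
                    list(shrink = s), "skin")
}

# radius of the in-plane polygon cut out by the three face half-planes of a
# triangle mixed cell (corners = pairwise plane intersections in the plane)
skin_tri_extent <- function(z, nrm, face_trims) {
  # build in-plane basis
  a <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unitize(a - sum(a * nrm) * nrm)
  b2 <- c(nrm[2L] * b1[3L] - nrm[3L] * b1[2L],
          nrm[3L] * b1[1L] - nrm[1L] * b1[3L],
          nrm[1L] * b1[2L] - nrm[2L] * b1[1L])
  lines <- lapply(face_trims, function(tr) {
    n2 <- c(sum(tr$n * b1), sum(tr$n * b2))
    c(n2, tr$b - sum(tr$n * z))          # n2 . y <= b (in-plane coords)
  })
  rho <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    A <- rbind(lines[[i]][1:2], lines[[j]][1:2])
    if (abs(det(A)) < 1e-12) next
    y <- solve(A, c(lines[[i]][3L], lines[[j]][3L]))
    rho <- max(rho, vnorm(y))
  }
  if (rho == 0) 1e3 else rho
}
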