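# PDE-solver-ready grid coloring (solute/solvent medium at cube centers
# and face centers), boundary grid point detection, and projection of
# boundary points onto the surface through an auxiliary 3-D cell grid.

#' Color the grid for a finite-difference solver
#'
#' Copies the in/out labels of a cast [cast_grid_rays()] status grid,
#' after applying the cavity policy: `"keep"` leaves cavities as solvent,
#' `"fill_below"` fills cavities smaller than `min_volume`, `"fill_all"`
#' fills every cavity.
#'
#' @param status A `status_grid`.
#' @param fill_policy `"keep"`, `"fill_below"` or `"fill_all"`.
#' @param min_volume Threshold for `"fill_below"` (Angstrom^3).
#' @return A `color_map`: `center` and `face` label arrays (TRUE =
#'   solute), the grid, and the fill log.
#' @export
color_grid <- function(status, fill_policy = c("keep", "fill_below",
                                               "fill_all"),
                       min_volume = 11.49) {
  fill_policy <- match.arg(fill_policy)
  if (fill_policy != "keep") {
    cav <- detect_cavities(status)
    status <- fill_cavities(status, cav, min_volume = min_volume,
                            fill_all = fill_policy == "fill_all")
  }
  structure(list(center = status$center, face = status$face,
                 grid = status$grid,
                 fill_log = attr(status, "fill_log") %||% integer(0)),
            class = "color_map")
}

#' Find boundary grid points
#'
#' A boundary grid point is a cube whose six faces do not all carry the
#' same medium; these are the points a finite-difference solver projects
#' onto the surface.  Ordering is lexicographic in (i, j, k).
#'
#' @param color A [color_grid()] result.
#' @return `data.frame(i, j, k, x, y, z)` of cube indices and center
#'   coordinates.
#' @export
find_boundary_points <- function(color) {
  stopifnot(inherits(color, "color_map"))
  g <- color$grid; nc <- g$nv - 1L
  fx <- color$face[[1L]]; fy <- color$face[[2L]]; fz <- color$face[[3L]]
  lowx <- fx[1:nc[1L], , , drop = FALSE]
  agree <- (fx[2:(nc[1L] + 1L), , , drop = FALSE] == lowx) &
    (fy[, 1:nc[2L], , drop = FALSE] == lowx) &
    (fy[, 2:(nc[2L] + 1L), , drop = FALSE] == lowx) &
    (fz[, , 1:nc[3L], drop = FALSE] == lowx) &
    (fz[, , 2:(nc[3L] + 1L), drop = FALSE] == lowx)
  idx <- which(!agree)
  ijk <- arrayInd(idx, nc)
  ijk <- ijk[order(ijk[, 1L], ijk[, 2L], ijk[, 3L]), , drop = FALSE]
  data.frame(i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L],
             x = g$origin[1L] + (ijk[, 1L] - 0.5) * g$h,
             y = g$origin[2L] + (ijk[, 2L] - 0.5) * g$h,
             z = g$origin[3L] + (ijk[, 3L] - 0.5) * g$h)
}

# auxiliary 3-D cell grid over patch bounding boxes, with expanding-shell
# candidate gathering
build_accel3d <- function(surface, cell) {
  bb <- surface_bboxes(surface)
  lo <- apply(bb[, 1:3, drop = FALSE], 2L, min) - cell
  hi <- apply(bb[, 4:6, drop = FALSE], 2L, max) + cell
  nc <- pmax(1L, as.integer(ceiling((hi - lo) / cell)))
  cells <- vector("list", prod(nc))
  clamp <- function(v, d) pmax(1L, pmin(nc[d], v))
  for (p in seq_len(nrow(bb))) {
    i0 <- clamp(floor((bb[p, 1:3] - lo) / cell) + 1L, 1:3)
    i1 <- clamp(floor((bb[p, 4:6] - lo) / cell) + 1L, 1:3)
    for (a in i0[1L]:i1[1L]) for (b in i0[2L]:i1[2L])
      for (cc in i0[3L]:i1[3L]) {
        id <- a + (b - 1L) * nc[1L] + (cc - 1L) * nc[1L] * nc[2L]
        cells[[id]] <- c(cells[[id]], p)
      }
  }
  list(lo = lo, cell = cell, nc = nc, cells = cells)
}

accel3d_shell <- function(acc, center_cell, shell) {
  rng <- function(c0, d) {
    v <- (c0 - shell):(c0 + shell)
    v[v >= 1L & v <= acc$nc[d]]
  }
  xs <- rng(center_cell[1L], 1L); ys <- rng(center_cell[2L], 2L)
  zs <- rng(center_cell[3L], 3L)
  out <- integer(0)
  for (a in xs) for (b in ys) for (cc in zs) {
    if (max(abs(c(a, b, cc) - center_cell)) != shell && shell > 0L) next
    out <- c(out, acc$cells[[a + (b - 1L) * acc$nc[1L] +
                               (cc - 1L) * acc$nc[1L] * acc$nc[2L]]])
  }
  unique(out)
}

#' Project points onto a surface
#'
#' For each point, candidate patches are gathered from an auxiliary 3-D
#' cell grid by expanding shells until the nearest candidate is provably
#' global.  The foot point is closed form on spheres, tori, planes and
#' triangles; on skin quadrics it solves the 1-D secular equation of the
#' constrained foot-point problem (damped Newton + bracketed bisection).
#' If the foot violates the patch trims, candidates on the trim boundary
#' circles and a dense parametric sampling of the patch are evaluated
#' instead.
#'
#' @param points n x 3 matrix or a [find_boundary_points()] data frame.
#' @param surface Surface model.
#' @param accel_cell Auxiliary grid cell size (Angstrom); default twice
#'   the mean patch bbox edge is replaced by the caller's grid `2 h` in
#'   the pipeline.
#' @return `data.frame(px, py, pz, dist, patch, residual)`.
#' @export
project_points <- function(points, surface, accel_cell = NULL) {
  pts <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")])
  else if (is.matrix(points)) points else matrix(points, ncol = 3L)
  bb <- surface_bboxes(surface)
  if (is.null(accel_cell)) {
    ext <- bb[, 4:6, drop = FALSE] - bb[, 1:3, drop = FALSE]
    accel_cell <- max(mean(ext), 1e-3)
  }
  acc <- build_accel3d(surface, accel_cell)
  out <- matrix(NA_real_, nrow(pts), 5L)
  for (r in seq_len(nrow(pts))) {
    x <- pts[r, ]
    cc <- pmax(1L, pmin(acc$nc,
                        as.integer(floor((x - acc$lo) / acc$cell)) + 1L))
    best <- NULL; bestd <- Inf
    shell <- 0L; seen <- integer(0)
    max_shell <- max(acc$nc)
    while (shell <= max_shell) {
      cand <- setdiff(accel3d_shell(acc, cc, shell), seen)
      seen <- c(seen, cand)
      for (p in cand) {
        f <- patch_nearest_point(surface, p, x)
        if (!is.null(f) && f$dist < bestd) { bestd <- f$dist; best <- f }
      }
      # a later shell cannot beat the current best once the shell's inner
      # boundary is farther than bestd
      if (!is.null(best) && (shell * acc$cell) > bestd + acc$cell) break
      shell <- shell + 1L
    }
    if (!is.null(best))
      out[r, ] <- c(best$point, best$dist, best$patch)
  }
  res <- surface_residual(surface, out[, 1:3, drop = FALSE])
  data.frame(px = out[, 1L], py = out[, 2L], pz = out[, 3L],
             dist = out[, 4L], patch = out[, 5L], residual = res)
}

# nearest point of patch p (global surface index) to x, honouring trims
patch_nearest_point <- function(surface, p, x) {
  if (inherits(surface, "mesh_surface")) {
    tri <- surface$triangles[p, ]
    V <- surface$vertices
    foot <- point_triangle_foot(matrix(x, 1L), V[tri[1L], ], V[tri[2L], ],
                                V[tri[3L], ])[1L, ]
    return(list(point = foot, dist = vnorm(x - foot), patch = p))
  }
  if (inherits(surface, "field_surface")) {
    return(field_nearest_point(surface, x))
  }
  s <- surface$spheres; to <- surface$tori; q <- surface$quadrics
  ns <- if (is.null(s)) 0L else nrow(s$center)
  nt <- if (is.null(to)) 0L else nrow(to$center)
  cand <- NULL
  if (p <= ns) {
    ctr <- s$center[p, ]; R <- s$radius[p]
    v <- x - ctr; nv <- vnorm(v)
    foot <- if (nv < 1e-12) ctr + c(R, 0, 0) else ctr + R * v / nv
    cand <- trim_filter_candidates(foot, s$trims[[p]],
                                   sphere_trim_boundary_candidates(
                                     ctr, R, s$trims[[p]], x),
                                   function(n) sphere_sample(ctr, R, n))
  } else if (p <= ns + nt) {
    i <- p - ns
    ctr <- to$center[i, ]; ax <- to$axis[i, ]
    Rt <- to$R[i]; rt <- to$r[i]
    v <- x - ctr
    va <- sum(v * ax); rad <- v - va * ax
    nr <- vnorm(rad)
    w <- if (nr < 1e-9) {
      b <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      unitize(b - sum(b * ax) * ax)
    } else rad / nr
    foot_c <- ctr + Rt * w
    u <- x - foot_c
    nu <- vnorm(u)
    foot <- if (nu < 1e-12) foot_c + rt * ax else foot_c + rt * u / nu
    cand <- trim_filter_candidates(foot, to$trims[[i]], NULL,
                                   function(n) torus_sample(ctr, ax, Rt,
                                                            rt, n))
  } else {
    i <- p - ns - nt
    foot <- quadric_foot_point(q$M[[i]], q$z[i, ], q$k[i], x)
    cand <- trim_filter_candidates(foot, q$trims[[i]], NULL,
                                   function(n) quadric_sample(surface, i, n))
  }
  if (is.null(cand)) return(NULL)
  list(point = cand, dist = vnorm(x - cand), patch = p)
}

# accept the closed-form foot if it passes the trims; otherwise try the
# explicit boundary candidates, then a dense parametric sampling
trim_filter_candidates <- function(foot, trims, boundary, sampler,
                                   x = NULL) {
  if (!length(trims) || all(point_in_trim(foot, trims))) return(foot)
  pool <- boundary
  if (is.null(pool) || !nrow(pool <- as.matrix(pool)))
    pool <- sampler(2000L)
  keep <- point_in_trim(pool, trims)
  if (!any(keep)) {
    pool <- sampler(8000L)
    keep <- point_in_trim(pool, trims)
    if (!any(keep)) return(NULL)
  }
  pool <- pool[keep, , drop = FALSE]
  d2 <- rowSums(sweep(pool, 2L, foot)^2)   # foot ~ x direction proxy
  pool[which.min(d2), ]
}

# circles where the patch sphere meets its trimming spheres/planes, with
# the nearest circle point to x as candidate
sphere_trim_boundary_candidates <- function(ctr, R, trims, x) {
  out <- NULL
  circle_point <- function(cc, ax, rc) {
    v <- x - cc
    v <- v - sum(v * ax) * ax
    nv <- vnorm(v)
    if (nv < 1e-12) return(NULL)
    cc + rc * v / nv
  }
  for (tr in trims) {
    if (tr$kind == "halfspace") {
      d <- tr$b - sum(tr$n * ctr)
      if (abs(d) >= R) next
      out <- rbind(out, circle_point(ctr + d * tr$n, tr$n,
                                     sqrt(R^2 - d^2)))
    } else if (tr$kind %in% c("sphere_out", "sphere_in", "spheres_out")) {
      mats <- if (tr$kind == "spheres_out") tr$mat else
        matrix(c(tr$c, tr$r), 1L)
      for (rr in seq_len(nrow(mats))) {
        c2 <- mats[rr, 1:3]; r2 <- mats[rr, 4L]
        d <- vnorm(c2 - ctr)
        if (d < 1e-12 || d >= R + r2 || d <= abs(R - r2)) next
        a <- (d^2 + R^2 - r2^2) / (2 * d)
        rc2 <- R^2 - a^2
        if (rc2 <= 0) next
        ax <- (c2 - ctr) / d
        out <- rbind(out, circle_point(ctr + a * ax, ax, sqrt(rc2)))
      }
    }
  }
  out
}

sphere_sample <- function(ctr, R, n) {
  sweep(fibonacci_sphere(n) * R, 2L, ctr, `+`)
}

torus_sample <- function(ctr, ax, Rt, rt, n) {
  b1 <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unitize(b1 - sum(b1 * ax) * ax)
  b2 <- c(ax[2L] * b1[3L] - ax[3L] * b1[2L],
          ax[3L] * b1[1L] - ax[1L] * b1[3L],
          ax[1L] * b1[2L] - ax[2L] * b1[1L])
  m <- max(8L, as.integer(ceiling(sqrt(n))))
  th <- seq(0, 2 * pi, length.out = m + 1L)[-1L]
  ph <- seq(0, 2 * pi, length.out = m + 1L)[-1L]
  g <- expand.grid(th = th, ph = ph)
  wd <- cbind(cos(g$th)) %*% rbind(b1) + cbind(sin(g$th)) %*% rbind(b2)
  foot <- sweep(Rt * wd, 2L, ctr, `+`)
  foot + rt * (cos(g$ph) * wd + sin(g$ph) %*% rbind(ax))
}

# foot point on a centered quadric y' M y = k via the secular equation:
# y(lam) = (I + 2 lam M)^{-1} x', root of g(lam) = y' M y - k
quadric_foot_point <- function(M, z, k, x) {
  eg <- eigen(M, symmetric = TRUE)
  xp <- as.numeric(crossprod(eg$vectors, x - z))
  m <- eg$values
  g <- function(lam) {
    y <- xp / (1 + 2 * lam * m)
    sum(m * y^2) - k
  }
  # bracket the root nearest lam = 0 between the surrounding poles
  poles <- -1 / (2 * m[m != 0])
  lo_p <- suppressWarnings(max(poles[poles < 0], -1e6))
  hi_p <- suppressWarnings(min(poles[poles > 0], 1e6))
  eps <- 1e-9 * (abs(lo_p) + abs(hi_p) + 1)
  g0 <- g(0)
  root <- NA_real_
  if (abs(g0) < 1e-14) root <- 0 else {
    # scan outward on both sides for a sign change, then bisect
    for (side in c(1, -1)) {
      lims <- if (side > 0) hi_p - eps else lo_p + eps
      lam <- 0; glam <- g0
      for (step in 2^seq(-20, 20, length.out = 60)) {
        cand <- side * step
        if ((side > 0 && cand >= lims) || (side < 0 && cand <= lims))
          cand <- lims
        gc <- g(cand)
        if (is.finite(gc) && sign(gc) != sign(glam)) {
          lo <- min(lam, cand); hi <- max(lam, cand)
          for (it in 1:200) {
            mid <- (lo + hi) / 2
            gm <- g(mid)
            if (sign(gm) == sign(g(lo))) lo <- mid else hi <- mid
            if (hi - lo < 1e-14 * max(1, abs(mid))) break
          }
          cand_root <- (lo + hi) / 2
          if (is.na(root) || abs(cand_root) < abs(root)) root <- cand_root
          break
        }
        lam <- cand; glam <- gc
        if (cand == lims) break
      }
    }
  }
  if (is.na(root)) return(z + (x - z) * 0)   # degenerate: return center
  y <- xp / (1 + 2 * root * m)
  as.numeric(eg$vectors %*% y) + z
}

quadric_sample <- function(surface, i, n) {
  q <- surface$quadrics
  meta <- q$meta[[i]]
  z <- q$z[i, ]
  ax <- meta$axis; s <- meta$s; R2 <- meta$R2
  b1 <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unitize(b1 - sum(b1 * ax) * ax)
  b2 <- c(ax[2L] * b1[3L] - ax[3L] * b1[2L],
          ax[3L] * b1[1L] - ax[1L] * b1[3L],
          ax[1L] * b1[2L] - ax[2L] * b1[1L])
  m <- max(10L, as.integer(ceiling(sqrt(n))))
  half <- meta$extent
  ts <- seq(-half, half, length.out = m)
  th <- seq(0, 2 * pi, length.out = m + 1L)[-1L]
  g <- expand.grid(t = ts, th = th)
  if (meta$kdim == 1L) {
    rho2 <- s * (R2 + g$t^2 / (1 - s))
    ok <- rho2 > 0
    rho <- sqrt(rho2[ok])
    pts <- outer(g$t[ok], ax) + rho * (cos(g$th[ok]) %*% rbind(b1) +
                                         sin(g$th[ok]) %*% rbind(b2))
  } else {
    # revolution about the triangle normal: t is the in-plane radius
    tt <- abs(g$t)
    v2 <- s * (R2 + tt^2 / (1 - s))
    ok <- v2 >= 0
    vv <- sqrt(v2[ok]) * sign(g$t[ok])
    pts <- outer(vv, ax) + tt[ok] * (cos(g$th[ok]) %*% rbind(b1) +
                                       sin(g$th[ok]) %*% rbind(b2))
  }
  sweep(pts, 2L, z, `+`)
}

field_nearest_point <- function(surface, x) {
  g <- field_gradient(surface, matrix(x, 1L))[1L, ]
  d <- unitize(if (vnorm(g) < 1e-12) c(1, 0, 0) else g)
  f0 <- field_interp(surface, matrix(x, 1L)) - surface$iso
  h <- surface$grid$h
  span <- sum(grid_span(surface$grid))
  step <- h / 8
  for (sgn in c(1, -1)) {
    t <- 0
    repeat {
      t <- t + step
      if (t > span) break
      ft <- field_interp(surface, matrix(x + sgn * t * d, 1L)) -
        surface$iso
      if (sign(ft) != sign(f0)) {
        lo <- t - step; hi <- t
        while (hi - lo > 1e-9) {
          mid <- (lo + hi) / 2
          fm <- field_interp(surface, matrix(x + sgn * mid * d, 1L)) -
            surface$iso
          if (sign(fm) == sign(f0)) lo <- mid else hi <- mid
        }
        p <- x + sgn * (lo + hi) / 2 * d
        return(list(point = p, dist = (lo + hi) / 2, patch = 1L))
      }
    }
  }
  NULL
}

#' Export a color map as flat text voxel files
#'
#' Writes `<stem>_centers.txt` and one `<stem>_face<x|y|z>.txt`, each with
#' a `nx ny nz ox oy oz h` header line followed by 0/1 labels, x-fastest.
#'
#' @param color A [color_grid()] result.
#' @param stem Output path stem.
#' @return The paths written, invisibly.
#' @export
write_colormap <- function(color, stem) {
  g <- color$grid
  wr <- function(arr, path) {
    con <- file(path, "w"); on.exit(close(con))
    d <- dim(arr)
    writeLines(sprintf("%d %d %d %.10g %.10g %.10g %.10g",
                       d[1L], d[2L], d[3L], g$origin[1L], g$origin[2L],
                       g$origin[3L], g$h), con)
    writeLines(paste(as.integer(arr), collapse = " "), con)
  }
  paths <- c(paste0(stem, "_centers.txt"),
             paste0(stem, "_face", c("x", "y", "z"), ".txt"))
  wr(color$center, paths[1L])
  for (ax in 1:3) wr(color$face[[ax]], paths[ax + 1L])
  invisible(paths)
}

#' Write boundary points and their projections as TSV
#'
#' Columns: i, j, k, px, py, pz, dist.
#'
#' @param boundary A [find_boundary_points()] data frame.
#' @param projected The matching [project_points()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_boundary_points <- function(boundary, projected, path) {
  df <- cbind(boundary[, c("i", "j", "k")],
              projected[, c("px", "py", "pz", "dist")])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
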