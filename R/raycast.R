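# Cubic grid construction, 2-D per-axis acceleration structures, and the
# parity-checked casting of Grid Rays (cube centers + face centers) and
# Edge Rays (cube vertices + analytic intersections on grid edges).

#' Build the cubic lattice around an atom set or bounding box
#'
#' The grid spacing is `h = 1/scale`; the cubic span is the largest side of
#' the (inflated) bounding box times `100/perfil`, centered on the system,
#' rounded up so each axis has an odd number of vertices.  Rays then start
#' and end strictly outside the surface.
#'
#' @param x An [atom_set()] or a 2 x 3 matrix `rbind(min, max)`.
#' @param scale Grids per Angstrom (`> 0`).
#' @param perfil Percentage of the grid span occupied by the solute
#'   bounding box (0 < perfil < 100).
#' @param inflate Extra margin added around the atoms (e.g. the probe
#'   radius), Angstrom.
#' @param max_vertices Error out above this total vertex count.
#' @return A `grid3d` object: `origin` (vertex 0), spacing `h`, vertex
#'   counts `nv`, and the request parameters.
#' @examples
#' g <- make_grid(gen_sphere_atom(1)$atoms, scale = 2, perfil = 50)
#' g$h          # 0.5
#' @export
make_grid <- function(x, scale = 2, perfil = 90, inflate = 0,
                      max_vertices = 2e7) {
  stopifnot(scale > 0, perfil > 0, perfil < 100)
  bb <- if (inherits(x, "atom_set")) {
    C <- atom_centers(x); r <- x$radius + inflate
    rbind(apply(C - r, 2L, min), apply(C + r, 2L, max))
  } else {
    stopifnot(is.matrix(x), all(dim(x) == c(2L, 3L)))
    x
  }
  side <- max(bb[2L, ] - bb[1L, ])
  if (side <= 0) side <- 1
  h <- 1 / scale
  span <- side * 100 / perfil
  ncell <- max(2L, 2L * as.integer(ceiling(span / (2 * h))))
  nv <- ncell + 1L
  if (nv^3 > max_vertices)
    stop("grid of ", nv, "^3 vertices exceeds max_vertices; ",
         "use a lower scale or higher perfil")
  center <- (bb[1L, ] + bb[2L, ]) / 2
  origin <- center - ncell * h / 2
  structure(list(origin = origin, h = h, nv = rep(nv, 3L),
                 scale = scale, perfil = perfil, bbox = bb),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d: %d^3 vertices, h = %.4g A, origin (%.3g, %.3g, %.3g)>\n",
              x$nv[1L], x$h, x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

grid_span <- function(grid) (grid$nv - 1L) * grid$h

# coordinates of cube centers / vertices along one axis
grid_center_coords <- function(grid, axis)
  grid$origin[axis] + (seq_len(grid$nv[axis] - 1L) - 0.5) * grid$h
grid_vertex_coords <- function(grid, axis)
  grid$origin[axis] + (seq_len(grid$nv[axis]) - 1L) * grid$h

#' Build the 2-D acceleration lattice for one casting axis
#'
#' Patch bounding boxes are projected on the plane orthogonal to `axis`;
#' each 2-D cell lists every patch whose projection intersects it, so the
#' list in a ray's cell is always a superset of the patches the ray can
#' hit.
#'
#' @param surface A surface model.
#' @param grid A [make_grid()] lattice.
#' @param axis Casting axis (1, 2 or 3).
#' @param cell Cell size of the 2-D lattice (default `2 * h`).
#' @return An `accel2d` object with a `lookup(u, v)` candidate query.
#' @export
build_accel <- function(surface, grid, axis, cell = 2 * grid$h) {
  d <- setdiff(1:3, axis)
  bb <- surface_bboxes(surface)
  lo <- grid$origin[d] - cell          # one-cell margin for jittered rays
  span <- grid_span(grid)[d] + 2 * cell
  nc <- pmax(1L, as.integer(ceiling(span / cell)))
  cells <- vector("list", prod(nc))
  if (!is.null(bb) && nrow(bb)) {
    i1 <- pmax(1L, pmin(nc[1L], floor((bb[, d[1L]] - lo[1L]) / cell) + 1L))
    i2 <- pmax(1L, pmin(nc[1L] * 0L + nc[2L],
                        floor((bb[, d[2L]] - lo[2L]) / cell) + 1L))
    j1 <- pmax(1L, pmin(nc[1L], floor((bb[, d[1L] + 3L] - lo[1L]) / cell) + 1L))
    j2 <- pmax(1L, pmin(nc[2L], floor((bb[, d[2L] + 3L] - lo[2L]) / cell) + 1L))
    # drop patches entirely outside the lattice
    out <- bb[, d[1L] + 3L] < lo[1L] | bb[, d[2L] + 3L] < lo[2L] |
      bb[, d[1L]] > lo[1L] + span[1L] | bb[, d[2L]] > lo[2L] + span[2L]
    for (p in which(!out)) {
      for (a in i1[p]:j1[p]) for (b in i2[p]:j2[p]) {
        id <- a + (b - 1L) * nc[1L]
        cells[[id]] <- c(cells[[id]], p)
      }
    }
  }
  structure(list(axis = axis, d = d, lo = lo, cell = cell, nc = nc,
                 cells = cells),
            class = "accel2d")
}

accel_candidates <- function(accel, u, v) {
  if (is.null(accel)) return(NULL)
  a <- floor((u - accel$lo[1L]) / accel$cell) + 1L
  b <- floor((v - accel$lo[2L]) / accel$cell) + 1L
  if (a < 1L || b < 1L || a > accel$nc[1L] || b > accel$nc[2L])
    return(integer(0))
  accel$cells[[a + (b - 1L) * accel$nc[1L]]] %||% integer(0)
}

#' Cast one axis-aligned ray with the parity-checksum protocol
#'
#' The hit count of a ray whose endpoints are outside a closed surface must
#' be even.  On an odd count, the ray is re-cast with the same small random
#' transverse perturbation applied to both endpoints, up to `retry` times;
#' the caller falls back to the nearest completed parallel ray when all
#' retries fail.
#'
#' @param surface Surface model.
#' @param origin,dir,t_max The ray (axis-aligned `dir` for grid rays).
#' @param accel Optional [build_accel()] structure for `dir`'s axis.
#' @param retry Maximum number of jittered re-casts (default 5).
#' @param eps Jitter magnitude (Angstrom).
#' @param seed Integer seed; jitters are deterministic in it.
#' @return List with `hits` (`data.frame(t, nx, ny, nz, patch)`, t relative
#'   to the *original* origin), `retries` used, and `ok` (parity met).
#' @export
cast_ray_checked <- function(surface, origin, dir, t_max, accel = NULL,
                             retry = 5L, eps = 0.01, seed = 1L) {
  d <- setdiff(1:3, which.max(abs(dir)))
  off <- c(0, 0, 0)
  for (att in 0:retry) {
    o <- origin + off
    cand <- if (is.null(accel)) NULL else
      accel_candidates(accel, o[d[1L]], o[d[2L]])
    hits <- surface_ray_hits(surface, o, dir, t_max, candidates = cand)
    if (nrow(hits) %% 2L == 0L)
      return(list(hits = hits, retries = att, ok = TRUE))
    jit <- with_seed(derive_seed(seed, att), function()
      stats::runif(2L, -eps, eps))
    off <- c(0, 0, 0)
    off[d] <- jit
  }
  list(hits = hits, retries = retry, ok = FALSE)
}

# ---- internal: cast all rays of one axis over one transverse lattice ----
#
# lattice = "center" (rays through cube centers: Grid Rays) or "vertex"
# (rays along cube edges: Edge Rays).  Returns per-ray sorted hit vectors
# (absolute coordinate along the axis), per-hit axis-normal components,
# and the cast report fields.
cast_axis_lattice <- function(surface, grid, axis, lattice, accel,
                              retry, eps, seed) {
  d <- setdiff(1:3, axis)
  if (is.list(lattice)) {
    u1 <- lattice$u1; u2 <- lattice$u2
    lattice <- "custom"
  } else {
    u1 <- if (lattice == "center") grid_center_coords(grid, d[1L]) else
      grid_vertex_coords(grid, d[1L])
    u2 <- if (lattice == "center") grid_center_coords(grid, d[2L]) else
      grid_vertex_coords(grid, d[2L])
  }
  x0 <- grid$origin[axis] - grid$h
  t_max <- grid_span(grid)[axis] + 2 * grid$h
  dir <- c(0, 0, 0); dir[axis] <- 1
  n1 <- length(u1); n2 <- length(u2)
  hits_t <- vector("list", n1 * n2)
  hits_c <- vector("list", n1 * n2)
  retries <- integer(n1 * n2)
  fellback <- logical(n1 * n2)
  last_good <- NULL
  lat_code <- switch(lattice, center = 1L, vertex = 2L, custom = 3L)
  for (b in seq_len(n2)) for (a in seq_len(n1)) {
    id <- a + (b - 1L) * n1
    o <- numeric(3L)
    o[axis] <- x0; o[d[1L]] <- u1[a]; o[d[2L]] <- u2[b]
    res <- cast_ray_checked(surface, o, dir, t_max, accel = accel,
                            retry = retry, eps = eps,
                            seed = derive_seed(seed, axis, lat_code, a, b))
    retries[id] <- res$retries
    if (!res$ok) {
      if (is.null(last_good))
        stop("parity failure with no stable neighbouring ray to copy")
      hits_t[[id]] <- last_good$t
      hits_c[[id]] <- last_good$c
      fellback[id] <- TRUE
      next
    }
    ht <- x0 + res$hits$t                 # absolute axis coordinate
    hc <- res$hits[[c("nx", "ny", "nz")[axis]]]
    hits_t[[id]] <- ht
    hits_c[[id]] <- hc
    last_good <- list(t = ht, c = hc)
  }
  list(axis = axis, d = d, lattice = lattice, n1 = n1, n2 = n2,
       hits_t = hits_t, hits_c = hits_c, retries = retries,
       fellback = fellback)
}

# classify sample coordinates along the axis for every ray of a lattice
# cast: inside iff an odd number of hits lies below the coordinate.
classify_lattice <- function(cast, coords) {
  n <- cast$n1 * cast$n2
  out <- matrix(FALSE, n, length(coords))
  for (id in seq_len(n)) {
    ht <- cast$hits_t[[id]]
    if (length(ht))
      out[id, ] <- (findInterval(coords, ht) %% 2L) == 1L
  }
  out
}

# place a (ray-id, along-axis) matrix into a 3-D array for a given axis
lattice_to_array <- function(m, axis, n1, n2, nax) {
  arr <- switch(axis,
                aperm(array(t(m), dim = c(nax, n1, n2)), c(1L, 2L, 3L)),
                aperm(array(t(m), dim = c(nax, n1, n2)), c(2L, 1L, 3L)),
                aperm(array(t(m), dim = c(nax, n1, n2)), c(2L, 3L, 1L)))
  arr
}

#' Cast Grid Rays: in/out status at cube centers and face centers
#'
#' One axis-aligned ray is cast per cube-center row for each requested
#' axis.  Each axis classifies every cube center (disagreements between
#' the three axes are resolved by majority and counted) and the face
#' centers perpendicular to it.  Per-ray inside intervals are retained for
#' volume estimation and the incident-ray area estimator.
#'
#' @param surface Surface model.
#' @param grid A [make_grid()] lattice enclosing the surface.
#' @param axes Casting axes (default all three).
#' @param retry,eps,seed Parity protocol settings; `eps` defaults to
#'   `0.01 * h`.
#' @param accel Optional list of [build_accel()] per axis.
#' @return A `status_grid` (centers, face centers, per-ray hits, report).
#' @export
cast_grid_rays <- function(surface, grid, axes = 1:3, retry = 5L,
                           eps = 0.01 * grid$h, seed = 1L, accel = NULL) {
  nc <- grid$nv - 1L
  center_axis <- list(); face <- list(); casts <- list()
  for (ax in axes) {
    acc <- if (is.null(accel)) build_accel(surface, grid, ax) else
      accel[[ax]]
    cast <- cast_axis_lattice(surface, grid, ax, "center", acc,
                              retry, eps, seed)
    cc <- classify_lattice(cast, grid_center_coords(grid, ax))
    vv <- classify_lattice(cast, grid_vertex_coords(grid, ax))
    center_axis[[ax]] <- lattice_to_array(cc, ax, cast$n1, cast$n2, nc[ax])
    face[[ax]] <- lattice_to_array(vv, ax, cast$n1, cast$n2, grid$nv[ax])
    casts[[ax]] <- cast
  }
  used <- axes
  votes <- Reduce(`+`, lapply(center_axis[used], function(a) a * 1L))
  need <- ceiling((length(used) + 1L) / 2)     # ties (impossible for 3) -> out
  center <- votes >= if (length(used) == 2L) 2L else need
  disagree <- if (length(used) > 1L)
    sum(votes > 0L & votes < length(used)) else 0L
  report <- list(
    rays = sum(vapply(casts[used], function(cs) cs$n1 * cs$n2, 1)),
    retries = sum(vapply(casts[used], function(cs) sum(cs$retries), 1)),
    fallbacks = sum(vapply(casts[used], function(cs) sum(cs$fellback), 1)),
    parity_failures = sum(vapply(casts[used],
                                 function(cs) sum(cs$fellback), 1)),
    center_disagreements = disagree)
  structure(list(grid = grid, center = center, center_axis = center_axis,
                 face = face, casts = casts, report = report, seed = seed),
            class = "status_grid")
}

#' Cast Edge Rays: cube-vertex status and analytic edge intersections
#'
#' One ray per lattice line through the cube vertices, for each axis.
#' Vertex in/out statuses come from hit parity (majority across the three
#' axes); every intersection is stored on its containing grid edge with
#' its analytic position and normal, feeding the analytic-vertex marching
#' cubes.
#'
#' @inheritParams cast_grid_rays
#' @return An `edge_rays` object: `vertex` logical array, per-axis edge
#'   hit stores, and the cast report.
#' @export
cast_edge_rays <- function(surface, grid, axes = 1:3, retry = 5L,
                           eps = 0.01 * grid$h, seed = 1L, accel = NULL) {
  nv <- grid$nv; nc <- nv - 1L
  vertex_axis <- list(); edge <- list(); casts <- list()
  for (ax in axes) {
    acc <- if (is.null(accel)) build_accel(surface, grid, ax) else
      accel[[ax]]
    cast <- cast_axis_lattice(surface, grid, ax, "vertex", acc,
                              retry, eps, seed + 7L)
    vv <- classify_lattice(cast, grid_vertex_coords(grid, ax))
    vertex_axis[[ax]] <- lattice_to_array(vv, ax, cast$n1, cast$n2, nv[ax])
    edge[[ax]] <- edge_hits_from_cast(cast, grid, ax)
    casts[[ax]] <- cast
  }
  votes <- Reduce(`+`, lapply(vertex_axis[axes], function(a) a * 1L))
  vertex <- votes >= if (length(axes) == 2L) 2L else
    ceiling((length(axes) + 1L) / 2)
  report <- list(
    rays = sum(vapply(casts[axes], function(cs) cs$n1 * cs$n2, 1)),
    retries = sum(vapply(casts[axes], function(cs) sum(cs$retries), 1)),
    fallbacks = sum(vapply(casts[axes], function(cs) sum(cs$fellback), 1)))
  structure(list(grid = grid, vertex = vertex, vertex_axis = vertex_axis,
                 edge = edge, casts = casts, report = report),
            class = "edge_rays")
}

# collect, for every grid edge along `axis`, the first and last stored hit
# (absolute coordinate + axis normal component) and the full hit table.
edge_hits_from_cast <- function(cast, grid, axis) {
  nv <- grid$nv; nc <- nv - 1L
  dims <- nv; dims[axis] <- nc[axis]
  first_t <- array(NA_real_, dims); last_t <- array(NA_real_, dims)
  first_c <- array(NA_real_, dims); last_c <- array(NA_real_, dims)
  count <- array(0L, dims)
  d <- cast$d
  rows <- integer(0); tcol <- numeric(0)
  for (b in seq_len(cast$n2)) for (a in seq_len(cast$n1)) {
    id <- a + (b - 1L) * cast$n1
    ht <- cast$hits_t[[id]]
    if (!length(ht)) next
    hc <- cast$hits_c[[id]]
    seg <- floor((ht - grid$origin[axis]) / grid$h) + 1L
    ok <- seg >= 1L & seg <= nc[axis]
    for (q in which(ok)) {
      idx3 <- integer(3L)
      idx3[axis] <- seg[q]; idx3[d[1L]] <- a; idx3[d[2L]] <- b
      im <- matrix(idx3, 1L)
      count[im] <- count[im] + 1L
      if (is.na(first_t[im]) || ht[q] < first_t[im]) {
        first_t[im] <- ht[q]; first_c[im] <- hc[q]
      }
      if (is.na(last_t[im]) || ht[q] > last_t[im]) {
        last_t[im] <- ht[q]; last_c[im] <- hc[q]
      }
    }
  }
  list(axis = axis, first_t = first_t, last_t = last_t,
       first_c = first_c, last_c = last_c, count = count)
}

#' Full grid inspection of a surface
#'
#' Convenience wrapper running [cast_grid_rays()] and [cast_edge_rays()]
#' with shared acceleration structures and assembling one status object.
#'
#' @inheritParams cast_grid_rays
#' @param edge_rays Cast Edge Rays too (needed for the analytic marching
#'   cubes; [mc_bisecting()] works without them).
#' @return A `status_grid` with the `edge_rays` result attached as
#'   `$edges` when requested.
#' @export
cast_surface <- function(surface, grid, retry = 5L, eps = 0.01 * grid$h,
                         seed = 1L, edge_rays = TRUE) {
  accel <- lapply(1:3, function(ax) build_accel(surface, grid, ax))
  sg <- cast_grid_rays(surface, grid, retry = retry, eps = eps,
                       seed = seed, accel = accel)
  if (edge_rays)
    sg$edges <- cast_edge_rays(surface, grid, retry = retry, eps = eps,
                               seed = seed, accel = accel)
  sg
}

#' Dump a status grid as a flat text voxel file
#'
#' Header line: `nx ny nz ox oy oz h`; then one status value (0 = outside,
#' 1 = inside) per cube center, x-fastest.
#'
#' @param status A `status_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_status_grid <- function(status, path) {
  g <- status$grid; nc <- g$nv - 1L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g %.10g",
                     nc[1L], nc[2L], nc[3L],
                     g$origin[1L], g$origin[2L], g$origin[3L], g$h), con)
  writeLines(paste(as.integer(aperm(status$center, c(1L, 2L, 3L))),
                   collapse = " "), con)
  invisible(path)
}
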