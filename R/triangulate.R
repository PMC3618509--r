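# Grid-consistent triangulation: analytic-vertex marching cubes (vertices
# are the stored ray/surface intersections on cube edges) and the
# bisecting variant (vertex statuses inferred from cube centers, midpoint
# vertices), plus smoothing, area accounting, the incident-ray area
# estimator, and mesh export.
#
# The 256-case marching-cubes table is generated, once per session, by
# contour tracing: crossings on the 12 cube edges are connected across
# each face (an ambiguous face with four crossings pairs the edges
# flanking each *inside* corner, so the outside region stays connected
# across the face); the resulting closed loops are oriented outward and
# fanned into triangles.  Because the face rule depends only on the shared
# face's corner statuses, adjacent cubes always agree and the mesh is
# crack-free on parity-consistent input.

# corner index = bx + 2 by + 4 bz (0..7); edges 1..12
mc_cube_topology <- function() {
  corners <- as.matrix(expand.grid(bx = 0:1, by = 0:1, bz = 0:1))
  edges <- rbind(
    # axis 1 (x) edges: (by, bz) = 00, 10, 01, 11
    cbind(a = c(0L, 2L, 4L, 6L), b = c(1L, 3L, 5L, 7L)),
    # axis 2 (y) edges: (bx, bz)
    cbind(a = c(0L, 1L, 4L, 5L), b = c(2L, 3L, 6L, 7L)),
    # axis 3 (z) edges: (bx, by)
    cbind(a = c(0L, 1L, 2L, 3L), b = c(4L, 5L, 6L, 7L)))
  faces <- list(
    c(0L, 2L, 6L, 4L),   # x = 0
    c(1L, 3L, 7L, 5L),   # x = 1
    c(0L, 1L, 5L, 4L),   # y = 0
    c(2L, 3L, 7L, 6L),   # y = 1
    c(0L, 1L, 3L, 2L),   # z = 0
    c(4L, 5L, 7L, 6L))   # z = 1
  edge_of <- function(a, b) {
    hit <- which((edges[, 1L] == a & edges[, 2L] == b) |
                   (edges[, 1L] == b & edges[, 2L] == a))
    hit[1L]
  }
  face_edges <- lapply(faces, function(fc) {
    vapply(1:4, function(q)
      edge_of(fc[q], fc[q %% 4L + 1L]), integer(1L))
  })
  list(corners = corners, edges = edges, faces = faces,
       face_edges = face_edges)
}

# loops (oriented edge-id sequences) for one corner-status byte
mc_trace_case <- function(status, topo) {
  cross <- status[topo$edges[, 1L] + 1L] != status[topo$edges[, 2L] + 1L]
  if (!any(cross)) return(list())
  partners <- vector("list", 12L)
  for (f in seq_along(topo$faces)) {
    fc <- topo$faces[[f]]; fe <- topo$face_edges[[f]]
    cr <- which(cross[fe])
    if (length(cr) == 2L) {
      e1 <- fe[cr[1L]]; e2 <- fe[cr[2L]]
      partners[[e1]] <- c(partners[[e1]], e2)
      partners[[e2]] <- c(partners[[e2]], e1)
    } else if (length(cr) == 4L) {
      # alternating corners: pair the two edges flanking each inside corner
      for (q in 1:4) {
        if (!status[fc[q] + 1L]) next
        ea <- fe[q]; eb <- fe[(q + 2L) %% 4L + 1L]   # edges q and q-1
        partners[[ea]] <- c(partners[[ea]], eb)
        partners[[eb]] <- c(partners[[eb]], ea)
      }
    }
  }
  loops <- list()
  todo <- which(cross)
  visited <- rep(FALSE, 12L)
  for (start in todo) {
    if (visited[start]) next
    loop <- start; visited[start] <- TRUE
    prev <- 0L; cur <- start
    repeat {
      nxt <- setdiff(partners[[cur]], prev)[1L]
      if (is.na(nxt) || nxt == start) break
      loop <- c(loop, nxt)
      visited[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }
  # orient each loop outward using edge-midpoint geometry
  mids <- (topo$corners[topo$edges[, 1L] + 1L, ] +
             topo$corners[topo$edges[, 2L] + 1L, ]) / 2
  lapply(loops, function(loop) {
    P <- mids[loop, , drop = FALSE]
    nloop <- nrow(P)
    Nw <- c(0, 0, 0)
    for (q in seq_len(nloop)) {
      v1 <- P[q, ]; v2 <- P[q %% nloop + 1L, ]
      Nw <- Nw + c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
                   v1[3L] * v2[1L] - v1[1L] * v2[3L],
                   v1[1L] * v2[2L] - v1[2L] * v2[1L])
    }
    e <- loop[1L]
    a <- topo$edges[e, 1L]; b <- topo$edges[e, 2L]
    inside_c <- if (status[a + 1L]) a else b
    outside_c <- if (status[a + 1L]) b else a
    d <- topo$corners[outside_c + 1L, ] - topo$corners[inside_c + 1L, ]
    if (sum(Nw * d) < 0) loop <- rev(loop)
    loop
  })
}

mc_table_env <- new.env(parent = emptyenv())

#' The 256-case marching-cubes triangulation table
#'
#' Generated once per session by the face-consistent contour-tracing rule
#' and cached.  Entry `case + 1` holds the oriented edge-id loops (edges
#' numbered 1-12; x-, then y-, then z-aligned) for the corner-status byte
#' `case` (bit `c` set when corner `c` is inside; corner index
#' `bx + 2 by + 4 bz`).
#'
#' @return List of 256 loop lists.
#' @export
mc_tables <- function() {
  if (!is.null(mc_table_env$tab)) return(mc_table_env$tab)
  topo <- mc_cube_topology()
  tab <- vector("list", 256L)
  for (case in 0:255) {
    status <- as.logical(bitwAnd(case, 2L^(0:7)))
    tab[[case + 1L]] <- mc_trace_case(status, topo)
  }
  mc_table_env$tab <- tab
  mc_table_env$topo <- topo
  tab
}

# global key of a cube-local edge: axis block + linear lattice index
mc_edge_key <- function(edge_local, i, j, k, nv) {
  topo <- mc_table_env$topo
  axis <- (edge_local - 1L) %/% 4L + 1L
  sub <- (edge_local - 1L) %% 4L
  a <- topo$edges[edge_local, 1L]
  off <- topo$corners[a + 1L, ]               # corner at the low end
  ii <- i + off[1L]; jj <- j + off[2L]; kk <- k + off[3L]
  nc <- nv - 1L
  base <- c(0L,
            nc[1L] * nv[2L] * nv[3L],
            nc[1L] * nv[2L] * nv[3L] + nv[1L] * nc[2L] * nv[3L])
  dims <- switch(axis, c(nc[1L], nv[2L], nv[3L]),
                 c(nv[1L], nc[2L], nv[3L]), c(nv[1L], nv[2L], nc[3L]))
  base[axis] + ii + (jj - 1L) * dims[1L] + (kk - 1L) * dims[1L] * dims[2L]
}

mc_edge_unkey <- function(key, nv) {
  nc <- nv - 1L
  n1 <- nc[1L] * nv[2L] * nv[3L]
  n2 <- nv[1L] * nc[2L] * nv[3L]
  axis <- ifelse(key <= n1, 1L, ifelse(key <= n1 + n2, 2L, 3L))
  rel <- key - c(0L, n1, n1 + n2)[axis]
  d1 <- ifelse(axis == 1L, nc[1L], nv[1L])
  d2 <- ifelse(axis == 2L, nc[2L], nv[2L])
  i <- (rel - 1L) %% d1 + 1L
  j <- ((rel - 1L) %/% d1) %% d2 + 1L
  k <- (rel - 1L) %/% (d1 * d2) + 1L
  cbind(axis = axis, i = i, j = j, k = k)
}

# core MC driver shared by the analytic and bisecting variants
mc_run <- function(vertex_status, grid, edge_pos) {
  tab <- mc_tables()
  nv <- grid$nv; nc <- nv - 1L
  vs <- vertex_status
  s <- list()
  corner_bits <- mc_table_env$topo$corners
  case <- array(0L, nc)
  for (cidx in 0:7) {
    off <- corner_bits[cidx + 1L, ]
    blk <- vs[(1L + off[1L]):(nc[1L] + off[1L]),
              (1L + off[2L]):(nc[2L] + off[2L]),
              (1L + off[3L]):(nc[3L] + off[3L]), drop = FALSE]
    case <- case + as.integer(blk) * 2L^cidx
  }
  active <- which(case != 0L & case != 255L)
  tri_keys <- list(); tri_cube <- list()
  fallbacks <- 0L
  if (length(active)) {
    ai <- arrayInd(active, nc)
    for (q in seq_along(active)) {
      i <- ai[q, 1L]; j <- ai[q, 2L]; k <- ai[q, 3L]
      loops <- tab[[case[active[q]] + 1L]]
      for (loop in loops) {
        keys <- vapply(loop, mc_edge_key, numeric(1L), i = i, j = j, k = k,
                       nv = nv)
        nl <- length(keys)
        if (nl < 3L) next
        for (w in 2:(nl - 1L)) {
          tri_keys[[length(tri_keys) + 1L]] <-
            c(keys[1L], keys[w], keys[w + 1L])
          tri_cube[[length(tri_cube) + 1L]] <- c(i, j, k)
        }
      }
    }
  }
  if (!length(tri_keys)) {
    return(structure(list(vertices = matrix(0, 0L, 3L),
                          triangles = matrix(0L, 0L, 3L),
                          cube = matrix(0L, 0L, 3L), grid = grid,
                          provenance = integer(0), fallbacks = 0L),
                     class = "tri_mesh"))
  }
  km <- do.call(rbind, tri_keys)
  cubes <- do.call(rbind, tri_cube)
  ukeys <- sort(unique(as.numeric(km)))
  pos <- edge_pos(ukeys)
  fallbacks <- attr(pos, "fallbacks") %||% 0L
  fallback_idx <- attr(pos, "fallback_idx") %||% integer(0)
  tri <- matrix(match(as.numeric(km), ukeys), ncol = 3L)
  # drop degenerate triangles (duplicate vertices, e.g. collapsed hits)
  good <- tri[, 1L] != tri[, 2L] & tri[, 2L] != tri[, 3L] &
    tri[, 1L] != tri[, 3L]
  structure(list(vertices = pos, triangles = tri[good, , drop = FALSE],
                 cube = cubes[good, , drop = FALSE], grid = grid,
                 provenance = ukeys, fallbacks = fallbacks,
                 fallback_vertices = fallback_idx),
            class = "tri_mesh")
}

#' Analytic-vertex marching cubes
#'
#' Each cube's triangulation case comes from the eight vertex statuses of
#' the Edge-Ray cast; each triangle vertex is placed at the stored
#' analytic intersection on its grid edge (when an edge carries several
#' hits, the one nearest the outside endpoint).  Vertices therefore lie on
#' the surface up to root-refinement accuracy.  A mixed edge left without
#' a hit (e.g. residue of cavity filling) falls back to the edge midpoint
#' and is counted in `$fallbacks`.
#'
#' @param status A `status_grid` from [cast_surface()] (with Edge Rays).
#' @return A `tri_mesh`: vertices, triangles, per-triangle owning cube.
#' @export
mc_analytic <- function(status) {
  stopifnot(inherits(status, "status_grid"), !is.null(status$edges))
  grid <- status$grid
  vt <- status$edges$vertex
  edge <- status$edges$edge
  nv <- grid$nv
  edge_pos <- function(keys) {
    info <- mc_edge_unkey(keys, nv)
    out <- matrix(0, length(keys), 3L)
    fb <- integer(0)
    for (r in seq_along(keys)) {
      ax <- info[r, 1L]; i <- info[r, 2L]; j <- info[r, 3L]; k <- info[r, 4L]
      d <- setdiff(1:3, ax)
      lowv <- c(i, j, k); hiv <- lowv; hiv[ax] <- hiv[ax] + 1L
      low_in <- vt[matrix(lowv, 1L)]
      ed <- edge[[ax]]
      im <- matrix(c(i, j, k), 1L)
      tv <- if (!is.na(ed$first_t[im])) {
        if (low_in) ed$last_t[im] else ed$first_t[im]
      } else {
        fb <- c(fb, r)
        grid$origin[ax] + (c(i, j, k)[ax] - 0.5) * grid$h
      }
      p <- numeric(3L)
      p[ax] <- tv
      p[d] <- grid$origin[d] + (c(i, j, k)[d] - 1L) * grid$h
      out[r, ] <- p
    }
    attr(out, "fallbacks") <- length(fb)
    attr(out, "fallback_idx") <- fb
    out
  }
  mc_run(vt, grid, edge_pos)
}

#' Bisecting marching cubes
#'
#' Runs from Grid Rays only: each cube-vertex status is the majority of
#' its up-to-eight surrounding cube-center statuses (ties toward outside),
#' and triangle vertices sit at mixed-edge midpoints.  Coarser than
#' [mc_analytic()] but needs one third of the casting work.
#'
#' @param status A `status_grid` (Edge Rays not required).
#' @return A `tri_mesh`.
#' @export
mc_bisecting <- function(status) {
  stopifnot(inherits(status, "status_grid"))
  grid <- status$grid
  nv <- grid$nv; nc <- nv - 1L
  cs <- status$center
  pad <- array(0L, nv + 1L)
  pad[2:(nc[1L] + 1L), 2:(nc[2L] + 1L), 2:(nc[3L] + 1L)] <- cs * 1L
  cnt <- array(0L, nv + 1L)
  cnt[2:(nc[1L] + 1L), 2:(nc[2L] + 1L), 2:(nc[3L] + 1L)] <- 1L
  votes <- array(0L, nv); total <- array(0L, nv)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    votes <- votes + pad[(1L + dx):(nv[1L] + dx),
                         (1L + dy):(nv[2L] + dy),
                         (1L + dz):(nv[3L] + dz)]
    total <- total + cnt[(1L + dx):(nv[1L] + dx),
                         (1L + dy):(nv[2L] + dy),
                         (1L + dz):(nv[3L] + dz)]
  }
  vs <- votes * 2L > total                # ties -> outside
  edge_pos <- function(keys) {
    info <- mc_edge_unkey(keys, nv)
    out <- matrix(0, length(keys), 3L)
    for (r in seq_along(keys)) {
      ax <- info[r, 1L]
      ijk <- info[r, 2:4]
      d <- setdiff(1:3, ax)
      p <- numeric(3L)
      p[ax] <- grid$origin[ax] + (ijk[ax] - 0.5) * grid$h
      p[d] <- grid$origin[d] + (ijk[d] - 1L) * grid$h
      out[r, ] <- p
    }
    out
  }
  mc_run(vs, grid, edge_pos)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (x$fallbacks) sprintf(", %d midpoint fallbacks",
                                       x$fallbacks) else ""))
  invisible(x)
}

#' Closedness, Euler characteristic and genus of a triangle mesh
#'
#' @param mesh A `tri_mesh` or `mesh_surface`.
#' @return List with `closed`, `V`, `E`, `F`, `euler`, and `genus`
#'   (`(2 - euler) / 2`, meaningful for connected closed meshes).
#' @export
mesh_topology <- function(mesh) {
  tri <- if (inherits(mesh, "mesh_surface")) mesh$triangles else
    mesh$triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3L, 1L)])
  und <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  key <- paste(und[, 1L], und[, 2L])
  cnt <- table(key)
  V <- length(unique(as.integer(tri)))
  E <- length(cnt)
  F <- nrow(tri)
  euler <- V - E + F
  list(closed = all(cnt == 2L), V = V, E = E, F = F, euler = euler,
       genus = as.integer(round((2 - euler) / 2)))
}

#' Laplacian mesh smoothing (low-pass filter)
#'
#' Each vertex moves toward the centroid of its 1-ring neighbours by
#' `lambda` per iteration; connectivity is untouched.
#'
#' @param mesh A `tri_mesh`.
#' @param iterations Number of passes (default 1).
#' @param lambda Step factor in (0, 1) (default 0.5).
#' @return The smoothed `tri_mesh`.
#' @export
laplacian_smooth <- function(mesh, iterations = 1L, lambda = 0.5) {
  stopifnot(lambda > 0, lambda < 1, iterations >= 0)
  if (iterations == 0L || !nrow(mesh$triangles)) return(mesh)
  V <- mesh$vertices; tri <- mesh$triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3L, 1L)])
  ed <- unique(rbind(ed, ed[, 2:1]))
  for (it in seq_len(iterations)) {
    sums <- rowsum(V[ed[, 2L], , drop = FALSE], ed[, 1L])
    cnts <- as.numeric(table(ed[, 1L]))
    cent <- sums / cnts
    idx <- as.integer(rownames(sums))
    V[idx, ] <- V[idx, ] + lambda * (cent - V[idx, ])
  }
  mesh$vertices <- V
  mesh$provenance <- rep(-1L, nrow(V))    # smoothed vertices
  mesh
}

#' Total and per-cube surface area of a grid-consistent mesh
#'
#' @param mesh A `tri_mesh` (per-cube map) or `mesh_surface` (total only).
#' @return List with `total` (Angstrom^2) and, for `tri_mesh`, `per_cube`
#'   (`data.frame(i, j, k, area)`).
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; tri <- mesh$triangles
  if (!nrow(tri)) return(list(total = 0, per_cube = NULL))
  e1 <- V[tri[, 2L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  e2 <- V[tri[, 3L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  a <- sqrt(rowSums(cr * cr)) / 2
  out <- list(total = sum(a))
  if (!is.null(mesh$cube) && nrow(mesh$cube) == nrow(tri)) {
    key <- paste(mesh$cube[, 1L], mesh$cube[, 2L], mesh$cube[, 3L])
    agg <- rowsum(a, key)
    ijk <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    out$per_cube <- data.frame(i = ijk[, 1L], j = ijk[, 2L],
                               k = ijk[, 3L], area = agg[, 1L])
  }
  out
}

#' Write the per-cube area map as TSV
#'
#' @param area Result of [mesh_area()] on a `tri_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_area_map <- function(area, path) {
  utils::write.table(area$per_cube, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Incident-ray surface area estimator
#'
#' Infers the area from the angle between each incident axis ray and the
#' surface normal at the hit:
#'
#'     A_hat = (A_plane / n_rays) * sum over hits of 1 / max(|cos theta|, clamp)
#'
#' with one ray per cube-center row, so `A_plane / n_rays = h^2`.  The
#' cosine clamp avoids division blow-up at grazing hits.  The averaged
#' variant is the mean over the three orthogonal casting axes.
#'
#' @param surface Surface model.
#' @param grid A [make_grid()] lattice.
#' @param axis Casting axis for the single-axis estimate.
#' @param clamp Lower bound on `|cos theta|` (default 0.1).
#' @param averaged Average over the three axes.
#' @param seed,retry Parity protocol settings.
#' @return Estimated area (Angstrom^2).
#' @export
incident_ray_area <- function(surface, grid, axis = 1L, clamp = 0.1,
                              averaged = FALSE, seed = 1L, retry = 5L) {
  axes <- if (averaged) 1:3 else axis
  est <- vapply(axes, function(ax) {
    accel <- build_accel(surface, grid, ax)
    cast <- cast_axis_lattice(surface, grid, ax, "center", accel,
                              retry, 0.01 * grid$h, seed)
    tot <- 0
    for (hc in cast$hits_c)
      if (length(hc)) tot <- tot + sum(1 / pmax(abs(hc), clamp))
    grid$h^2 * tot
  }, numeric(1L))
  mean(est)
}

#' Export a triangle mesh
#'
#' Formats: GeomView `off` (`OFF` header), ascii `ply`, or MSMS `msms`
#' (`.vert`/`.face` pair with 1-based indices).
#'
#' @param mesh A `tri_mesh` or `mesh_surface`.
#' @param path Output path (for `msms`, the common stem).
#' @param format `"off"`, `"ply"` or `"msms"`.
#' @return The path(s) written, invisibly.
#' @export
export_mesh <- function(mesh, path, format = c("off", "ply", "msms")) {
  format <- match.arg(format)
  V <- mesh$vertices; tri <- mesh$triangles
  out <- switch(format,
                off = { write_off_file(V, tri, path); path },
                ply = { write_ply_file(V, tri, path); path },
                msms = write_msms_files(V, tri, path))
  invisible(out)
}
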