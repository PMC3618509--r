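# Imported triangle-mesh surfaces: GeomView OFF, ascii PLY and MSMS
# .vert/.face readers, closedness (manifold) checking, and the mesh
# ray-hit contract with half-open shared-edge ownership.

#' Load a closed triangle mesh as a surface model
#'
#' Supported formats: GeomView `off`, ascii `ply`, and MSMS `msms` (a
#' matching `.vert`/`.face` pair; pass the path without extension or the
#' `.vert` file).  The mesh must be closed: every edge shared by exactly
#' two triangles.  Non-manifold input is rejected with a message listing
#' offending edges.  Orientation is made consistently outward (positive
#' enclosed volume).
#'
#' @param path Input file.
#' @param format `"off"`, `"ply"` or `"msms"`; guessed from the extension
#'   by default.
#' @return A `mesh_surface` with fields `vertices` (V x 3) and
#'   `triangles` (F x 3, 1-based).
#' @export
load_mesh_surface <- function(path, format = c("auto", "off", "ply", "msms")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", vert = "msms",
                     face = "msms", "msms")
  }
  m <- switch(format,
              off = read_off(path),
              ply = read_ply(path),
              msms = read_msms(path))
  mesh_surface(m$vertices, m$triangles)
}

#' Construct a mesh surface from arrays
#'
#' @param vertices V x 3 numeric matrix (Angstrom).
#' @param triangles F x 3 integer matrix of 1-based vertex indices.
#' @return A `mesh_surface`; closedness and orientation are checked.
#' @export
mesh_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  check_closed(triangles)
  s <- structure(list(vertices = vertices, triangles = triangles,
                      definition = "mesh"),
                 class = c("mesh_surface", "surface_model"))
  if (mesh_signed_volume(vertices, triangles) < 0)
    s$triangles <- triangles[, c(1L, 3L, 2L)]
  s
}

check_closed <- function(tri) {
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3L, 1L)])
  und <- t(apply(ed, 1L, sort))
  key <- paste(und[, 1L], und[, 2L])
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad))
    stop("mesh is not closed: ", length(bad),
         " boundary/non-manifold edge(s), e.g. ",
         paste(utils::head(bad, 5L), collapse = "; "))
  # consistent orientation: each directed edge must appear exactly once
  dkey <- paste(ed[, 1L], ed[, 2L])
  if (anyDuplicated(dkey))
    stop("mesh is not consistently oriented")
  invisible(TRUE)
}

mesh_signed_volume <- function(V, tri) {
  v1 <- V[tri[, 1L], , drop = FALSE]
  v2 <- V[tri[, 2L], , drop = FALSE]
  v3 <- V[tri[, 3L], , drop = FALSE]
  sum(v1[, 1L] * (v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L]) -
        v1[, 2L] * (v2[, 1L] * v3[, 3L] - v2[, 3L] * v3[, 1L]) +
        v1[, 3L] * (v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])) / 6
}

#' @export
print.mesh_surface <- function(x, ...) {
  cat(sprintf("<mesh surface: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' @export
surface_bboxes.mesh_surface <- function(surface) {
  V <- surface$vertices; tri <- surface$triangles
  t(vapply(seq_len(nrow(tri)), function(i) {
    P <- V[tri[i, ], , drop = FALSE]
    c(apply(P, 2L, min), apply(P, 2L, max))
  }, numeric(6L)))
}

#' @export
surface_ray_hits.mesh_surface <- function(surface, origin, dir, t_max,
                                          candidates = NULL) {
  tri <- surface$triangles
  if (is.null(candidates)) candidates <- seq_len(nrow(tri))
  if (!length(candidates))
    return(finalize_hits(numeric(0), matrix(0, 0, 3), integer(0)))
  tt <- tri[candidates, , drop = FALSE]
  V <- surface$vertices
  h <- ray_triangles_batch(origin, dir,
                           V[tt[, 1L], , drop = FALSE],
                           V[tt[, 2L], , drop = FALSE],
                           V[tt[, 3L], , drop = FALSE], t_max)
  if (!nrow(h))
    return(finalize_hits(numeric(0), matrix(0, 0, 3), integer(0)))
  # half-open ownership of shared edges: a hit lying on an edge is kept
  # only by the triangle that traverses that edge from the smaller to the
  # larger vertex index; hits on vertices are deduplicated by position.
  bt <- 1e-10
  w <- 1 - h$u - h$v
  keep <- rep(TRUE, nrow(h))
  for (r in seq_len(nrow(h))) {
    bc <- c(w[r], h$u[r], h$v[r])
    onedge <- which(bc < bt)
    if (length(onedge) == 1L) {
      tv <- tt[h$idx[r], ]
      e <- switch(onedge, tv[c(2L, 3L)], tv[c(3L, 1L)], tv[c(1L, 2L)])
      if (e[1L] > e[2L]) keep[r] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  if (!nrow(h))
    return(finalize_hits(numeric(0), matrix(0, 0, 3), integer(0)))
  pid <- candidates[h$idx]
  v1 <- V[tri[pid, 1L], , drop = FALSE]
  e1 <- V[tri[pid, 2L], , drop = FALSE] - v1
  e2 <- V[tri[pid, 3L], , drop = FALSE] - v1
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n <- n / pmax(sqrt(rowSums(n * n)), 1e-300)
  out <- finalize_hits(h$t, n, pid, dedup_tol = 1e-9)
  out
}

#' @export
surface_residual.mesh_surface <- function(surface, points, patch = NULL) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  V <- surface$vertices; tri <- surface$triangles
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(tri))) {
    d <- point_triangle_dist(pts, V[tri[i, 1L], ], V[tri[i, 2L], ],
                             V[tri[i, 3L], ])
    best <- pmin(best, d)
  }
  best
}

# distance from points to one triangle (barycentric clamp)
point_triangle_dist <- function(pts, a, b, c) {
  foot <- point_triangle_foot(pts, a, b, c)
  sqrt(rowSums((pts - foot)^2))
}

point_triangle_foot <- function(pts, a, b, c) {
  ab <- b - a; ac <- c - a
  g11 <- sum(ab * ab); g12 <- sum(ab * ac); g22 <- sum(ac * ac)
  ap <- sweep(pts, 2L, a)
  w1 <- as.numeric(ap %*% ab); w2 <- as.numeric(ap %*% ac)
  det <- g11 * g22 - g12 * g12
  u <- (w1 * g22 - w2 * g12) / det
  v <- (w2 * g11 - w1 * g12) / det
  # clamp into the triangle
  u <- pmax(0, u); v <- pmax(0, v)
  s <- u + v
  over <- s > 1
  u[over] <- u[over] / s[over]; v[over] <- v[over] / s[over]
  # refine clamped points onto edges
  foot <- rep(a, each = nrow(pts)) + outer(u, ab) + outer(v, ac)
  for (edge in list(list(a, b), list(a, c), list(b, c))) {
    p0 <- edge[[1L]]; p1 <- edge[[2L]]
    d <- p1 - p0; L2 <- sum(d * d)
    t <- pmin(1, pmax(0, as.numeric(sweep(pts, 2L, p0) %*% d) / L2))
    cand <- rep(p0, each = nrow(pts)) + outer(t, d)
    better <- rowSums((pts - cand)^2) < rowSums((pts - foot)^2)
    foot[better, ] <- cand[better, , drop = FALSE]
  }
  foot
}

## ---- format readers/writers ----

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(toupper(lines[1L]), "OFF"))
    stop("not an OFF file (missing OFF header): ", path)
  counts <- as.integer(strsplit(lines[2L], "[[:space:]]+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  vtx <- do.call(rbind, lapply(lines[3:(2L + nv)], function(l)
    as.numeric(strsplit(l, "[[:space:]]+")[[1L]][1:3])))
  fl <- lines[(3L + nv):(2L + nv + nf)]
  tri <- do.call(rbind, lapply(fl, function(l) {
    f <- as.integer(strsplit(l, "[[:space:]]+")[[1L]])
    if (f[1L] != 3L) stop("only triangle faces supported in OFF input")
    f[2:4] + 1L
  }))
  list(vertices = vtx, triangles = tri)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1L]), "ply")) stop("not a PLY file: ", path)
  hend <- which(trimws(lines) == "end_header")[1L]
  header <- lines[1:hend]
  if (!any(grepl("format ascii", header)))
    stop("only ascii PLY supported")
  nv <- as.integer(sub(".*element vertex ", "",
                       grep("element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face ", "",
                       grep("element face", header, value = TRUE)[1L]))
  body <- lines[(hend + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- do.call(rbind, lapply(body[1:nv], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])))
  tri <- do.call(rbind, lapply(body[(nv + 1L):(nv + nf)], function(l) {
    f <- as.integer(strsplit(trimws(l), "[[:space:]]+")[[1L]])
    if (f[1L] != 3L) stop("only triangle faces supported in PLY input")
    f[2:4] + 1L
  }))
  list(vertices = vtx, triangles = tri)
}

msms_paths <- function(path) {
  if (grepl("\\.vert$", path)) {
    c(path, sub("\\.vert$", ".face", path))
  } else if (grepl("\\.face$", path)) {
    c(sub("\\.face$", ".vert", path), path)
  } else {
    c(paste0(path, ".vert"), paste0(path, ".face"))
  }
}

read_msms <- function(path) {
  pp <- msms_paths(path)
  if (!file.exists(pp[1L]) || !file.exists(pp[2L]))
    stop("MSMS input needs a matching .vert/.face pair: ", path)
  vl <- readLines(pp[1L], warn = FALSE)[-(1:3)]   # 3-line headers
  fl <- readLines(pp[2L], warn = FALSE)[-(1:3)]
  vl <- vl[nzchar(trimws(vl))]; fl <- fl[nzchar(trimws(fl))]
  vtx <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])))
  tri <- do.call(rbind, lapply(fl, function(l)
    as.integer(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])))
  list(vertices = vtx, triangles = tri)        # already 1-based
}

write_off_file <- function(V, tri, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(V), nrow(tri)), con)
  writeLines(sprintf("%.10g %.10g %.10g", V[, 1L], V[, 2L], V[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1L] - 1L, tri[, 2L] - 1L,
                     tri[, 3L] - 1L), con)
}

write_ply_file <- function(V, tri, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tri)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g", V[, 1L], V[, 2L], V[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1L] - 1L, tri[, 2L] - 1L,
                     tri[, 3L] - 1L), con)
}

write_msms_files <- function(V, tri, path) {
  pp <- msms_paths(path)
  conv <- file(pp[1L], "w")
  writeLines(c("# vertices", "#", sprintf("%8d", nrow(V))), conv)
  writeLines(sprintf("%12.6f %12.6f %12.6f", V[, 1L], V[, 2L], V[, 3L]),
             conv)
  close(conv)
  conf <- file(pp[2L], "w")
  writeLines(c("# faces", "#", sprintf("%8d", nrow(tri))), conf)
  writeLines(sprintf("%8d %8d %8d", tri[, 1L], tri[, 2L], tri[, 3L]), conf)
  close(conf)
  pp
}
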