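# Regular (weighted Delaunay) triangulation of weighted points, computed as
# the lower convex hull of the lift (x, |x|^2 - w) to the 4-D paraboloid.
# The 4-D hull itself is delegated to Qhull through the system `python` +
# scipy; atom sets with at most four points are handled combinatorially.

degenerate_error <- function(msg) {
  structure(class = c("surfray_degenerate", "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}

python_binary <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no `python` interpreter on PATH (needed for the Qhull 4-D hull)")
  p
}

qhull_lower_hull_4d <- function(pts4) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(pts4, fin, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- c(
    "import sys",
    "import numpy as np",
    "from scipy.spatial import ConvexHull",
    "pts = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "hull = ConvexHull(pts, qhull_options='Qt')",
    "eq = hull.equations",
    "low = eq[:, 3] < -1e-10",
    "simp = hull.simplices[low]",
    "np.savetxt(sys.argv[2], simp, fmt='%d', delimiter=',')")
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(sf), add = TRUE)
  writeLines(script, sf)
  err <- tempfile(); on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(
    system2(python_binary(), c(sf, fin, fout), stdout = FALSE, stderr = err))
  if (status != 0L)
    stop(degenerate_error(paste(
      "Qhull failed on the lifted point set:",
      paste(readLines(err, warn = FALSE), collapse = " "))))
  txt <- readLines(fout, warn = FALSE)
  txt <- txt[nzchar(txt)]
  if (!length(txt)) return(matrix(integer(0), 0L, 4L))
  m <- do.call(rbind, lapply(strsplit(txt, ","), as.integer)) + 1L
  m
}

canon_rows <- function(m) t(apply(m, 1L, sort))

dedup_rows <- function(m) {
  if (!nrow(m)) return(m)
  m <- canon_rows(m)
  m[!duplicated(apply(m, 1L, paste, collapse = "_")), , drop = FALSE]
}

tet_volume6 <- function(C) {
  det(rbind(C[2L, ] - C[1L, ], C[3L, ] - C[1L, ], C[4L, ] - C[1L, ]))
}

# Regular triangulation. centers: n x 3; weights: length n (usually r^2).
# Returns list(tets, tris, edges, verts) with 1-based point indices, plus
# coface maps tri2tet (rows aligned with tris) and edge ids per tri.
regular_triangulation <- function(centers, weights) {
  n <- nrow(centers)
  tets <- if (n >= 5L) {
    lifted <- cbind(centers, rowSums(centers^2) - weights)
    tt <- qhull_lower_hull_4d(lifted)
    if (!nrow(tt))
      stop(degenerate_error("empty lower hull (degenerate lifted points)"))
    tt
  } else if (n == 4L) {
    v6 <- tet_volume6(centers)
    if (abs(v6) < 1e-10)
      stop(degenerate_error("four coplanar points"))
    matrix(1:4, 1L)
  } else {
    matrix(integer(0), 0L, 4L)
  }
  tets <- dedup_rows(tets)
  tris <- if (nrow(tets)) {
    dedup_rows(rbind(tets[, c(1L, 2L, 3L)], tets[, c(1L, 2L, 4L)],
                     tets[, c(1L, 3L, 4L)], tets[, c(2L, 3L, 4L)]))
  } else if (n == 3L) {
    a <- centers[2L, ] - centers[1L, ]; b <- centers[3L, ] - centers[1L, ]
    cr <- c(a[2L] * b[3L] - a[3L] * b[2L], a[3L] * b[1L] - a[1L] * b[3L],
            a[1L] * b[2L] - a[2L] * b[1L])
    if (vnorm(cr) < 1e-10) stop(degenerate_error("three collinear points"))
    matrix(1:3, 1L)
  } else matrix(integer(0), 0L, 3L)
  edges <- if (nrow(tris)) {
    dedup_rows(rbind(tris[, c(1L, 2L)], tris[, c(1L, 3L)],
                     tris[, c(2L, 3L)]))
  } else if (n == 2L) {
    if (vnorm(centers[2L, ] - centers[1L, ]) < 1e-12)
      stop(degenerate_error("coincident centers"))
    matrix(1:2, 1L)
  } else matrix(integer(0), 0L, 2L)
  verts <- if (nrow(edges)) sort(unique(as.integer(edges))) else 1L
  list(tets = tets, tris = tris, edges = edges, verts = verts,
       centers = centers, weights = weights)
}

simplex_key <- function(m) apply(m, 1L, paste, collapse = "_")

# incidence of the triangulation: for every simplex its cofaces (one
# dimension up) and faces (one dimension down), as index lists.
rt_incidence <- function(rt) {
  tk <- simplex_key(rt$tets)
  rk <- simplex_key(rt$tris)
  ek <- simplex_key(rt$edges)
  tri_id <- function(m) match(simplex_key(canon_rows(m)), rk)
  edge_id <- function(m) match(simplex_key(canon_rows(m)), ek)

  tri_faces_of_tet <- function(tet)
    rbind(tet[c(1L, 2L, 3L)], tet[c(1L, 2L, 4L)], tet[c(1L, 3L, 4L)],
          tet[c(2L, 3L, 4L)])
  tri2tet <- vector("list", nrow(rt$tris))
  if (nrow(rt$tets))
    for (i in seq_len(nrow(rt$tets))) {
      ids <- tri_id(tri_faces_of_tet(rt$tets[i, ]))
      for (j in ids) tri2tet[[j]] <- c(tri2tet[[j]], i)
    }
  edge2tri <- vector("list", nrow(rt$edges))
  if (nrow(rt$tris))
    for (i in seq_len(nrow(rt$tris))) {
      tr <- rt$tris[i, ]
      ids <- edge_id(rbind(tr[c(1L, 2L)], tr[c(1L, 3L)], tr[c(2L, 3L)]))
      for (j in ids) edge2tri[[j]] <- c(edge2tri[[j]], i)
    }
  vert2edge <- vector("list", max(rt$verts))
  if (nrow(rt$edges))
    for (i in seq_len(nrow(rt$edges))) {
      e <- rt$edges[i, ]
      vert2edge[[e[1L]]] <- c(vert2edge[[e[1L]]], i)
      vert2edge[[e[2L]]] <- c(vert2edge[[e[2L]]], i)
    }
  edge2tet <- lapply(edge2tri, function(tris)
    sort(unique(unlist(tri2tet[tris]))))
  list(tri2tet = tri2tet, edge2tri = edge2tri, edge2tet = edge2tet,
       vert2edge = vert2edge)
}

# orthocenter of a weighted simplex: the point of the affine hull with equal
# power distance to every vertex, plus the squared orthoradius R2.
orthocenter <- function(C, w) {
  k <- nrow(C) - 1L
  if (k == 0L) return(list(z = C[1L, ], R2 = w[1L]))
  U <- t(C[-1L, , drop = FALSE]) - C[1L, ]     # 3 x k
  beta <- vapply(seq_len(k), function(j)
    sum(C[j + 1L, ]^2) - w[j + 1L] - sum(C[1L, ]^2) + w[1L], numeric(1L))
  A <- 2 * crossprod(U)                        # k x k
  rhs <- beta - 2 * as.numeric(C[1L, ] %*% U)
  alpha <- solve(A, rhs)
  z <- C[1L, ] + as.numeric(U %*% alpha)
  list(z = z, R2 = w[1L] - sum((z - C[1L, ])^2))
}
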