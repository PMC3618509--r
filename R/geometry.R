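# Exact-as-practical geometric primitives: real-root isolation by Sturm
# sequences and ray intersection with spheres, tori, quadrics and triangles.
# All lengths are in Angstrom; rays carry a unit direction and a finite t_max.

#' Create a ray
#'
#' A ray is a half-open segment `origin + t * dir`, `0 <= t <= t_max`.
#' Grid rays used by the caster are axis-aligned, but any unit direction is
#' accepted.
#'
#' @param origin Numeric length-3 start point (Angstrom).
#' @param dir Numeric length-3 direction; normalised internally.
#' @param t_max Positive ray length (Angstrom).
#' @return An object of class `surf_ray`.
#' @examples
#' r <- new_ray(c(-2, 0, 0), c(1, 0, 0), 10)
#' ray_sphere(r, c(0, 0, 0), 1)
#' @export
new_ray <- function(origin, dir, t_max) {
  stopifnot(length(origin) == 3L, length(dir) == 3L, is.finite(t_max), t_max > 0)
  n <- sqrt(sum(dir^2))
  if (!is.finite(n) || n == 0) stop("ray direction must be a nonzero vector")
  structure(list(origin = as.numeric(origin), dir = as.numeric(dir) / n,
                 t_max = as.numeric(t_max)),
            class = "surf_ray")
}

## ---- polynomial helpers (ascending coefficients: p[1] + p[2] x + ...) ----

poly_trim <- function(p, tol = 0) {
  n <- length(p)
  while (n > 1L && abs(p[n]) <= tol) n <- n - 1L
  p[seq_len(n)]
}

poly_eval <- function(p, x) {
  r <- rep(p[length(p)], length(x))
  if (length(p) > 1L)
    for (k in rev(seq_len(length(p) - 1L))) r <- r * x + p[k]
  r
}

poly_deriv <- function(p) {
  if (length(p) <= 1L) return(0)
  p[-1L] * seq_len(length(p) - 1L)
}

# quotient/remainder of a by b (both ascending, b trimmed)
poly_divrem <- function(a, b) {
  db <- length(b) - 1L
  r <- a
  q <- numeric(max(1L, length(a) - db))
  while (length(poly_trim(r)) - 1L >= db && any(r != 0)) {
    r <- poly_trim(r)
    dr <- length(r) - 1L
    if (dr < db) break
    f <- r[length(r)] / b[length(b)]
    q[dr - db + 1L] <- f
    sub <- c(numeric(dr - db), b * f)
    r <- r - sub[seq_along(r)]
    r[length(r)] <- 0
  }
  list(q = q, r = poly_trim(r))
}

sturm_chain <- function(p) {
  scale <- max(abs(p))
  p <- p / scale
  chain <- list(poly_trim(p), poly_trim(poly_deriv(p)))
  tol <- 1e-13
  while (length(chain[[length(chain)]]) > 1L) {
    r <- poly_divrem(chain[[length(chain) - 1L]], chain[[length(chain)]])$r
    r <- poly_trim(r, tol * max(1, max(abs(r))))
    if (all(abs(r) <= tol)) break
    chain[[length(chain) + 1L]] <- -r
  }
  chain
}

# number of sign changes of the chain at each x (vectorised over x)
sturm_changes <- function(chain, x) {
  vals <- vapply(chain, poly_eval, numeric(length(x)), x = x)
  if (length(x) == 1L) vals <- matrix(vals, nrow = 1L)
  apply(vals, 1L, function(v) {
    v <- v[abs(v) > 1e-300]
    if (length(v) <= 1L) return(0L)
    sum(diff(sign(v)) != 0)
  })
}

#' Isolate the real roots of a low-degree polynomial by Sturm sequences
#'
#' Roots inside `interval` are isolated with the Sturm sequence of `p`, then
#' refined by bisection to `tol` (absolute) and polished with a few guarded
#' Newton steps.  Multiple roots are collapsed to a single entry, as the
#' Sturm count is over distinct roots.
#'
#' @param p Numeric coefficient vector in ascending order
#'   (`p[1] + p[2] x + ...`), degree >= 1 after trimming.
#' @param interval Numeric length-2 search interval `c(a, b)`, `a < b`.
#' @param tol Absolute refinement tolerance on the root location.
#' @return Sorted numeric vector of distinct real roots in the interval.
#' @examples
#' sturm_roots(c(-1, 0, 1), c(-2, 2))        # x^2 - 1  -> -1, 1
#' sturm_roots(c(0.25, -1, 1), c(0, 1))      # (x - 0.5)^2 -> 0.5
#' @export
sturm_roots <- function(p, interval, tol = 1e-10) {
  if (any(!is.finite(p))) stop("non-finite polynomial coefficients")
  p <- poly_trim(as.numeric(p))
  if (length(p) < 2L) stop("polynomial degree must be >= 1")
  a <- interval[1L]; b <- interval[2L]
  stopifnot(is.finite(a), is.finite(b), a < b)
  p <- p / p[length(p)]            # normalise by the leading coefficient
  chain <- sturm_chain(p)
  # expand ends slightly so roots at the endpoints are counted
  eps <- max(tol, 1e-12 * max(1, abs(a), abs(b)))
  a0 <- a - eps; b0 <- b + eps
  nroots <- function(lo, hi) {
    ch <- sturm_changes(chain, c(lo, hi))
    max(0L, ch[1L] - ch[2L])
  }
  total <- nroots(a0, b0)
  if (total == 0L) return(numeric(0))
  roots <- numeric(0)
  stack <- list(c(a0, b0, total))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]; n <- seg[3L]
    if (n == 0L) next
    if (hi - lo < tol) {               # cluster below tolerance: one root
      roots <- c(roots, (lo + hi) / 2)
      next
    }
    if (n == 1L) {
      roots <- c(roots, sturm_refine(p, chain, lo, hi, tol))
      next
    }
    mid <- (lo + hi) / 2
    nl <- nroots(lo, mid)
    stack[[length(stack) + 1L]] <- c(lo, mid, nl)
    stack[[length(stack) + 1L]] <- c(mid, hi, n - nl)
  }
  roots <- sort(roots)
  pmin(pmax(roots, a), b)
}

# refine a single root inside (lo, hi): plain bisection when the sign
# changes, Sturm-count bisection otherwise (even multiplicity), then a few
# guarded Newton steps.
sturm_refine <- function(p, chain, lo, hi, tol) {
  flo <- poly_eval(p, lo); fhi <- poly_eval(p, hi)
  if (sign(flo) != sign(fhi) && flo != 0 && fhi != 0) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- poly_eval(p, mid)
      if (fm == 0) { lo <- hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      ch <- sturm_changes(chain, c(lo, mid))
      if (ch[1L] - ch[2L] >= 1L) hi <- mid else lo <- mid
    }
  }
  x <- (lo + hi) / 2
  dp <- poly_deriv(p)
  for (i in 1:3) {
    d <- poly_eval(dp, x)
    if (abs(d) < 1e-300) break
    step <- poly_eval(p, x) / d
    xn <- x - step
    if (!is.finite(xn) || xn < lo - tol || xn > hi + tol) break
    x <- xn
  }
  x
}

## ---- crossing filter: drop even-multiplicity (grazing) roots ----

# keep only roots where the polynomial changes sign; tangential contact does
# not flip the in/out parity and is discarded by convention.
crossing_roots <- function(p, roots, span) {
  if (!length(roots)) return(roots)
  delta <- max(1e-8 * max(1, span), 1e-9)
  keep <- vapply(roots, function(r) {
    s1 <- poly_eval(p, r - delta); s2 <- poly_eval(p, r + delta)
    is.finite(s1) && is.finite(s2) && sign(s1) != sign(s2) && s1 != 0
  }, logical(1L))
  roots[keep]
}

## ---- ray / sphere ----

# vectorised core: one ray against many spheres. Returns data.frame(t, idx).
ray_spheres_batch <- function(origin, dir, centers, radii, t_max,
                              tangent_tol = 1e-12) {
  if (!nrow(centers)) return(data.frame(t = numeric(0), idx = integer(0)))
  m <- sweep(centers, 2L, origin)            # c - o
  b <- as.numeric(m %*% dir)                 # projection of center on ray
  cc <- rowSums(m * m) - radii^2
  disc <- b * b - cc
  hit <- which(disc > tangent_tol)
  if (!length(hit)) return(data.frame(t = numeric(0), idx = integer(0)))
  sq <- sqrt(disc[hit])
  t1 <- b[hit] - sq; t2 <- b[hit] + sq
  tt <- c(t1, t2); idx <- c(hit, hit)
  keep <- tt >= 0 & tt <= t_max
  data.frame(t = tt[keep], idx = idx[keep])
}

#' Intersect a ray with a sphere
#'
#' Returns 0 or 2 parameter values: grazing contact (discriminant within
#' `1e-12` of zero) is reported as no intersection so that in/out parity is
#' preserved.  Normals point away from the center for `convex` patches and
#' toward it for `concave` (probe) patches, i.e. always out of the material
#' side.
#'
#' @param ray A [new_ray()] object.
#' @param center Sphere center (length 3).
#' @param radius Sphere radius (> 0).
#' @param orientation `"convex"` (atom) or `"concave"` (probe sphere).
#' @return `data.frame(t, nx, ny, nz)` sorted by `t` (possibly 0 rows).
#' @export
ray_sphere <- function(ray, center, radius, orientation = "convex") {
  stopifnot(inherits(ray, "surf_ray"), radius > 0)
  h <- ray_spheres_batch(ray$origin, ray$dir, matrix(center, 1L), radius,
                         ray$t_max)
  if (!nrow(h)) return(empty_hits())
  t <- sort(h$t)
  pts <- outer(t, ray$dir) + rep(ray$origin, each = length(t))
  n <- sweep(pts, 2L, center) / radius
  if (orientation == "concave") n <- -n
  data.frame(t = t, nx = n[, 1L], ny = n[, 2L], nz = n[, 3L])
}

empty_hits <- function() {
  data.frame(t = numeric(0), nx = numeric(0), ny = numeric(0), nz = numeric(0))
}

## ---- ray / torus ----

# quartic coefficients (ascending) of the torus implicit equation restricted
# to origin + t*dir.  Torus: center ct, unit axis a, major R, minor r.
torus_ray_poly <- function(origin, dir, ct, axis, R, r) {
  m <- origin - ct
  md <- sum(m * dir); mm <- sum(m * m)
  ma <- sum(m * axis); da <- sum(dir * axis)
  a1 <- 2 * md; a0 <- mm + R^2 - r^2
  b2 <- 1 - da^2; b1 <- 2 * (md - ma * da); b0 <- mm - ma^2
  c(a0^2 - 4 * R^2 * b0,
    2 * a1 * a0 - 4 * R^2 * b1,
    a1^2 + 2 * a0 - 4 * R^2 * b2,
    2 * a1,
    1)
}

torus_implicit <- function(pts, ct, axis, R, r) {
  v <- sweep(pts, 2L, ct)
  vv <- rowSums(v * v); va <- as.numeric(v %*% axis)
  (vv + R^2 - r^2)^2 - 4 * R^2 * (vv - va^2)
}

torus_gradient <- function(pts, ct, axis, R, r) {
  v <- sweep(pts, 2L, ct)
  vv <- rowSums(v * v); va <- as.numeric(v %*% axis)
  g <- 4 * v * (vv + R^2 - r^2) - 8 * R^2 * (v - outer(va, axis))
  g
}

#' Intersect a ray with a torus
#'
#' The ray is substituted into the degree-4 implicit form of the torus and
#' the real roots are isolated with [sturm_roots()]; grazing (even
#' multiplicity) roots are discarded.  Normals are the normalised implicit
#' gradient, pointing out of the solid tube.
#'
#' @inheritParams ray_sphere
#' @param axis Unit symmetry axis of the torus.
#' @param major_radius,minor_radius Torus radii `R > 0`, `r > 0`.
#' @return `data.frame(t, nx, ny, nz)` with 0 to 4 rows, ascending `t`.
#' @export
ray_torus <- function(ray, center, axis, major_radius, minor_radius) {
  stopifnot(inherits(ray, "surf_ray"), major_radius > 0, minor_radius > 0)
  axis <- axis / sqrt(sum(axis^2))
  p <- torus_ray_poly(ray$origin, ray$dir, center, axis,
                      major_radius, minor_radius)
  roots <- sturm_roots(p, c(0, ray$t_max))
  roots <- crossing_roots(p, roots, ray$t_max)
  if (!length(roots)) return(empty_hits())
  pts <- outer(roots, ray$dir) + rep(ray$origin, each = length(roots))
  g <- torus_gradient(pts, center, axis, major_radius, minor_radius)
  g <- g / pmax(sqrt(rowSums(g * g)), 1e-300)
  data.frame(t = roots, nx = g[, 1L], ny = g[, 2L], nz = g[, 3L])
}

## ---- ray / quadric ----

# internal quadrics are stored centered: f(x) = (x-z)' M (x-z) - k
quadric_ray_roots <- function(origin, dir, M, z, k, t_max,
                              tangent_tol = 1e-12) {
  m <- origin - z
  a <- as.numeric(dir %*% M %*% dir)
  b <- 2 * as.numeric(m %*% M %*% dir)
  cc <- as.numeric(m %*% M %*% m) - k
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) return(numeric(0))   # degenerate restriction
    t <- -cc / b
    return(t[t >= 0 & t <= t_max])
  }
  disc <- b * b - 4 * a * cc
  if (disc <= tangent_tol) return(numeric(0))
  sq <- sqrt(disc)
  t <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  t[t >= 0 & t <= t_max]
}

#' Intersect a ray with a quadric surface
#'
#' The quadric is given as a symmetric 4x4 matrix `Q` of the homogeneous
#' form `x' Q x = 0`.  The restriction to the ray is a quadratic whose real
#' roots are returned; a degenerate (identically zero) restriction yields no
#' hits.  Normals are the normalised gradient of the quadric form.
#'
#' @inheritParams ray_sphere
#' @param Q Symmetric 4x4 coefficient matrix.
#' @return `data.frame(t, nx, ny, nz)` with 0 to 2 rows.
#' @export
ray_quadric <- function(ray, Q) {
  stopifnot(inherits(ray, "surf_ray"), all(dim(Q) == c(4L, 4L)))
  if (max(abs(Q - t(Q))) > 1e-9 * max(1, max(abs(Q))))
    stop("Q must be symmetric")
  A <- Q[1:3, 1:3]; q3 <- Q[1:3, 4L]; c0 <- Q[4L, 4L]
  o <- ray$origin; d <- ray$dir
  a <- as.numeric(d %*% A %*% d)
  b <- 2 * as.numeric(o %*% A %*% d) + 2 * sum(q3 * d)
  cc <- as.numeric(o %*% A %*% o) + 2 * sum(q3 * o) + c0
  t <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else {
      tt <- -cc / b; tt[tt >= 0 & tt <= ray$t_max]
    }
  } else {
    disc <- b * b - 4 * a * cc
    if (disc <= 1e-12) numeric(0) else {
      sq <- sqrt(disc)
      tt <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
      tt[tt >= 0 & tt <= ray$t_max]
    }
  }
  if (!length(t)) return(empty_hits())
  pts <- outer(t, d) + rep(o, each = length(t))
  g <- 2 * (pts %*% A + rep(q3, each = length(t)))
  g <- g / pmax(sqrt(rowSums(g * g)), 1e-300)
  data.frame(t = t, nx = g[, 1L], ny = g[, 2L], nz = g[, 3L])
}

## ---- ray / triangle ----

#' Intersect a ray with a triangle
#'
#' Barycentric (Moeller-Trumbore style) test.  Hits on the closed triangle
#' (including edges and vertices) are reported; the mesh-level caster
#' applies half-open edge ownership so that a ray crossing a shared edge is
#' counted exactly once across the two incident triangles.  Zero-area
#' triangles are treated as misses.
#'
#' @inheritParams ray_sphere
#' @param v1,v2,v3 Triangle vertices (length-3 each).
#' @return Single-row `data.frame(t, u, v)` (barycentric weights of `v2`,
#'   `v3`) or a 0-row frame on a miss.
#' @export
ray_triangle <- function(ray, v1, v2, v3) {
  stopifnot(inherits(ray, "surf_ray"))
  h <- ray_triangles_batch(ray$origin, ray$dir,
                           matrix(v1, 1L), matrix(v2, 1L), matrix(v3, 1L),
                           ray$t_max)
  h[, c("t", "u", "v")]
}

# one ray against many triangles; returns t, idx and barycentrics
ray_triangles_batch <- function(origin, dir, V1, V2, V3, t_max,
                                eps = 1e-12) {
  if (!nrow(V1))
    return(data.frame(t = numeric(0), idx = integer(0),
                      u = numeric(0), v = numeric(0)))
  e1 <- V2 - V1; e2 <- V3 - V1
  # pvec = dir x e2
  px <- dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L]
  py <- dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L]
  pz <- dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L]
  det <- e1[, 1L] * px + e1[, 2L] * py + e1[, 3L] * pz
  ok <- abs(det) > eps                      # parallel or degenerate -> miss
  inv <- ifelse(ok, 1 / det, NA_real_)
  tx <- origin[1L] - V1[, 1L]; ty <- origin[2L] - V1[, 2L]
  tz <- origin[3L] - V1[, 3L]
  u <- (tx * px + ty * py + tz * pz) * inv
  # qvec = tvec x e1
  qx <- ty * e1[, 3L] - tz * e1[, 2L]
  qy <- tz * e1[, 1L] - tx * e1[, 3L]
  qz <- tx * e1[, 2L] - ty * e1[, 1L]
  v <- (dir[1L] * qx + dir[2L] * qy + dir[3L] * qz) * inv
  t <- (e2[, 1L] * qx + e2[, 2L] * qy + e2[, 3L] * qz) * inv
  bt <- 1e-12
  keep <- which(ok & u >= -bt & v >= -bt & (u + v) <= 1 + bt &
                  t >= 0 & t <= t_max)
  data.frame(t = t[keep], idx = keep, u = u[keep], v = v[keep])
}

## ---- trimming primitives ----

#' Trimming primitives
#'
#' A trim is a pure point predicate; a patch keeps a point only if *every*
#' trim in its list accepts it.  `trim_halfspace` keeps `n . x <= b`;
#' `trim_sphere` keeps the inside (`keep = "inside"`) or outside of a
#' sphere.  Patch builders add composite trims internally (e.g. the
#' solvent-excluded-surface torus arc); [point_in_trim()] evaluates them
#' all.
#'
#' @param normal,offset Half-space `normal . x <= offset`.
#' @param center,radius Trimming sphere.
#' @param keep `"inside"` or `"outside"` for the sphere trim.
#' @return A trim primitive (list with a `kind` field).
#' @export
trim_halfspace <- function(normal, offset) {
  n <- sqrt(sum(normal^2))
  list(kind = "halfspace", n = as.numeric(normal) / n,
       b = as.numeric(offset) / n)
}

#' @rdname trim_halfspace
#' @export
trim_sphere <- function(center, radius, keep = c("outside", "inside")) {
  keep <- match.arg(keep)
  list(kind = if (keep == "outside") "sphere_out" else "sphere_in",
       c = as.numeric(center), r = as.numeric(radius))
}

# batch sphere-outside trim: keep points outside ALL spheres in `mat`
# (columns cx, cy, cz, r); used for SAS-exposure and probe-probe clipping.
trim_spheres_out <- function(mat) {
  list(kind = "spheres_out", mat = mat)
}

# SES saddle-arc trim for a torus patch: a point q on the torus is kept iff
# (a) its foot probe center p = ct + rt * radial(q) is outside all neighbour
# SAS spheres (partial burial of the probe circle) and (b) q - p lies in the
# cone spanned by (ci - p) and (cj - p) (the rolling arc between the two
# contact points).
trim_torus_arc <- function(ct, axis, rt, ci, cj, neighbours) {
  list(kind = "torus_arc", ct = ct, axis = axis, rt = rt,
       ci = ci, cj = cj, nb = neighbours)
}

eval_trim <- function(trim, pts, tol = 1e-9) {
  switch(trim$kind,
    halfspace = as.numeric(pts %*% trim$n) <= trim$b + tol,
    sphere_out = rowSums(sweep(pts, 2L, trim$c)^2) >= (trim$r - tol)^2,
    sphere_in = rowSums(sweep(pts, 2L, trim$c)^2) <= (trim$r + tol)^2,
    spheres_out = {
      mat <- trim$mat
      d2 <- outer(rowSums(pts * pts), rowSums(mat[, 1:3, drop = FALSE]^2),
                  `+`) - 2 * tcrossprod(pts, mat[, 1:3, drop = FALSE])
      ok <- d2 >= rep((mat[, 4L] - tol)^2, each = nrow(pts))
      rowSums(ok) == nrow(mat)
    },
    torus_arc = {
      v1 <- pts[, 1L] - trim$ct[1L]; v2 <- pts[, 2L] - trim$ct[2L]
      v3 <- pts[, 3L] - trim$ct[3L]
      ax <- trim$axis
      va <- v1 * ax[1L] + v2 * ax[2L] + v3 * ax[3L]
      r1 <- v1 - va * ax[1L]; r2 <- v2 - va * ax[2L]; r3 <- v3 - va * ax[3L]
      rn <- sqrt(r1 * r1 + r2 * r2 + r3 * r3)
      ok <- rn > 1e-12
      f <- trim$rt / pmax(rn, 1e-300)
      foot <- cbind(trim$ct[1L] + f * r1, trim$ct[2L] + f * r2,
                    trim$ct[3L] + f * r3)
      keep <- ok
      nb <- trim$nb
      if (!is.null(nb) && nrow(nb)) {
        d2 <- outer(rowSums(foot * foot),
                    rowSums(nb[, 1:3, drop = FALSE]^2), `+`) -
          2 * tcrossprod(foot, nb[, 1:3, drop = FALSE])
        okn <- d2 >= rep((nb[, 4L] - tol)^2, each = nrow(foot))
        keep <- keep & rowSums(okn) == nrow(nb)
      }
      # cone test in the axial plane through the foot point
      a1 <- cbind(trim$ci[1L] - foot[, 1L], trim$ci[2L] - foot[, 2L],
                  trim$ci[3L] - foot[, 3L])
      a2 <- cbind(trim$cj[1L] - foot[, 1L], trim$cj[2L] - foot[, 2L],
                  trim$cj[3L] - foot[, 3L])
      w <- pts - foot
      g11 <- rowSums(a1 * a1); g12 <- rowSums(a1 * a2); g22 <- rowSums(a2 * a2)
      w1 <- rowSums(w * a1); w2 <- rowSums(w * a2)
      det <- g11 * g22 - g12 * g12
      alpha <- (w1 * g22 - w2 * g12) / det
      beta <- (w2 * g11 - w1 * g12) / det
      keep & is.finite(alpha) & is.finite(beta) &
        alpha >= -1e-9 & beta >= -1e-9
    },
    stop("unknown trim kind: ", trim$kind))
}

#' Test a point against a list of trims
#'
#' Conjunction of all trim predicates; an empty list accepts every point.
#'
#' @param point Numeric length-3 point, or an n x 3 matrix of points.
#' @param trims List of trim primitives (see [trim_halfspace()]).
#' @return Logical vector, one entry per point.
#' @export
point_in_trim <- function(point, trims) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  keep <- rep(TRUE, nrow(pts))
  for (tr in trims) keep <- keep & eval_trim(tr, pts)
  keep
}

## ---- misc small helpers shared across modules ----

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) v / vnorm(v)

# deterministic per-item seed derived from a user seed (kept below 2^31)
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647)
  for (i in ids) s <- (s * 48271 + as.double(i %% 2147483647)) %% 2147483647
  as.integer(s)
}

# evaluate fn with a temporary RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## ---- batched monic-quartic Sturm solver ----
#
# The ray/torus quartics produced by torus_ray_poly are monic, so the
# whole Sturm chain has closed-form coefficients and root isolation can
# be vectorised across many (ray, torus) pairs at once.  Rows whose chain
# degenerates (vanishing leading remainder coefficients: biquadratics,
# multiple roots) fall back to the generic scalar sturm_roots.

quartic_chain_batch <- function(a, b, c, d) {
  A2 <- 3 * a^2 / 16 - b / 2
  B2 <- a * b / 8 - 3 * c / 4
  C2 <- a * c / 16 - d
  q1 <- 4 / A2
  q0 <- (3 * a * A2 - 4 * B2) / A2^2
  A3 <- -(2 * b - q1 * C2 - q0 * B2)
  B3 <- -(c - q0 * C2)
  t <- -B3 / A3
  P4 <- -(A2 * t^2 + B2 * t + C2)
  # degeneracy relative to the cancelling terms of each leading coefficient
  tolA2 <- 1e-12 * (3 * a^2 / 16 + abs(b) / 2 + 1)
  tolA3 <- 1e-11 * (2 * abs(b) + abs(q1 * C2) + abs(q0 * B2) + 1)
  bad <- !is.finite(A2 + B2 + C2 + A3 + B3 + P4) |
    abs(A2) < tolA2 | abs(A3) < tolA3
  list(a = a, b = b, c = c, d = d, A2 = A2, B2 = B2, C2 = C2,
       A3 = A3, B3 = B3, P4 = P4, bad = bad)
}

# Sturm sign-change count of chain rows `idx` at points `x`
quartic_changes_batch <- function(ch, idx, x) {
  x2 <- x * x
  s0 <- sign(((x + ch$a[idx]) * x + ch$b[idx]) * x2 +
               ch$c[idx] * x + ch$d[idx])
  s1 <- sign((4 * x + 3 * ch$a[idx]) * x2 + 2 * ch$b[idx] * x + ch$c[idx])
  s2 <- sign((ch$A2[idx] * x + ch$B2[idx]) * x + ch$C2[idx])
  s3 <- sign(ch$A3[idx] * x + ch$B3[idx])
  s4 <- sign(ch$P4[idx])
  z <- s1 == 0; s1[z] <- s0[z]
  z <- s2 == 0; s2[z] <- s1[z]
  z <- s3 == 0; s3[z] <- s2[z]
  z <- s4 == 0; s4[z] <- s3[z]
  (s0 != s1 & s0 != 0) + (s1 != s2) + (s2 != s3) + (s3 != s4)
}

quartic_eval_batch <- function(ch, idx, x) {
  (((x + ch$a[idx]) * x + ch$b[idx]) * x + ch$c[idx]) * x + ch$d[idx]
}

# distinct real roots in [lo, hi] for each monic quartic row of `coef`
# (n x 5, ascending, leading coefficient 1).  Returns data.frame(row, t).
quartic_roots_batch <- function(coef, lo, hi, tol = 1e-10) {
  n <- nrow(coef)
  if (!n) return(data.frame(row = integer(0), t = numeric(0)))
  ch <- quartic_chain_batch(coef[, 4L], coef[, 3L], coef[, 2L], coef[, 1L])
  out_row <- integer(0); out_t <- numeric(0)
  # scalar fallback for degenerate chains
  for (r in which(ch$bad)) {
    rt <- sturm_roots(coef[r, ], c(lo, hi), tol)
    rt <- crossing_roots(coef[r, ], rt, hi - lo)
    out_row <- c(out_row, rep(r, length(rt))); out_t <- c(out_t, rt)
  }
  good <- which(!ch$bad)
  if (length(good)) {
    eps <- max(tol, 1e-12 * max(1, abs(lo), abs(hi)))
    vlo <- quartic_changes_batch(ch, good, rep(lo - eps, length(good)))
    vhi <- quartic_changes_batch(ch, good, rep(hi + eps, length(good)))
    cnt <- vlo - vhi
    act <- cnt > 0L
    iv_row <- good[act]; iv_lo <- rep(lo - eps, sum(act))
    iv_hi <- rep(hi + eps, sum(act))
    iv_nlo <- vlo[act]; iv_nhi <- vhi[act]
    root_row <- integer(0); root_lo <- numeric(0); root_hi <- numeric(0)
    while (length(iv_row)) {
      cnts <- iv_nlo - iv_nhi
      drop <- cnts <= 0L
      done <- !drop & (cnts == 1L | (iv_hi - iv_lo) < tol)
      if (any(done)) {
        root_row <- c(root_row, iv_row[done])
        root_lo <- c(root_lo, iv_lo[done])
        root_hi <- c(root_hi, iv_hi[done])
      }
      keep <- !(drop | done)
      if (!any(keep)) break
      iv_row <- iv_row[keep]; iv_lo <- iv_lo[keep]; iv_hi <- iv_hi[keep]
      iv_nlo <- iv_nlo[keep]; iv_nhi <- iv_nhi[keep]
      mid <- (iv_lo + iv_hi) / 2
      vmid <- quartic_changes_batch(ch, iv_row, mid)
      iv_row <- c(iv_row, iv_row)
      iv_lo <- c(iv_lo, mid); iv_hi <- c(mid, iv_hi)
      iv_nlo <- c(iv_nlo, vmid); iv_nhi <- c(vmid, iv_nhi)
    }
    # refine isolated roots by Sturm-count bisection (handles even
    # multiplicity), vectorised across intervals
    if (length(root_row)) {
      nlo <- quartic_changes_batch(ch, root_row, root_lo)
      while (max(root_hi - root_lo) > tol) {
        mid <- (root_lo + root_hi) / 2
        vmid <- quartic_changes_batch(ch, root_row, mid)
        left <- (nlo - vmid) >= 1L
        root_hi[left] <- mid[left]
        root_lo[!left] <- mid[!left]
      }
      x <- (root_lo + root_hi) / 2
      # guarded Newton polish
      for (it in 1:3) {
        dp <- ((4 * x + 3 * ch$a[root_row]) * x +
                 2 * ch$b[root_row]) * x + ch$c[root_row]
        step <- quartic_eval_batch(ch, root_row, x) / dp
        step[!is.finite(step)] <- 0
        xn <- x - step
        ok <- xn >= root_lo - tol & xn <= root_hi + tol
        x[ok] <- xn[ok]
      }
      # keep only sign-changing (odd multiplicity) roots
      delta <- pmax(1e-8 * max(1, abs(hi - lo)), 10 * tol)
      sL <- sign(quartic_eval_batch(ch, root_row, x - delta))
      sR <- sign(quartic_eval_batch(ch, root_row, x + delta))
      keep <- sL != sR & sL != 0
      out_row <- c(out_row, root_row[keep])
      out_t <- c(out_t, pmin(pmax(x[keep], lo), hi))
    }
  }
  data.frame(row = out_row, t = out_t)
}
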