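# Independent oracles used across the suite.  These deliberately avoid the
# package's patch/trim machinery: membership tests are direct geometric
# predicates, and ray-crossing references come from dense sign scans of
# the implicit surface functions.

# union-of-balls membership
oracle_union_inside <- function(centers, radii, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
      (pts[, 3] - centers[i, 3])^2
    inside <- inside | d2 < radii[i]^2
  }
  inside
}

# signed distance to the union-of-balls boundary (negative inside)
oracle_union_signed_dist <- function(centers, radii, pts) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(centers))) {
    di <- sqrt((pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
                 (pts[, 3] - centers[i, 3])^2) - radii[i]
    d <- pmin(d, di)
  }
  d
}

# skin-body membership by minimising the shrunken-ball envelope over every
# simplex of the weighted point set (independent of mixed cells/trims)
oracle_skin_inside <- function(centers, weights, s, x) {
  h <- rowSums(centers^2) - weights
  M <- nrow(centers)
  phi_simplex <- function(idx) {
    k <- length(idx)
    Cs <- centers[idx, , drop = FALSE]
    A <- 2 * (1 - s) * Cs %*% t(Cs)
    KKT <- rbind(cbind(A, 1), c(rep(1, k), 0))
    rhs <- c(2 * as.numeric(Cs %*% x) - s * h[idx], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) return(Inf)
    lam <- sol[1:k]
    if (any(lam < -1e-12)) return(Inf)
    z <- as.numeric(t(Cs) %*% lam)
    sum((x - z)^2) - s * (sum(z^2) - sum(h[idx] * lam))
  }
  best <- Inf
  for (i in 1:M)
    best <- min(best, sum((x - centers[i, ])^2) - s * weights[i])
  if (M >= 2) {
    cmb <- utils::combn(M, 2)
    for (q in seq_len(ncol(cmb))) best <- min(best, phi_simplex(cmb[, q]))
  }
  if (M >= 3) {
    cmb <- utils::combn(M, 3)
    for (q in seq_len(ncol(cmb))) best <- min(best, phi_simplex(cmb[, q]))
  }
  if (M >= 4) {
    cmb <- utils::combn(M, 4)
    for (q in seq_len(ncol(cmb))) best <- min(best, phi_simplex(cmb[, q]))
  }
  best <= 0
}

# dense sign-change scan of an implicit function along a ray
oracle_ray_scan <- function(fimpl, origin, dir, t_max, step = 1e-4) {
  ts <- seq(0, t_max, by = step)
  pts <- outer(ts, dir) + rep(origin, each = length(ts))
  v <- fimpl(pts)
  sw <- which(v[-1] * v[-length(v)] < 0)
  vapply(sw, function(i) {
    lo <- ts[i]; hi <- ts[i + 1]
    flo <- v[i]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      fm <- fimpl(matrix(origin + mid * dir, 1))
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# classify points by parity of +z ray crossings
classify_by_parity <- function(surface, pts, reach = 50) {
  vapply(seq_len(nrow(pts)), function(i) {
    h <- surface_ray_hits(surface, pts[i, ], c(0, 0, 1), reach)
    nrow(h) %% 2 == 1
  }, logical(1))
}

# uniformly random rotation matrix (deterministic under the session seed)
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_atoms <- function(atoms, Rm) {
  C <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rm)
  atom_set(C[, 1], C[, 2], C[, 3], atoms$radius)
}

# relative spread of a sample (range over mean)
rel_spread <- function(x) (max(x) - min(x)) / mean(x)
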