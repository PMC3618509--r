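# Skin surface via the mixed complex.

test_that("an isolated atom's skin is the sqrt(s)-shrunken sphere", {
  at <- atom_set(0.3, -0.2, 0.1, 1.5)
  sk <- build_skin(at, shrink = 0.45)
  h <- surface_ray_hits(sk, c(-5, -0.2, 0.1), c(1, 0, 0), 10)
  expect_equal(diff(h$t) / 2, sqrt(0.45) * 1.5, tolerance = 2e-4)
})

test_that("skin membership matches the shrunken-ball envelope oracle", {
  at <- atom_set(c(0, 1.6), c(0, 0), c(0, 0), c(1.2, 1.0))
  sk <- build_skin(at, shrink = 0.45, perturb_magnitude = 0)
  C <- as.matrix(at[, c("x", "y", "z")]); w <- at$radius^2
  set.seed(31)
  pts <- matrix(c(runif(500, -2, 3.6), runif(1000, -2, 2)), ncol = 3)
  got <- classify_by_parity(sk, pts)
  ref <- vapply(seq_len(nrow(pts)), function(i)
    oracle_skin_inside(C, w, 0.45, pts[i, ]), logical(1))
  expect_equal(got, ref)
})

test_that("four-atom skin (with tetrahedron cells) matches the oracle", {
  at <- atom_set(c(0, 2, 1, 1), c(0, 0, 1.8, 0.6), c(0, 0, 0, 1.7),
                 c(1.1, 1.0, 0.9, 1.0))
  sk <- build_skin(at, shrink = 0.45, perturb_magnitude = 0)
  C <- as.matrix(at[, c("x", "y", "z")]); w <- at$radius^2
  set.seed(32)
  pts <- matrix(c(runif(400, -1.5, 3.5), runif(400, -1.5, 3),
                  runif(400, -1.5, 3)), ncol = 3)
  got <- classify_by_parity(sk, pts)
  ref <- vapply(seq_len(nrow(pts)), function(i)
    oracle_skin_inside(C, w, 0.45, pts[i, ]), logical(1))
  # tolerate only points within float noise of the surface
  dis <- which(got != ref)
  expect_lt(length(dis), 3L)
})

test_that("shrink = 1 reproduces the union-of-balls boundary", {
  fx <- gen_random_cluster(n = 6, box = 2, r_range = c(0.8, 1.5), seed = 4)
  sk <- build_skin(fx$atoms, shrink = 1)
  C <- as.matrix(fx$atoms[, c("x", "y", "z")])
  set.seed(33)
  pts <- matrix(runif(1200, -3.5, 3.5), ncol = 3)
  dist <- oracle_union_signed_dist(C, fx$atoms$radius, pts)
  pts <- pts[abs(dist) > 1e-3, , drop = FALSE]
  expect_equal(classify_by_parity(sk, pts),
               oracle_union_inside(C, fx$atoms$radius, pts))
})

test_that("skin classification is invariant under rigid motion", {
  at <- atom_set(c(0, 1.6, 0.9), c(0, 0, 1.2), c(0, 0, 0.3),
                 c(1.2, 1.0, 0.8))
  sk0 <- build_skin(at, shrink = 0.45, perturb_magnitude = 0)
  set.seed(34)
  pts <- matrix(runif(450, -2, 3), ncol = 3)
  got0 <- classify_by_parity(sk0, pts)
  Rm <- random_rotation(); tr <- c(2, -1, 0.5)
  atr <- rotate_atoms(at, Rm)
  atr$x <- atr$x + tr[1]; atr$y <- atr$y + tr[2]; atr$z <- atr$z + tr[3]
  skr <- build_skin(atr, shrink = 0.45, perturb_magnitude = 0)
  ptsr <- pts %*% t(Rm) + rep(tr, each = nrow(pts))
  got1 <- classify_by_parity(skr, ptsr)
  expect_equal(got1, got0)
})
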