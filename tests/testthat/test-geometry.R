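# Ray/patch intersection kernels and the Sturm root solver.

test_that("sturm_roots finds and collapses real roots", {
  expect_equal(sturm_roots(c(-1, 0, 1), c(-2, 2)), c(-1, 1))
  expect_equal(sturm_roots(c(0.25, -1, 1), c(0, 1)), 0.5)   # double root
  expect_error(sturm_roots(c(NaN, 1), c(0, 1)), "non-finite")
  expect_error(sturm_roots(5, c(0, 1)), "degree")
})

test_that("sturm_roots matches a dense sign-change scan on random quartics", {
  set.seed(41)
  for (rep in 1:20) {
    rts <- sort(runif(4, -1.4, 1.4))
    p <- 1
    for (r in rts) p <- c(0, p) - c(r * p, 0)       # prod (x - r_i)
    got <- sturm_roots(p, c(-2, 2), tol = 1e-10)
    # oracle: scan p for sign changes at 1e-4 steps
    xs <- seq(-2, 2, by = 1e-4)
    v <- surfray:::poly_eval(p, xs)
    sw <- which(v[-1] * v[-length(v)] < 0)
    expect_equal(length(got), length(sw))
    expect_lt(max(abs(got - rts)), 1e-7)
  }
})

test_that("batched quartic solver agrees with the scalar Sturm path", {
  set.seed(42)
  for (rep in 1:200) {
    co <- c(runif(4, -5, 5), 1)
    got <- sort(surfray:::quartic_roots_batch(matrix(co, 1), -6, 6)$t)
    ref <- surfray:::crossing_roots(co, sturm_roots(co, c(-6, 6)), 12)
    expect_equal(length(got), length(ref))
    if (length(ref)) expect_lt(max(abs(got - ref)), 1e-7)
  }
})

test_that("ray_sphere returns crossing pairs and discards grazing contact", {
  r <- new_ray(c(-2, 0, 0), c(1, 0, 0), 10)
  h <- ray_sphere(r, c(0, 0, 0), 1)
  expect_equal(h$t, c(1, 3))
  expect_equal(h$nx, c(-1, 1))                      # outward normals
  # tangent ray: no intersection by the parity convention
  expect_equal(nrow(ray_sphere(new_ray(c(-2, 1, 0), c(1, 0, 0), 10),
                               c(0, 0, 0), 1)), 0L)
  # concave orientation flips the normal
  hc <- ray_sphere(r, c(0, 0, 0), 1, orientation = "concave")
  expect_equal(hc$nx, c(1, -1))
  # random rays against the quadratic-formula oracle
  set.seed(7)
  for (rep in 1:50) {
    o <- runif(3, -4, 4); d <- rnorm(3); d <- d / sqrt(sum(d^2))
    ctr <- runif(3, -1, 1); R <- runif(1, 0.5, 2)
    h <- ray_sphere(new_ray(o, d, 20), ctr, R)
    m <- o - ctr
    disc <- sum(m * d)^2 - (sum(m * m) - R^2)
    if (disc > 1e-6) {
      tt <- sort(c(-sum(m * d) - sqrt(disc), -sum(m * d) + sqrt(disc)))
      tt <- tt[tt >= 0 & tt <= 20]
      expect_equal(h$t, tt, tolerance = 1e-12)
    }
  }
})

test_that("ray_torus solves the quartic and matches an implicit scan", {
  tor <- list(c = c(0, 0, 0), a = c(0, 0, 1), R = 2, r = 0.5)
  h <- ray_torus(new_ray(c(-3, 0, 0), c(1, 0, 0), 10),
                 tor$c, tor$a, tor$R, tor$r)
  expect_equal(h$t, c(0.5, 1.5, 4.5, 5.5), tolerance = 1e-9)
  # along the symmetry axis: through the hole
  expect_equal(nrow(ray_torus(new_ray(c(0, 0, -3), c(0, 0, 1), 10),
                              tor$c, tor$a, tor$R, tor$r)), 0L)
  fimpl <- function(p) surfray:::torus_implicit(p, tor$c, tor$a, tor$R,
                                                tor$r)
  set.seed(8)
  for (rep in 1:15) {
    o <- c(runif(2, -4, 4), runif(1, -2, 2))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    h <- ray_torus(new_ray(o, d, 12), tor$c, tor$a, tor$R, tor$r)
    ref <- oracle_ray_scan(fimpl, o, d, 12)
    expect_equal(nrow(h), length(ref))
    if (length(ref)) expect_lt(max(abs(h$t - ref)), 1e-6)
  }
})

test_that("ray_quadric handles spheres and hyperboloids", {
  Q <- diag(c(1, 1, 1, -1))                         # unit sphere
  set.seed(9)
  for (rep in 1:100) {
    o <- runif(3, -3, 3); d <- rnorm(3); d <- d / sqrt(sum(d^2))
    hq <- ray_quadric(new_ray(o, d, 10), Q)
    hs <- ray_sphere(new_ray(o, d, 10), c(0, 0, 0), 1)
    expect_equal(hq$t, hs$t, tolerance = 1e-10)
  }
  Qh <- diag(c(1, 1, -1, -1))                       # x^2 + y^2 - z^2 = 1
  h <- ray_quadric(new_ray(c(-3, 0, 0), c(1, 0, 0), 10), Qh)
  expect_equal(h$t, c(2, 4), tolerance = 1e-10)
  expect_error(ray_quadric(new_ray(c(0, 0, 0), c(1, 0, 0), 1),
                           matrix(1:16, 4)), "symmetric")
})

test_that("ray_triangle uses barycentric coordinates", {
  r <- new_ray(c(1 / 3, 1 / 3, 0), c(0, 0, 1), 5)
  h <- ray_triangle(r, c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_equal(h$t, 1)
  # parallel to the plane: miss
  rp <- new_ray(c(-1, 0.2, 1), c(1, 0, 0), 5)
  expect_equal(nrow(ray_triangle(rp, c(0, 0, 1), c(1, 0, 1),
                                 c(0, 1, 1))), 0L)
})

test_that("a ray through a shared mesh edge is counted exactly once", {
  # the box face diagonal is shared by two coplanar triangles
  fx <- gen_box_mesh(2, 2, 2)
  h <- surface_ray_hits(fx$mesh, c(0, 0, -5), c(0, 0, 1), 10)
  expect_equal(nrow(h), 2L)                         # one crossing per face
  expect_equal(h$t, c(4, 6))
})

test_that("point_in_trim is a conjunction of predicates", {
  expect_true(point_in_trim(c(1, 2, 3), list()))
  hs <- trim_halfspace(c(1, 0, 0), 0)               # keep x <= 0
  expect_false(point_in_trim(c(1, 0, 0), list(hs)))
  expect_true(point_in_trim(c(-1, 0, 0), list(hs)))
  # convex tetrahedral trim against a barycentric containment oracle
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  trims <- lapply(faces, function(f) {
    e1 <- V[f[2], ] - V[f[1], ]; e2 <- V[f[3], ] - V[f[1], ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    inner <- V[setdiff(1:4, f)[1], ]
    if (sum(n * (inner - V[f[1], ])) < 0) n <- -n   # keep the inside
    trim_halfspace(-n, -sum(n * V[f[1], ]))
  })
  set.seed(10)
  pts <- matrix(runif(300, -0.2, 1.2), ncol = 3)
  got <- point_in_trim(pts, trims)
  Ti <- solve(t(cbind(V[2, ] - V[1, ], V[3, ] - V[1, ], V[4, ] - V[1, ])))
  bc <- sweep(pts, 2, V[1, ]) %*% t(Ti)
  ref <- bc[, 1] >= -1e-9 & bc[, 2] >= -1e-9 & bc[, 3] >= -1e-9 &
    rowSums(bc) <= 1 + 1e-9
  expect_equal(got, ref)
})

test_that("intersections are invariant under rigid motion of ray and patch", {
  set.seed(12)
  for (rep in 1:10) {
    Rm <- random_rotation()
    tr <- runif(3, -5, 5)
    o <- c(-3, runif(1, -1, 1), runif(1, -1, 1))
    d <- c(1, 0, 0)
    h0 <- ray_torus(new_ray(o, d, 12), c(0, 0, 0), c(0, 0, 1), 2, 0.5)
    h1 <- ray_torus(new_ray(as.numeric(Rm %*% o) + tr,
                            as.numeric(Rm %*% d), 12),
                    tr, as.numeric(Rm %*% c(0, 0, 1)), 2, 0.5)
    expect_equal(h0$t, h1$t, tolerance = 1e-9)
    hs0 <- ray_sphere(new_ray(o, d, 12), c(0.5, 0, 0), 1.2)
    hs1 <- ray_sphere(new_ray(as.numeric(Rm %*% o) + tr,
                              as.numeric(Rm %*% d), 12),
                      as.numeric(Rm %*% c(0.5, 0, 0)) + tr, 1.2)
    expect_equal(hs0$t, hs1$t, tolerance = 1e-9)
  }
})

test_that("a torus degenerating to its circle yields no spurious roots", {
  set.seed(14)
  for (rep in 1:25) {
    o <- c(-10, runif(1, -3, 3), runif(1, -3, 3))
    h <- ray_torus(new_ray(o, c(1, 0, 0), 25), c(0, 0, 0), c(0, 0, 1),
                   2, 1e-8)
    expect_equal(nrow(h), 0L)      # tangential contact is discarded
  }
})

test_that("closed primitives give even hit counts from outside", {
  set.seed(13)
  for (rep in 1:40) {
    o <- c(-10, runif(1, -3, 3), runif(1, -3, 3))
    d <- c(1, 0, 0)
    expect_equal(nrow(ray_sphere(new_ray(o, d, 25), runif(3, -1, 1),
                                 runif(1, 0.5, 2))) %% 2, 0)
    expect_equal(nrow(ray_torus(new_ray(o, d, 25), runif(3, -1, 1),
                                c(0, 0, 1), 2, 0.6)) %% 2, 0)
  }
})
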