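# Grid construction, acceleration structures, and the parity protocol.

test_that("make_grid arithmetic matches the scale/perfil convention", {
  g <- make_grid(gen_sphere_atom(1)$atoms, scale = 2, perfil = 50)
  expect_equal(g$h, 0.5)
  expect_equal(g$nv, rep(9L, 3))                 # span 4 A, odd vertices
  expect_equal(surfray:::grid_span(g), rep(4, 3))
  # perfil 90 leaves at least 5% margin per side
  g2 <- make_grid(gen_sphere_atom(1)$atoms, scale = 4, perfil = 90)
  span <- surfray:::grid_span(g2)[1]
  expect_gte((span - 2) / 2 / span, 0.05)
  # atoms plus probe strictly inside
  fx <- gen_random_cluster(n = 12, seed = 2)
  g3 <- make_grid(fx$atoms, scale = 2, perfil = 90, inflate = 1.4)
  C <- as.matrix(fx$atoms[, c("x", "y", "z")])
  r <- fx$atoms$radius + 1.4
  expect_true(all(C - r > rep(g3$origin, each = nrow(C))))
  expect_true(all(C + r < rep(g3$origin + surfray:::grid_span(g3),
                              each = nrow(C))))
  expect_error(make_grid(fx$atoms, scale = 50, max_vertices = 1e4),
               "lower scale")
})

test_that("accelerated candidate lists reproduce brute-force hits", {
  fx <- gen_random_cluster(n = 15, box = 3, r_range = c(0.7, 1.5),
                           seed = 9)
  s <- build_ses(fx$atoms, probe_radius = 1.4)
  g <- make_grid(fx$atoms, scale = 2, perfil = 90, inflate = 1.4)
  acc <- build_accel(s, g, 1)
  set.seed(91)
  for (i in 1:100) {
    o <- c(g$origin[1] - g$h, runif(1, g$origin[2], g$origin[2] + 12),
           runif(1, g$origin[3], g$origin[3] + 12))
    cand <- surfray:::accel_candidates(acc, o[2], o[3])
    h1 <- surface_ray_hits(s, o, c(1, 0, 0), 40, candidates = cand)
    h2 <- surface_ray_hits(s, o, c(1, 0, 0), 40, candidates = NULL)
    expect_equal(h1$t, h2$t)
    expect_equal(h1$patch, h2$patch)
  }
  # a patch fully outside the lattice is listed nowhere
  far <- build_ses(atom_set(1e3, 1e3, 1e3, 1), 0)
  acc2 <- build_accel(far, g, 1)
  expect_true(all(vapply(acc2$cells, length, 1L) == 0L))
})

test_that("an open surface exhausts retries, falls back, then errors", {
  # half-sphere: a deliberately non-closed patch set
  open_s <- surfray:::new_patch_surface(
    list(center = matrix(0, 1, 3), radius = 1, orient = 1,
         trims = list(list(trim_halfspace(c(0, 0, 1), 0)))),
    NULL, NULL, NULL, list(), "test")
  r <- cast_ray_checked(open_s, c(0.2, 0.1, -5), c(0, 0, 1), 10,
                        retry = 4, eps = 1e-3, seed = 3)
  expect_false(r$ok)
  expect_equal(r$retries, 4L)
  # rays that miss the cap are fine; rays through it fall back and are
  # flagged in the report
  g <- make_grid(rbind(c(-1, -1, -1), c(1, 1, 1)), scale = 2, perfil = 50)
  st <- cast_grid_rays(open_s, g, axes = 3L)
  expect_gt(st$report$fallbacks, 0)
  # a sphere whose lower crossing lies beyond every ray's span: each ray
  # sees exactly one hit, so the very first ray is already odd and there
  # is no stable neighbour to copy
  big <- surfray:::new_patch_surface(
    list(center = matrix(c(0, 0, -4), 1, 3), radius = 5, orient = 1,
         trims = list(list())),
    NULL, NULL, NULL, list(), "test")
  expect_error(cast_grid_rays(big, g, axes = 3L),
               "no stable neighbouring ray")
})

test_that("sphere casting classifies centers, faces and vertices", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0, perturb_magnitude = 0)
  g <- make_grid(at, scale = 4, perfil = 80)
  st <- cast_surface(s, g, seed = 3)
  nc <- g$nv - 1L
  mid <- (nc[1] + 1L) %/% 2L
  expect_true(st$center[mid, mid, mid])
  expect_false(st$center[1, 1, 1])
  expect_equal(st$report$center_disagreements, 0)
  cc <- lapply(1:3, function(a) surfray:::grid_center_coords(g, a))
  truth <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`) < 1
  expect_equal(sum(st$center != truth), 0L)
  # empty patch set: everything outside
  empty <- surfray:::new_patch_surface(
    list(center = matrix(0, 0, 3), radius = numeric(0),
         orient = numeric(0), trims = list()),
    NULL, NULL, NULL, list(), "empty")
  st0 <- cast_grid_rays(empty, g)
  expect_false(any(st0$center))
})

test_that("edge-ray hits lie on the surface and respect edge parity", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 4, perfil = 80)
  er <- cast_edge_rays(s, g, seed = 4)
  vc <- lapply(1:3, function(a) surfray:::grid_vertex_coords(g, a))
  e1 <- er$edge[[1]]
  idx <- which(!is.na(e1$first_t), arr.ind = TRUE)
  pts <- cbind(e1$first_t[idx], vc[[2]][idx[, 2]], vc[[3]][idx[, 3]])
  expect_lt(max(surface_residual(s, pts)), 1e-8)
  # an edge with equal endpoint statuses carries an even hit count
  vt <- er$vertex
  for (r in seq_len(min(nrow(idx), 200))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    if (vt[i, j, k] == vt[i + 1, j, k])
      expect_equal(e1$count[i, j, k] %% 2L, 0L)
    else
      expect_equal(e1$count[i, j, k] %% 2L, 1L)
  }
})

test_that("casting is deterministic for a fixed seed", {
  fx <- gen_two_atoms(1, 1, 2.5)
  s <- build_ses(fx$atoms, 1.4)
  g <- make_grid(fx$atoms, scale = 2, perfil = 90, inflate = 1.4)
  s1 <- cast_surface(s, g, seed = 11)
  s2 <- cast_surface(s, g, seed = 11)
  expect_identical(s1$center, s2$center)
  expect_identical(s1$edges$vertex, s2$edges$vertex)
  expect_identical(s1$casts[[1]]$hits_t, s2$casts[[1]]$hits_t)
})

test_that("the degenerate lattice-aligned mesh keeps full parity", {
  fx <- gen_degenerate_mesh()
  g <- make_grid(rbind(c(-1, -1, -1), c(1, 1, 1)), scale = 2, perfil = 50)
  st <- cast_surface(fx$mesh, g, seed = 5)
  expect_equal(st$report$fallbacks, 0)
  expect_equal(st$edges$report$fallbacks, 0)
  v <- volume_from_intervals(st)
  expect_equal(v$averaged, fx$truth$volume, tolerance = 1e-9)
})

test_that("status grids dump to the flat voxel format", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 2, perfil = 80)
  st <- cast_grid_rays(s, g)
  f <- tempfile(fileext = ".txt")
  write_status_grid(st, f)
  lines <- readLines(f)
  hdr <- as.numeric(strsplit(lines[1], " ")[[1]])
  expect_equal(hdr[1:3], g$nv - 1L)
  vals <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(length(vals), prod(g$nv - 1L))
  expect_equal(sum(vals), sum(st$center))
})
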