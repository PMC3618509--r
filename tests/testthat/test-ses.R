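# Solvent-excluded / van der Waals / solvent-accessible patch builders.

test_that("an isolated atom gives one untrimmed convex sphere patch", {
  s <- build_ses(gen_sphere_atom(2)$atoms, probe_radius = 1.4)
  expect_equal(nrow(s$spheres$center), 1L)
  expect_null(s$tori)
  expect_equal(length(s$spheres$trims[[1]]), 0L)
  expect_equal(s$spheres$radius, 2)
})

test_that("two distant atoms give two untrimmed spheres and no torus", {
  fx <- gen_two_atoms(1, 1, 10)
  s <- build_ses(fx$atoms, probe_radius = 1.4)
  expect_equal(nrow(s$spheres$center), 2L)
  expect_null(s$tori)
})

test_that("a bridged pair gives trimmed spheres plus one saddle torus", {
  fx <- gen_two_atoms(1, 1, 2.5, probe_radius = 1.4)
  s <- build_ses(fx$atoms, probe_radius = 1.4)
  expect_equal(nrow(s$spheres$center), 2L)      # no triples: no probes
  expect_equal(nrow(s$tori$center), 1L)
  expect_gt(length(s$spheres$trims[[1]]), 0L)
  # neck radius from the rolling-probe construction
  h <- surface_ray_hits(s, c(1.25, 0, -5), c(0, 0, 1), 10)
  rt <- sqrt(2.4^2 - 1.25^2)
  expect_equal(abs(h$t - 5), rep(rt - 1.4, 2), tolerance = 2e-4)
})

test_that("vdw is the union of balls: parity matches the direct oracle", {
  fx <- gen_random_cluster(n = 8, box = 2.5, r_range = c(0.8, 1.6),
                           seed = 6)
  s <- build_vdw(fx$atoms)
  C <- as.matrix(fx$atoms[, c("x", "y", "z")])
  set.seed(61)
  pts <- matrix(runif(900, -4.5, 4.5), ncol = 3)
  # skip points within the perturbation distance of the boundary
  dist <- oracle_union_signed_dist(C, fx$atoms$radius, pts)
  pts <- pts[abs(dist) > 1e-3, , drop = FALSE]
  got <- classify_by_parity(s, pts)
  ref <- oracle_union_inside(C, fx$atoms$radius, pts)
  expect_equal(got, ref)
})

test_that("ses with zero probe and vdw classify identically", {
  fx <- gen_random_cluster(n = 6, box = 2, r_range = c(0.8, 1.4), seed = 8)
  s0 <- build_ses(fx$atoms, probe_radius = 0, seed = 2)
  sv <- build_vdw(fx$atoms, seed = 2)
  set.seed(81)
  pts <- matrix(runif(600, -3.5, 3.5), ncol = 3)
  expect_equal(classify_by_parity(s0, pts), classify_by_parity(sv, pts))
})

test_that("sas inflates radii by the probe", {
  s <- build_sas(gen_sphere_atom(1)$atoms, probe_radius = 1.4)
  h <- surface_ray_hits(s, c(-5, 0, 0), c(1, 0, 0), 10)
  expect_equal(diff(h$t) / 2, 2.4, tolerance = 2e-4)
  # two distant atoms: SAS area is additive (sum of inflated spheres)
  fx <- gen_two_atoms(1, 1.2, 12)
  s2 <- build_sas(fx$atoms, probe_radius = 1.4)
  g <- make_grid(fx$atoms, scale = 4, perfil = 90, inflate = 1.4)
  st <- cast_surface(s2, g, seed = 1)
  ar <- mesh_area(mc_analytic(st))$total
  truth <- 4 * pi * (2.4^2 + 2.6^2)
  expect_lt(abs(ar - truth) / truth, 0.02)
})

test_that("the bridged-pair mesh area matches the revolution quadrature", {
  fx <- gen_two_atoms(1, 1, 2.5, probe_radius = 1.4)
  s <- build_ses(fx$atoms, probe_radius = 1.4)
  g <- make_grid(fx$atoms, scale = 4, perfil = 90, inflate = 1.4)
  st <- cast_surface(s, g, seed = 1)
  ar <- mesh_area(mc_analytic(st))$total
  # inscribed flat triangles sit below the curved truth by the chordal
  # deficit (~h^2/R^2, about 1% here)
  expect_lt(abs(ar - fx$truth$ses_area) / fx$truth$ses_area, 0.015)
  vol <- estimate_volume(s, g, seed = 1)$averaged
  expect_lt(abs(vol - fx$truth$ses_volume) / fx$truth$ses_volume, 0.015)
})

test_that("parity holds over random rays on the bridged pair", {
  fx <- gen_two_atoms(1, 1, 2.5, probe_radius = 1.4)
  s <- build_ses(fx$atoms, probe_radius = 1.4)
  set.seed(62)
  odd <- 0L
  for (i in 1:300) {
    o <- c(-6, runif(1, -3, 3), runif(1, -3, 3))
    h <- surface_ray_hits(s, o, c(1, 0, 0), 25)
    if (nrow(h) %% 2L == 1L) odd <- odd + 1L
  }
  expect_equal(odd, 0L)
})
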