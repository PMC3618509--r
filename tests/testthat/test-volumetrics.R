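# Volume estimation, cavity detection and conditional filling.

test_that("a lattice-aligned box has exact interval volume", {
  fx <- gen_box_mesh(2, 2, 2)
  g <- make_grid(rbind(c(-1, -1, -1), c(1, 1, 1)), scale = 2, perfil = 50)
  st <- cast_grid_rays(fx$mesh, g, seed = 1)
  v <- volume_from_intervals(st)
  expect_equal(unname(v$per_axis), rep(8, 3), tolerance = 1e-12)
})

test_that("sphere volume converges and axes agree", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 8, perfil = 80)
  st <- cast_grid_rays(s, g, seed = 2)
  v <- volume_from_intervals(st)
  truth <- 4 * pi / 3
  expect_lt(abs(v$averaged - truth) / truth, 0.02)
  expect_lt(rel_spread(v$per_axis), 0.01)         # three-axis agreement
  # the denser-quadrature estimator is tighter at scale 4
  g4 <- make_grid(at, scale = 4, perfil = 80)
  v4 <- estimate_volume(s, g4, rays_per_cell = 2, seed = 2)
  expect_lt(abs(v4$averaged - truth) / truth, 0.01)
})

test_that("the hollow shell yields one cavity of the right volume", {
  fx <- gen_hollow_shell(seed = 2, verify = FALSE)
  s <- build_vdw(fx$atoms, seed = 2)
  g <- make_grid(fx$atoms, scale = 4, perfil = 90)
  st <- cast_grid_rays(s, g, seed = 2)
  cav <- detect_cavities(st)
  expect_equal(length(cav$cavities), 1L)
  expect_lt(abs(cav$table$volume_A3 - fx$truth$void_volume) /
              fx$truth$void_volume, 0.05)
  # partition: exterior + cavities + inside cover all cube centers
  lab <- cav$exterior + st$center
  for (cv in cav$cavities) lab[cv$voxels] <- lab[cv$voxels] + 1L
  expect_true(all(lab == 1L))
  # volume additivity of the outside region
  h3 <- g$h^3
  expect_equal(sum(!st$center) * h3,
               sum(cav$exterior) * h3 + sum(cav$table$volume_A3))
  # report export
  f <- tempfile(fileext = ".tsv")
  write_cavity_report(cav, f)
  tab <- utils::read.delim(f)
  expect_equal(tab$volume_A3, cav$table$volume_A3)
})

test_that("two disjoint shells yield two cavities", {
  a1 <- gen_hollow_shell(seed = 3, verify = FALSE)$atoms
  a2 <- a1; a2$x <- a2$x + 9
  both <- atom_set(c(a1$x, a2$x), c(a1$y, a2$y), c(a1$z, a2$z),
                   c(a1$radius, a2$radius))
  s <- build_vdw(both, seed = 3)
  g <- make_grid(both, scale = 2, perfil = 90)
  st <- cast_grid_rays(s, g, seed = 3)
  expect_equal(length(detect_cavities(st)$cavities), 2L)
})

test_that("filling respects the threshold and is idempotent", {
  fx <- gen_hollow_shell(seed = 2, verify = FALSE)
  s <- build_vdw(fx$atoms, seed = 2)
  g <- make_grid(fx$atoms, scale = 3, perfil = 90)
  st <- cast_surface(s, g, seed = 2)
  cav <- detect_cavities(st)
  # min_volume 0: identity
  st0 <- fill_cavities(st, cav, min_volume = 0)
  expect_identical(st0$center, st$center)
  # the default water threshold leaves a ~45 A^3 cavity untouched
  stw <- fill_cavities(st, cav, min_volume = 11.49)
  expect_identical(stw$center, st$center)
  # filling above the cavity volume removes it and repairs the field
  stf <- fill_cavities(st, cav, min_volume = 1e4)
  expect_equal(length(detect_cavities(stf)$cavities), 0L)
  m <- mc_analytic(stf)
  tp <- mesh_topology(m)
  expect_true(tp$closed)
  expect_equal(tp$euler, 2L)                     # genus-0 single shell
  # idempotence
  stf2 <- fill_cavities(stf, detect_cavities(stf), min_volume = 1e4)
  expect_identical(stf2$center, stf$center)
})

test_that("a surface leaking over the boundary is flagged", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 2, perfil = 80)
  st <- cast_grid_rays(s, g)
  st$center[] <- TRUE          # nothing outside at the boundary
  expect_error(detect_cavities(st), "does not enclose")
})
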