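# Fixture generators and their recorded ground truths.

test_that("sphere and two-atom truths are self-consistent", {
  fx <- gen_sphere_atom(1)
  expect_equal(fx$truth$area, 4 * pi)
  expect_equal(fx$truth$volume, 4 * pi / 3)
  far <- gen_two_atoms(1, 1, 10)
  expect_equal(far$truth$vdw_area, 8 * pi)
  # overlapping pair against a Monte-Carlo membership oracle
  near <- gen_two_atoms(1, 1, 1.5, probe_radius = 0)
  set.seed(71)
  pts <- matrix(runif(3e4 * 3, -1.5, 3), ncol = 3)
  frac <- mean(oracle_union_inside(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                                   c(1, 1), pts))
  mc_vol <- frac * 4.5^3
  expect_lt(abs(near$truth$vdw_volume - mc_vol) / mc_vol, 0.05)
  # the SES quadrature collapses to the union values as the probe vanishes
  tiny <- gen_two_atoms(1, 1, 1.5, probe_radius = 1e-4)
  expect_lt(abs(tiny$truth$ses_area - near$truth$vdw_area) /
              near$truth$vdw_area, 1e-3)
  expect_lt(abs(tiny$truth$ses_volume - near$truth$vdw_volume) /
              near$truth$vdw_volume, 1e-3)
})

test_that("the linear chain truth follows inclusion-exclusion", {
  fx <- gen_linear_chain(n = 3, R = 1, overlap = 0.25)
  pair <- gen_two_atoms(1, 1, 1.5, probe_radius = 0)
  expect_equal(fx$truth$vdw_area,
               3 * 4 * pi - 2 * (8 * pi - pair$truth$vdw_area))
  expect_error(gen_linear_chain(overlap = 0.7), "overlap")
})

test_that("c60 atoms are exactly cospherical", {
  fx <- gen_c60()
  C <- as.matrix(fx$atoms[, c("x", "y", "z")])
  expect_equal(nrow(C), 60L)
  d <- sqrt(rowSums(C^2))
  expect_lt(max(abs(d - 3.55)), 1e-12)
  # nearest-neighbour distance matches the truncated icosahedron bond
  D <- as.matrix(dist(C)); diag(D) <- Inf
  expect_equal(sd(apply(D, 1, min)), 0, tolerance = 1e-9)
})

test_that("hollow shells are watertight or refuse to emit", {
  fx <- gen_hollow_shell(seed = 5, verify = FALSE)
  expect_equal(fx$truth$cavities, 1L)
  expect_gt(fx$truth$void_volume, 10)
  # identical seed, identical fixture
  fx2 <- gen_hollow_shell(seed = 5, verify = FALSE)
  expect_identical(fx$atoms, fx2$atoms)
  expect_identical(fx$truth$void_volume, fx2$truth$void_volume)
  # too sparse a shell is rejected before emission
  expect_error(gen_hollow_shell(n_atoms = 12, atom_radius = 0.5,
                                verify = FALSE), "watertight")
})

test_that("mesh fixtures carry exact topology and refine to their truths", {
  tor <- gen_torus_mesh(2, 0.7, nu = 24, nv = 12)
  expect_equal(mesh_topology(tor$mesh)$euler, 0L)     # genus 1
  a1 <- mesh_area(tor$mesh)$total
  a2 <- mesh_area(gen_torus_mesh(2, 0.7, nu = 96, nv = 48)$mesh)$total
  truth <- 4 * pi^2 * 2 * 0.7
  expect_lt(abs(a2 - truth) / truth, abs(a1 - truth) / truth)
  expect_lt(abs(a2 - truth) / truth, 0.01)
  box <- gen_box_mesh(2, 2, 2)
  expect_equal(box$truth$volume, 8)
  expect_equal(mesh_area(box$mesh)$total, 24)
  deg <- gen_degenerate_mesh()
  expect_true(mesh_topology(deg$mesh)$closed)
})
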