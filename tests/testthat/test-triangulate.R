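# Analytic-vertex and bisecting marching cubes, smoothing, areas, export.

test_that("the generated case table has the expected structure", {
  tab <- mc_tables()
  expect_length(tab, 256L)
  expect_length(tab[[1]], 0L)                     # all outside
  expect_length(tab[[256]], 0L)                   # all inside
  # one corner inside: a single triangle cutting that corner
  expect_length(tab[[2]], 1L)
  expect_length(tab[[2]][[1]], 3L)
  # every loop pairs edges that share a cube face
  topo <- surfray:::mc_cube_topology()
  for (case in c(2, 25, 61, 105, 151, 254)) {
    for (loop in tab[[case + 1]]) {
      n <- length(loop)
      for (q in seq_len(n)) {
        e1 <- loop[q]; e2 <- loop[q %% n + 1]
        shared <- vapply(topo$face_edges, function(fe)
          e1 %in% fe && e2 %in% fe, logical(1))
        expect_true(any(shared))
      }
    }
  }
})

test_that("analytic MC places vertices on the surface", {
  fx <- gen_two_atoms(1, 1, 2.5)
  s <- build_ses(fx$atoms, 1.4)
  g <- make_grid(fx$atoms, scale = 4, perfil = 90, inflate = 1.4)
  st <- cast_surface(s, g, seed = 5)
  m <- mc_analytic(st)
  expect_equal(m$fallbacks, 0L)
  expect_lt(max(surface_residual(s, m$vertices)), 1e-9)
  tp <- mesh_topology(m)
  expect_true(tp$closed)
  expect_equal(tp$genus, 0L)
  # grid consistency: triangle vertices inside the closed owning cube
  lo <- rep(g$origin, each = nrow(m$cube)) +
    (m$cube - 1L) * g$h - 1e-9
  hi <- lo + g$h + 2e-9
  for (cidx in 1:3) {
    V <- m$vertices[m$triangles[, cidx], , drop = FALSE]
    expect_true(all(V >= lo & V <= hi))
  }
})

test_that("a fully inside or outside region emits no triangles", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 2, perfil = 80)
  st <- cast_surface(s, g, seed = 1)
  st$edges$vertex[] <- TRUE
  expect_equal(nrow(mc_analytic(st)$triangles), 0L)
})

test_that("a re-cast torus mesh keeps genus 1", {
  fx <- gen_torus_mesh(2, 0.7, nu = 48, nv = 24)
  V <- fx$mesh$vertices
  g <- make_grid(rbind(apply(V, 2, min), apply(V, 2, max)),
                 scale = 4, perfil = 85)
  st <- cast_surface(fx$mesh, g, seed = 6)
  m <- mc_analytic(st)
  tp <- mesh_topology(m)
  expect_true(tp$closed)
  expect_equal(tp$euler, 0L)                      # genus 1
  v <- volume_from_intervals(st)
  expect_lt(abs(v$averaged - fx$truth$volume) / fx$truth$volume, 0.03)
})

test_that("bisecting MC works from grid rays alone, same topology", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 4, perfil = 80)
  st <- cast_grid_rays(s, g, seed = 2)            # no Edge Rays at all
  mb <- mc_bisecting(st)
  tp <- mesh_topology(mb)
  expect_true(tp$closed)
  expect_equal(tp$genus, 0L)
  ar <- mesh_area(mb)$total
  expect_lt(abs(ar - 4 * pi) / (4 * pi), 0.05)
})

test_that("laplacian smoothing shrinks area but not connectivity", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 4, perfil = 80)
  m <- mc_analytic(cast_surface(s, g, seed = 2))
  expect_identical(laplacian_smooth(m, 0)$vertices, m$vertices)
  areas <- numeric(4)
  mm <- m
  areas[1] <- mesh_area(mm)$total
  for (it in 2:4) {
    mm <- laplacian_smooth(mm, 1, 0.5)
    areas[it] <- mesh_area(mm)$total
  }
  expect_true(all(diff(areas) < 0))               # monotone shrinkage
  expect_equal(nrow(mm$vertices), nrow(m$vertices))
  expect_equal(nrow(mm$triangles), nrow(m$triangles))
})

test_that("per-cube areas conserve the total", {
  fx <- gen_two_atoms(1, 1, 2.5)
  s <- build_ses(fx$atoms, 1.4)
  g <- make_grid(fx$atoms, scale = 3, perfil = 90, inflate = 1.4)
  m <- mc_analytic(cast_surface(s, g, seed = 7))
  ar <- mesh_area(m)
  expect_lt(abs(sum(ar$per_cube$area) - ar$total) / ar$total, 1e-12)
  f <- tempfile(fileext = ".tsv")
  write_area_map(ar, f)
  tab <- utils::read.delim(f)
  expect_equal(sum(tab$area), ar$total, tolerance = 1e-9)
  # one right triangle has area 1/2
  one <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
              triangles = matrix(1:3, 1), cube = matrix(1L, 1, 3))
  expect_equal(mesh_area(one)$total, 0.5)
})

test_that("the incident-ray estimator is exact on a square-on face", {
  fx <- gen_box_mesh(2, 2, 2)
  g <- make_grid(rbind(c(-1, -1, -1), c(1, 1, 1)), scale = 2, perfil = 50)
  a <- incident_ray_area(fx$mesh, g, axis = 1)
  expect_equal(a, 8, tolerance = 1e-12)   # both x faces, cos theta = 1
})

test_that("the incident-ray estimator approaches the sphere area", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 8, perfil = 80)
  a1 <- incident_ray_area(s, g, axis = 1, clamp = 0.1)
  expect_lt(abs(a1 - 4 * pi) / (4 * pi), 0.05)
  a3 <- incident_ray_area(s, g, averaged = TRUE, clamp = 0.1)
  expect_lt(abs(a3 - 4 * pi) / (4 * pi), 0.05)
})
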