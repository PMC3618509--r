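# Mesh import/export and the closedness contract.

icosahedron_off_lines <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F0 <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10),
              c(0, 10, 11), c(1, 5, 9), c(5, 11, 4), c(11, 10, 2),
              c(10, 7, 6), c(7, 1, 8), c(3, 9, 4), c(3, 4, 2),
              c(3, 2, 6), c(3, 6, 8), c(3, 8, 9), c(4, 9, 5),
              c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  c("OFF", "12 20 0",
    sprintf("%.10f %.10f %.10f", V[, 1], V[, 2], V[, 3]),
    sprintf("3 %d %d %d", F0[, 1], F0[, 2], F0[, 3]))
}

test_that("an icosahedron OFF loads as a closed mesh", {
  f <- tempfile(fileext = ".off")
  writeLines(icosahedron_off_lines(), f)
  m <- load_mesh_surface(f)
  expect_equal(nrow(m$vertices), 12L)
  expect_equal(nrow(m$triangles), 20L)
  tp <- mesh_topology(m)
  expect_true(tp$closed)
  expect_equal(tp$genus, 0L)
})

test_that("a mesh with a missing face is rejected as not closed", {
  lines <- icosahedron_off_lines()
  lines[2] <- "12 19 0"
  f <- tempfile(fileext = ".off")
  writeLines(lines[-length(lines)], f)
  expect_error(load_mesh_surface(f), "not closed")
})

test_that("export/import round trips preserve counts and area", {
  fx <- gen_torus_mesh(2, 0.7, nu = 16, nv = 8)
  a0 <- mesh_area(fx$mesh)$total
  for (fmt in c("off", "ply", "msms")) {
    stem <- tempfile()
    path <- if (fmt == "msms") stem else paste0(stem, ".", fmt)
    export_mesh(fx$mesh, path, fmt)
    m2 <- load_mesh_surface(path, if (fmt == "msms") "msms" else fmt)
    expect_equal(nrow(m2$vertices), nrow(fx$mesh$vertices))
    expect_equal(nrow(m2$triangles), nrow(fx$mesh$triangles))
    tol <- if (fmt == "msms") 1e-5 else 1e-9   # %12.6f coordinates
    expect_lt(abs(mesh_area(m2)$total - a0) / a0, tol)
  }
})

test_that("format details: OFF header word and 1-based MSMS faces", {
  fx <- gen_box_mesh(2, 2, 2)
  f <- tempfile(fileext = ".off")
  export_mesh(fx$mesh, f, "off")
  expect_identical(readLines(f, n = 1L), "OFF")
  stem <- tempfile()
  export_mesh(fx$mesh, stem, "msms")
  face <- readLines(paste0(stem, ".face"))[-(1:3)]
  idx <- as.integer(unlist(strsplit(trimws(face), "[[:space:]]+")))
  expect_gte(min(idx), 1L)
  expect_lte(max(idx), 8L)
})

test_that("orientation is repaired to give positive enclosed volume", {
  fx <- gen_box_mesh(2, 2, 2)
  flipped <- mesh_surface(fx$mesh$vertices,
                          fx$mesh$triangles[, c(1, 3, 2)])
  expect_gt(surfray:::mesh_signed_volume(flipped$vertices,
                                         flipped$triangles), 0)
})
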