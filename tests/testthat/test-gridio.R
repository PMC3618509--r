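# Grid coloring, boundary point detection, and surface projection.

test_that("color_grid applies the cavity policy", {
  fx <- gen_hollow_shell(seed = 2, verify = FALSE)
  s <- build_vdw(fx$atoms, seed = 2)
  g <- make_grid(fx$atoms, scale = 3, perfil = 90)
  st <- cast_grid_rays(s, g, seed = 2)
  keep <- color_grid(st, "keep")
  expect_identical(keep$center, st$center)       # identity on the status
  filled <- color_grid(st, "fill_all")
  # floodfill oracle: no outside label disconnected from the boundary
  cavs <- detect_cavities(st)
  inner <- unlist(lapply(cavs$cavities, `[[`, "voxels"))
  expect_true(all(filled$center[inner]))
  expect_equal(filled$fill_log, 1L)
  # below-threshold policy keeps the big void
  kept <- color_grid(st, "fill_below", min_volume = 11.49)
  expect_identical(kept$center, st$center)
})

test_that("boundary points match a direct mixed-face scan", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 4, perfil = 80)
  st <- cast_grid_rays(s, g, seed = 1)
  cm <- color_grid(st, "keep")
  bp <- find_boundary_points(cm)
  expect_gt(nrow(bp), 0L)
  # oracle: loop over all cubes comparing their six face labels
  nc <- g$nv - 1L
  ref <- NULL
  for (k in seq_len(nc[3])) for (j in seq_len(nc[2]))
    for (i in seq_len(nc[1])) {
      f <- c(cm$face[[1]][i, j, k], cm$face[[1]][i + 1, j, k],
             cm$face[[2]][i, j, k], cm$face[[2]][i, j + 1, k],
             cm$face[[3]][i, j, k], cm$face[[3]][i, j, k + 1])
      if (length(unique(f)) > 1L) ref <- rbind(ref, c(i, j, k))
    }
  got <- as.matrix(bp[, c("i", "j", "k")])
  dimnames(got) <- NULL
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               ref[order(ref[, 1], ref[, 2], ref[, 3]), ])
  # deterministic lexicographic order
  expect_true(!is.unsorted(order(bp$i, bp$j, bp$k)))
  # an all-inside grid has no boundary points
  cm2 <- cm; cm2$center[] <- TRUE
  for (ax in 1:3) cm2$face[[ax]][] <- TRUE
  expect_equal(nrow(find_boundary_points(cm2)), 0L)
})

test_that("projection onto a sphere is the radial foot point", {
  s <- build_ses(gen_sphere_atom(1.5)$atoms, 0, perturb_magnitude = 0)
  set.seed(51)
  pts <- matrix(rnorm(60), ncol = 3) * 2
  pr <- project_points(pts, s)
  d <- sqrt(rowSums(pts^2))
  expect_equal(pr$dist, abs(d - 1.5), tolerance = 1e-9)
  expect_lt(max(pr$residual), 1e-6)
})

test_that("projection onto a triangle interior is the perpendicular foot", {
  fx <- gen_box_mesh(2, 2, 2)
  p <- c(0.2, -0.3, 5)
  pr <- project_points(matrix(p, 1), fx$mesh)
  expect_equal(c(pr$px, pr$py, pr$pz), c(0.2, -0.3, 1), tolerance = 1e-12)
  expect_equal(pr$dist, 4)
})

test_that("torus projections agree with a dense parameter-sweep oracle", {
  tor <- surfray:::new_patch_surface(
    list(center = matrix(0, 0, 3), radius = numeric(0),
         orient = numeric(0), trims = list()),
    list(center = matrix(c(0, 0, 0), 1), axis = matrix(c(0, 0, 1), 1),
         R = 2, r = 0.6, orient = 1, trims = list(list())),
    NULL, NULL, list(), "torus")
  set.seed(52)
  pts <- matrix(runif(45, -3, 3), ncol = 3)
  pr <- project_points(pts, tor)
  torus_pt <- function(th, ph)
    cbind((2 + 0.6 * cos(ph)) * cos(th), (2 + 0.6 * cos(ph)) * sin(th),
          0.6 * sin(ph))
  sweep_min <- function(p, th, ph) {
    gg <- expand.grid(th = th, ph = ph)
    samp <- torus_pt(gg$th, gg$ph)
    d <- sqrt(colSums((t(samp) - p)^2))
    b <- which.min(d)
    list(d = d[b], th = gg$th[b], ph = gg$ph[b])
  }
  for (i in seq_len(nrow(pts))) {
    # coarse 100 x 100 sweep, then a local refinement pass around the
    # best sample so the oracle itself resolves 1e-4
    co <- sweep_min(pts[i, ], seq(0, 2 * pi, length.out = 101)[-101],
                    seq(0, 2 * pi, length.out = 101)[-101])
    w <- 2 * pi / 100
    fi <- sweep_min(pts[i, ],
                    seq(co$th - w, co$th + w, length.out = 121),
                    seq(co$ph - w, co$ph + w, length.out = 121))
    expect_lt(abs(pr$dist[i] - fi$d), 1e-4)
    expect_lt(pr$residual[i], 1e-6)
  }
})

test_that("projected skin boundary points land on the surface", {
  at <- atom_set(c(0, 1.6), c(0, 0), c(0, 0), c(1.2, 1.0))
  sk <- build_skin(at, shrink = 0.45, perturb_magnitude = 0)
  g <- make_grid(at, scale = 3, perfil = 80)
  st <- cast_grid_rays(sk, g, seed = 3)
  bp <- find_boundary_points(color_grid(st, "keep"))
  pr <- project_points(utils::head(bp, 40), sk)
  expect_lt(max(pr$residual), 1e-6)
  # boundary cubes sit within a cube diagonal of the surface
  expect_lt(max(pr$dist), sqrt(3) * g$h)
  f <- tempfile(fileext = ".tsv")
  write_boundary_points(utils::head(bp, 40), pr, f)
  expect_equal(nrow(utils::read.delim(f)), 40L)
})

test_that("color maps export to voxel text files", {
  at <- atom_set(0, 0, 0, 1)
  s <- build_ses(at, 0)
  g <- make_grid(at, scale = 2, perfil = 80)
  cm <- color_grid(cast_grid_rays(s, g), "keep")
  stem <- tempfile()
  paths <- write_colormap(cm, stem)
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  lines <- readLines(paths[1])
  expect_equal(as.numeric(strsplit(lines[1], " ")[[1]])[1:3], g$nv - 1L)
})
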