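test_that("the PCA-oriented box recovers box dimensions in any pose", {
  bx <- mesh_box(c(-1, -0.5, -0.25), c(1, 0.5, 0.25))
  ob <- compute_obb(bx)
  expect_equal(sort(ob$half), c(0.25, 0.5, 1), tolerance = 1e-9)
  expect_equal(crossprod(ob$axes), diag(3), tolerance = 1e-9)

  q <- neurofil:::quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  bx2 <- bx
  bx2$vertices <- neurofil:::quat_rotate(q, bx$vertices)
  ob2 <- compute_obb(bx2)
  expect_equal(sort(ob2$half), c(0.25, 0.5, 1), tolerance = 1e-6)
  # all vertices inside the box
  W <- sweep(bx2$vertices, 2, ob2$center) %*% ob2$axes
  expect_true(all(abs(W) <= matrix(ob2$half, nrow(W), 3, byrow = TRUE) + 1e-9))

  tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  obt <- compute_obb(tet)
  Wt <- sweep(tet$vertices, 2, obt$center) %*% obt$axes
  expect_true(all(abs(Wt) <= matrix(obt$half, nrow(Wt), 3, byrow = TRUE) + 1e-9))
})

test_that("voxel occupancy matches analytic volumes", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  g <- voxelize(cube, 0.1)
  expect_lt(abs(sum(g$occ) - 1000) / 1000, 0.05)

  sph <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 3)
  gs <- voxelize(sph, 0.05)
  expect_lt(abs(sum(gs$occ) * 0.05^3 - 4.18879) / 4.18879, 0.05)

  patch <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                   rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_warning(gp <- voxelize(patch, 0.1), "degenerate")
  expect_identical(sum(gp$occ), 0L)
})

test_that("voxelize enforces its budget", {
  expect_error(voxelize(mesh_box(), 1e-4, voxel_budget = 1000^3),
               class = "neurofil_voxel_budget")
})

test_that("morphological closing joins gaps within the dilation reach", {
  g0 <- structure(list(occ = array(FALSE, c(20, 9, 9)), voxel_size = 1,
                       origin = c(0, 0, 0), axes = diag(3),
                       center = c(0, 0, 0)), class = "voxel_grid")
  g0$occ[3:5, 4:6, 4:6] <- TRUE
  g0$occ[8:10, 4:6, 4:6] <- TRUE # 2-voxel gap, within the closing reach
  expect_identical(morphological_close(g0, 0, 0)$occ, g0$occ)
  expect_identical(neurofil:::count_components(g0$occ), 2L)
  closed <- morphological_close(g0, 2, 2)
  expect_identical(neurofil:::count_components(closed$occ), 1L)

  blob <- voxelize(mesh_icosphere(c(0, 0, 0), 0.5, subdiv = 2), 0.05,
                   pad_voxels = 5)
  cl <- morphological_close(blob, 2, 2)
  expect_identical(neurofil:::count_components(cl$occ), 1L)
  # closing a convex blob changes volume by at most a surface shell
  surface_voxels <- sum(blob$occ) - sum(morphological_close(blob, 0, 1)$occ)
  expect_lte(abs(sum(cl$occ) - sum(blob$occ)), max(surface_voxels, 1) * 2)
})

test_that("surface extraction is closed and volume-accurate", {
  sph <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 3)
  g <- voxelize(sph, 0.05, pad_voxels = 4) # ball of 20 voxel radius
  m <- extract_surface(g, 1, 0.5)
  expect_true(is_watertight(m))
  expect_lt(abs(mesh_metrics(m)$volume - 4.18879) / 4.18879, 0.05)

  gc <- voxelize(mesh_box(), 0.1, pad_voxels = 3)
  mc <- extract_surface(gc, 0, 0.5) # no smoothing: stepped but closed
  expect_true(is_watertight(mc))

  g0 <- g
  g0$occ[] <- FALSE
  expect_error(extract_surface(g0, 1, 0.5), class = "neurofil_empty_mesh")
})

test_that("mesh metrics integrate area, volume and mass center", {
  mm <- mesh_metrics(mesh_box(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(mm$surface_area, 6)
  expect_identical(mm$volume, 1)
  expect_equal(mm$mass_center, c(0.5, 0.5, 0.5))

  tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  mt <- mesh_metrics(tet)
  expect_equal(mt$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(mt$mass_center, c(0.25, 0.25, 0.25), tolerance = 1e-12)

  flipped <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  flipped$faces[3, ] <- flipped$faces[3, c(1, 3, 2)]
  mf <- mesh_metrics(flipped)
  expect_equal(mf$volume, 1, tolerance = 1e-12)
  expect_equal(mf$mass_center, c(0.5, 0.5, 0.5), tolerance = 1e-12)

  open <- mesh_box()
  open$faces <- open$faces[-1, ]
  expect_warning(mo <- mesh_metrics(open), "open mesh")
  expect_true(is.na(mo$volume))
  expect_false(is.na(mo$surface_area))
})

test_that("metrics CSV has the documented dialect and empty open cells", {
  p <- tempfile(fileext = ".csv")
  open <- suppressWarnings(mesh_metrics({
    o <- mesh_box(); o$faces <- o$faces[-1, ]; o
  }))
  write_metrics_csv(list(cube = mesh_metrics(mesh_box()), holed = open), p)
  lines <- readLines(p)
  expect_length(lines, 3L)
  expect_identical(lines[1], "id,surface_area_um2,volume_um3,com_x,com_y,com_z")
  expect_match(lines[3], "^holed,[0-9.]+,,,,$")
  tab <- read.csv(p)
  expect_equal(tab$volume_um3[1], 1)
  expect_true(is.na(tab$volume_um3[2]))
})

test_that("repair unifies a holed sphere into a watertight surface", {
  hs <- mesh_icosphere(c(0, 0, 0), 0.5, subdiv = 3)
  hs$faces <- hs$faces[-(1:8), ]
  res <- repair_mesh(hs, repair_config(voxel_size = 0.025))
  expect_true(is_watertight(res$mesh))
  expect_identical(res$n_components, 1L)
  vol <- 4 / 3 * pi * 0.5^3
  expect_lt(abs(res$metrics$volume - vol) / vol, 0.07)
})

test_that("sampled Hausdorff distances match analytic sphere geometry", {
  a <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 2)
  rep0 <- hausdorff(a, a, n_samples = 2000, seed = 3)
  expect_lt(rep0$symmetric, 1e-12)
  expect_identical(rep0$symmetric, max(rep0$directed_ab, rep0$directed_ba))
  expect_lte(rep0$min_error, rep0$mean_error)
  expect_lte(rep0$mean_error, rep0$max_error)
})

test_that("Hausdorff is invariant under a common rigid transform", {
  a <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 2)
  b <- mesh_box(c(0.5, 0, 0), c(2, 1, 1))
  r1 <- hausdorff(a, b, n_samples = 2000, seed = 5)
  q <- neurofil:::quat_from_axis_angle(c(1, 2, 3), 1.1)
  tr <- c(4, -2, 7)
  a2 <- a; a2$vertices <- sweep(neurofil:::quat_rotate(q, a$vertices), 2, tr, "+")
  b2 <- b; b2$vertices <- sweep(neurofil:::quat_rotate(q, b$vertices), 2, tr, "+")
  r2 <- hausdorff(a2, b2, n_samples = 2000, seed = 5)
  expect_equal(r2$directed_ab, r1$directed_ab, tolerance = 1e-6)
  expect_equal(r2$mean_error, r1$mean_error, tolerance = 1e-6)
})

test_that("distance coloring maps the ramp endpoints to blue and red", {
  a <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 1)
  b <- mesh_icosphere(c(0.5, 0, 0), 1, subdiv = 2)
  rep1 <- hausdorff(a, b, n_samples = nrow(a$vertices), seed = 1)
  p <- tempfile(fileext = ".ply")
  color_by_distance(a, rep1, p)
  m <- read_ply(p)
  cols <- attr(m, "vertex_colors")
  d <- rep1$vertex_distances
  expect_equal(unname(cols[which.min(d), ]), c(0, 0, 255))
  expect_equal(unname(cols[which.max(d), ]), c(255, 0, 0))

  # uniform distances: a single color
  repu <- hausdorff(a, a, n_samples = nrow(a$vertices), seed = 1)
  color_by_distance(a, repu, p)
  cu <- attr(read_ply(p), "vertex_colors")
  expect_identical(nrow(unique(cu)), 1L)

  # widened bounds: no vertex reaches the red endpoint
  color_by_distance(a, rep1, p, ramp_bounds = c(0, 2 * max(d)))
  cw <- attr(read_ply(p), "vertex_colors")
  expect_true(all(cw[, 1] < 255))
})
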