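octo <- function(r, z) {
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  cbind(r * cos(ang), r * sin(ang), z)
}

test_that("the hull of two stacked unit squares is the unit cube", {
  cs <- contour_stack(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0),
                           cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 1)))
  h <- soma_from_contours(cs, remesh = FALSE)
  mm <- mesh_metrics(h)
  expect_equal(mm$volume, 1, tolerance = 1e-12)
  expect_equal(mm$surface_area, 6, tolerance = 1e-12)
  expect_true(is_watertight(h))
})

test_that("hull volume of stacked octagons is bounded by the sphere", {
  r <- 5
  zs <- r * c(-0.8, -0.4, 0, 0.4, 0.8)
  cs <- contour_stack(lapply(zs, function(z) octo(sqrt(r^2 - z^2), z)))
  h <- soma_from_contours(cs, remesh = FALSE)
  vol <- mesh_metrics(h)$volume
  expect_lt(vol, 4 / 3 * pi * r^3)
  # at least the volume of the inscribed double frustum stack (brute force)
  frustum <- function(r1, r2, h_) pi * h_ / 3 * (r1^2 + r1 * r2 + r2^2)
  radii <- sqrt(r^2 - zs^2) * cos(pi / 8) # octagon inradius
  lower <- sum(mapply(frustum, radii[-5], radii[-1], diff(zs)))
  expect_gt(vol, lower)
})

test_that("a single contour cannot make a 3D soma", {
  cs1 <- structure(list(contours = list(octo(3, 0))),
                   class = "contour_stack")
  expect_error(soma_from_contours(cs1), class = "neurofil_degenerate_hull")
  cs2 <- contour_stack(list(octo(3, 0), octo(2, 0))) # coplanar
  expect_error(soma_from_contours(cs2), class = "neurofil_degenerate_hull")
})

test_that("isotropic remeshing yields uniform edges on the hull surface", {
  cs <- contour_stack(list(octo(4, -6), octo(7, -3), octo(8, 0),
                           octo(7, 3), octo(4, 6)))
  hull <- soma_from_contours(cs, remesh = FALSE)
  m <- soma_from_contours(cs)
  target <- neurofil:::bbox_diagonal(hull) / 20
  E <- unique(neurofil:::mesh_edges(m))
  el <- sqrt(rowSums((m$vertices[E[, 1], ] - m$vertices[E[, 2], ])^2))
  expect_gte(mean(el >= 0.5 * target & el <= 1.5 * target), 0.95)
  expect_true(is_watertight(m))
  # convex within tolerance: no vertex outside any hull face plane
  nrm <- neurofil:::face_normals(hull)
  off <- rowSums(nrm * hull$vertices[hull$faces[, 1], ])
  viol <- max(apply(m$vertices, 1, function(p) max(nrm %*% p - off)))
  expect_lt(viol, 1e-6 * neurofil:::bbox_diagonal(hull))
})

test_that("sphere soma from neurite starts uses barycenter and min distance", {
  s1 <- soma_sphere_from_neurites(rbind(c(1, 0, 0), c(-1, 0, 0),
                                        c(0, 1, 0), c(0, -1, 0)))
  expect_equal(s1$center, c(0, 0, 0))
  expect_equal(s1$radius, 1)

  s2 <- soma_sphere_from_neurites(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)))
  expect_equal(s2$center, c(0, 1 / 3, 0))
  expect_equal(s2$radius, 2 / 3)

  expect_error(soma_sphere_from_neurites(rbind(c(1, 0, 0))),
               class = "neurofil_insufficient_data")
})

test_that("neurite starts inside the soma are trimmed to the surface", {
  nd <- data.frame(id = 1:4, parent = c(0L, 1L, 2L, 3L),
                   x = c(1, 3, 6, 9), y = 0, z = 0,
                   radius = c(1, 1, 0.8, 0.6), part = "basal",
                   stringsAsFactors = FALSE)
  t2 <- trim_neurite_starts(neuron_tracing(nd), soma_sphere(c(0, 0, 0), 5))
  expect_identical(nrow(t2$nodes), 3L)
  expect_equal(t2$nodes$x, c(5, 6, 9), tolerance = 1e-9)
  # radius linearly interpolated on the 3 -> 6 segment at x = 5
  expect_equal(t2$nodes$radius[1], 1 + (2 / 3) * (0.8 - 1), tolerance = 1e-9)

  outside <- chain_tracing(3)
  outside$nodes$x <- outside$nodes$x + 10
  t3 <- trim_neurite_starts(outside, soma_sphere(c(0, 0, 0), 5))
  expect_equal(t3$nodes$x, outside$nodes$x)

  inside <- chain_tracing(3, spacing = 0.5)
  expect_error(trim_neurite_starts(inside, soma_sphere(c(0, 0, 0), 5)),
               class = "neurofil_neurite_swallowed")
})

test_that("soma cross-sections recover analytic contours", {
  cs <- soma_to_contours(soma_sphere(c(0, 0, 0), 2), n_levels = 5)
  eq <- cs$contours[[3]] # central level sits at the equator
  rr <- sqrt(rowSums(eq[, 1:2]^2))
  expect_lt(max(abs(rr - 2)) / 2, 0.005)
  # counterclockwise seen from +z: positive shoelace area
  shoelace <- sum(eq[, 1] * c(eq[-1, 2], eq[1, 2]) -
                    c(eq[-1, 1], eq[1, 1]) * eq[, 2]) / 2
  expect_gt(shoelace, 0)

  cc <- soma_to_contours(soma_mesh(mesh_box(c(0, 0, 0), c(1, 1, 1))),
                         n_levels = 3)
  sec <- cc$contours[[2]]
  expect_equal(range(sec[, 1]), c(0, 1), tolerance = 1e-9)
  expect_equal(range(sec[, 2]), c(0, 1), tolerance = 1e-9)

  expect_error(soma_to_contours(soma_sphere(c(0, 0, 0), 2), n_levels = 2),
               class = "neurofil_bad_argument")
})

test_that("soma-to-contour round trip preserves section areas within 5%", {
  cs <- contour_stack(list(octo(4, -6), octo(7, -3), octo(8, 0),
                           octo(7, 3), octo(4, 6)))
  m <- soma_from_contours(cs)
  back <- soma_to_contours(soma_mesh(m), n_levels = 5)
  poly_area <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  mid_in <- poly_area(octo(8, 0))
  mid_out <- poly_area(back$contours[[3]])
  expect_lt(abs(mid_out - mid_in) / mid_in, 0.05)
})

test_that("soma deformation pulls the nearest vertex and stays closed", {
  sm <- mesh_icosphere(c(0, 0, 0), 1, subdiv = 2)
  expect_identical(deform_soma_to_neurites(sm, rbind(c(3, 0, 0)), 0),
                   sm)
  dm <- deform_soma_to_neurites(sm, rbind(c(3, 0, 0)), 1)
  expect_lt(min(sqrt(rowSums(sweep(dm$vertices, 2, c(3, 0, 0))^2))), 1e-9)
  expect_true(is_watertight(dm))
})
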