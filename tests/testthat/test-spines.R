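test_that("a posed cylinder canonicalizes to the origin-based +Y pose", {
  # cylinder of height 2, base disc centered at (5,5,5), outward base
  # normal (0,0,-1): body extends toward +z
  cyl <- mesh_revolve(c(0, 2), c(0.4, 0.4), n_seg = 24)
  q <- neurofil:::quat_between(c(0, 1, 0), c(0, 0, 1))
  cyl$vertices <- sweep(neurofil:::quat_rotate(q, cyl$vertices), 2,
                        c(5, 5, 5), "+")
  rec <- canonicalize_spine(cyl)
  V <- rec$canonical_mesh$vertices
  expect_lt(max(abs(colMeans(V[abs(V[, 2]) < 1e-9, , drop = FALSE])[c(1, 3)])),
            1e-6)
  expect_equal(range(V[, 2]), c(0, 2), tolerance = 1e-9)
  back <- restore_spine_pose(rec)
  expect_lt(max(abs(back$vertices - cyl$vertices)), 1e-6)
})

test_that("an already-canonical spine gets the identity pose", {
  m <- mesh_revolve(c(0, 1.5), c(0.3, 0.3), n_seg = 20)
  rec <- canonicalize_spine(m)
  expect_lt(max(abs(rec$world_translation)), 1e-9)
  expect_equal(abs(rec$world_rotation[1]), 1, tolerance = 1e-9)
})

test_that("a closed sphere has no flat base", {
  expect_error(canonicalize_spine(mesh_icosphere(c(0, 0, 0), 1, subdiv = 2)),
               class = "neurofil_no_base")
})

test_that("placement moves the canonical spine onto the line", {
  m <- mesh_revolve(c(0, 3), c(0.5, 0.5), n_seg = 20)
  rec <- canonicalize_spine(m)
  p1 <- place_spine(rec, spine_line(c(0, 0, 0), c(0, 3, 0)))
  expect_equal(range(p1$vertices[, 2]), c(0, 3), tolerance = 1e-9)

  d <- c(1, 1, 1) / sqrt(3)
  ln <- spine_line(c(2, -1, 4), c(2, -1, 4) + 2 * d)
  p2 <- place_spine(rec, ln, scale_to_line = TRUE)
  # transform-composition oracle: the canonical tip (0, h, 0) must land on
  # insertion + 2 * direction
  heights <- as.vector((p2$vertices -
                          matrix(ln$insertion, nrow(p2$vertices), 3,
                                 byrow = TRUE)) %*% d)
  expect_equal(max(heights), 2, tolerance = 1e-6)

  expect_error(spine_line(c(1, 1, 1), c(1, 1, 1)),
               class = "neurofil_bad_spine_line")
})

test_that("place after canonicalize restores the measured geometry", {
  for (seed in 1:3) {
    sp <- generate_spine_mesh(seed)
    rec <- canonicalize_spine(sp)
    h <- max(rec$canonical_mesh$vertices[, 2])
    dir_w <- as.vector(neurofil:::quat_rotate(rec$world_rotation,
                                              matrix(c(0, 1, 0), 1)))
    ln <- spine_line(rec$world_translation, rec$world_translation + h * dir_w)
    back <- place_spine(rec, ln)
    expect_lt(max(abs(back$vertices - sp$vertices)), 1e-6)
  }
})

test_that("spines attach to the nearest tracing point within the threshold", {
  t <- chain_tracing(5)
  near <- spine_line(c(1, 0.05, 0), c(1, 1, 0))
  t1 <- attach_spines(t, list(near), 0.1)
  expect_identical(nrow(t1$spines), 1L)
  expect_identical(t1$spines$parent_id, 2L)
  expect_equal(t1$spines$y, 1)

  far <- spine_line(c(1, 5, 0), c(1, 6, 0))
  expect_warning(t2 <- attach_spines(t, list(far), 0.1), "unattached")
  expect_identical(nrow(t2$spines), 0L)

  # equidistant between nodes 2 and 3: earliest depth-first point wins
  mid <- spine_line(c(1.5, 0.05, 0), c(1.5, 1, 0))
  t3 <- attach_spines(t, list(mid), 1)
  expect_identical(t3$spines$parent_id, 2L)
  # annotation only: the neurite table is untouched
  expect_identical(t3$nodes, t$nodes)
})

test_that("length-file rows map head to end and last point to insertion", {
  out <- spines_from_length_file(list(rbind(c(0, 2, 0), c(0, 0, 0))))
  expect_equal(out[[1]]$insertion, c(0, 0, 0))
  expect_equal(out[[1]]$end, c(0, 2, 0))

  three <- spines_from_length_file(list(rbind(c(5, 5, 5), c(4, 4, 4),
                                              c(3, 3, 3))))
  expect_equal(three[[1]]$insertion, c(3, 3, 3))
  expect_equal(three[[1]]$end, c(5, 5, 5))

  expect_warning(
    none <- spines_from_length_file(list(rbind(c(1, 1, 1), c(1, 1, 1)))),
    "skipped")
  expect_length(none, 0L)
})

test_that("spine sampling is seeded, Poisson-distributed and tangential", {
  t <- generate_neuron(41, n_bifurcations = 3)
  expect_length(sample_spine_positions(t, 0), 0L)
  a <- sample_spine_positions(t, 0.5, seed = 9)
  b <- sample_spine_positions(t, 0.5, seed = 9)
  expect_identical(a, b)
  lens <- vapply(a, function(l) sqrt(sum((l$end - l$insertion)^2)),
                 numeric(1))
  expect_true(all(lens >= 0.5 & lens <= 2.5))

  branches <- iter_branches(t)
  total <- sum(vapply(branches, function(bb)
    sum(sqrt(rowSums((bb$xyz[-1, , drop = FALSE] -
                        bb$xyz[-npoints(bb), , drop = FALSE])^2))),
    numeric(1)))
  counts <- vapply(1:200, function(s)
    length(sample_spine_positions(t, 1, seed = s)), numeric(1))
  bounds <- qpois(c(0.005, 0.995), lambda = total)
  expect_gte(mean(counts >= bounds[1] & counts <= bounds[2]), 0.97)
  expect_lt(abs(mean(counts) - total), 4 * sqrt(total / 200))
})

test_that("verbatim records keep the identity pose and are non-reusable", {
  sp <- generate_spine_mesh(11)
  rec <- spine_record_verbatim(sp, "isosurface")
  expect_false(rec$reusable)
  expect_identical(restore_spine_pose(rec)$vertices, sp$vertices)
  sd <- file.path(tempdir(), "spine-store-verbatim")
  unlink(sd, recursive = TRUE)
  id <- spine_store_put(sd, rec)
  expect_false(spine_store_get(sd, id)$reusable)
})

test_that("the spine store round-trips records through OBJ + sidecar", {
  sd <- file.path(tempdir(), "spine-store-test")
  unlink(sd, recursive = TRUE)
  recs <- lapply(1:3, function(s)
    canonicalize_spine(generate_spine_mesh(s), source_tag = sprintf("s%d", s)))
  ids <- vapply(recs, function(r) spine_store_put(sd, r), character(1))
  expect_length(unique(ids), 3L)
  expect_identical(spine_store_list(sd), sort(ids))

  got <- spine_store_get(sd, ids[2])
  expect_lt(max(abs(got$canonical_mesh$vertices -
                      recs[[2]]$canonical_mesh$vertices)), 1e-5)
  expect_equal(got$world_rotation, recs[[2]]$world_rotation,
               tolerance = 1e-12)
  expect_equal(got$metrics$volume, recs[[2]]$metrics$volume,
               tolerance = 1e-12)
  expect_identical(got$source_tag, "s2")

  csvp <- spine_store_metrics_csv(sd)
  tab <- read.csv(csvp)
  expect_identical(nrow(tab), 3L)

  file.remove(file.path(sd, paste0(ids[1], ".json")))
  expect_error(spine_store_get(sd, ids[1]), class = "neurofil_store_error")
})
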