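test_that("the neuron generator is deterministic and counts branches", {
  a <- generate_neuron(7, n_bifurcations = 3)
  b <- generate_neuron(7, n_bifurcations = 3)
  expect_identical(a$nodes, b$nodes)

  expect_length(iter_branches(generate_neuron(8, n_bifurcations = 0)), 1L)
  expect_length(iter_branches(generate_neuron(9, n_bifurcations = 5)), 11L)
})

test_that("generated trees respect the inter-branch clearance", {
  t <- generate_neuron(10, n_bifurcations = 4, step = 1)
  branches <- iter_branches(t)
  # points on different branches, both far from any bifurcation, keep
  # >= 4 * step clearance
  bif_pts <- as.matrix(t$nodes[neurofil:::n_children(t) >= 2,
                               c("x", "y", "z"), drop = FALSE])
  for (i in seq_along(branches)) {
    for (j in seq_len(i - 1)) {
      A <- branches[[i]]$xyz
      B <- branches[[j]]$xyz
      keepA <- apply(neurofil:::cross_dist2(A, bif_pts), 1,
                     function(d) min(d) > 36)
      keepB <- apply(neurofil:::cross_dist2(B, bif_pts), 1,
                     function(d) min(d) > 36)
      if (any(keepA) && any(keepB)) {
        dmin <- sqrt(min(neurofil:::cross_dist2(A[keepA, , drop = FALSE],
                                                B[keepB, , drop = FALSE])))
        expect_gte(dmin, 4)
      }
    }
  }
})

test_that("fragmentation without inversion concatenates to the branch", {
  t <- generate_neuron(11, n_bifurcations = 0)
  branch <- iter_branches(t)[[1]]
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 12, invert_prob = 0)
  frags <- read_filament_vrml(f)
  centers <- do.call(rbind, lapply(frags, function(fr)
    fragment_to_polyline(fr)$xyz))
  # drop the one-slice overlap duplicates: consecutive fragment starts
  # repeat the previous fragment's last point
  dedup <- centers[c(TRUE, rowSums((centers[-1, , drop = FALSE] -
                                      centers[-nrow(centers), ,
                                              drop = FALSE])^2) > 1e-12), ]
  expect_equal(dedup, unname(branch$xyz), tolerance = 1e-6)
})

test_that("emitted files have 17-aligned coordinates and repeated suffixes", {
  t <- generate_neuron(13, n_bifurcations = 3)
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 14)
  geoms <- neurofil:::read_vrml_geometries(f)
  expect_true(all(vapply(geoms, function(g) nrow(g$coordinates), integer(1))
                  %% 17L == 0L))
  ids <- vapply(geoms, `[[`, character(1), "source_identifier")
  expect_gt(sum(duplicated(ids)), 0L) # suffixes deliberately repeat
})

test_that("the emitted dialect round-trips to the ground-truth topology", {
  t <- generate_neuron(15, n_bifurcations = 5)
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 16, invert_prob = 0.3, shuffle = TRUE)
  tr <- vrml_to_tracing(f, soma_source = "none")
  expect_same_topology(t, tr)
})

test_that("generated spine meshes are watertight with the right base", {
  for (seed in 1:3) {
    sp <- generate_spine_mesh(seed, neck_radius = 0.22)
    expect_true(is_watertight(sp))
    base <- neurofil:::detect_flat_base(sp)
    disc <- pi * 0.22^2
    expect_lt(abs(base$area - disc) / disc, 0.05)
    # canonicalization inverts the recorded pose
    rec <- canonicalize_spine(sp)
    pose <- attr(sp, "pose")
    expect_lt(max(abs(rec$world_translation - pose$translation)), 1e-5)
    axis_pose <- as.vector(neurofil:::quat_rotate(pose$rotation,
                                                  matrix(c(0, 1, 0), 1)))
    axis_rec <- as.vector(neurofil:::quat_rotate(rec$world_rotation,
                                                 matrix(c(0, 1, 0), 1)))
    expect_lt(max(abs(axis_pose - axis_rec)), 1e-5)
  }
  expect_identical(generate_spine_mesh(4)$vertices,
                   generate_spine_mesh(4)$vertices)
})

test_that("spine mesh volume tracks the analytic profile volume", {
  sp <- generate_spine_mesh(5, n_seg = 48)
  vol <- mesh_metrics(sp)$volume
  truth <- attr(sp, "analytic_volume")
  expect_lt(abs(vol - truth) / truth, 0.05) # azimuthal discretization
})

test_that("broken spines are reproducible with a holed component", {
  a <- generate_broken_spine(6)
  b <- generate_broken_spine(6)
  expect_identical(lapply(a, `[[`, "vertices"), lapply(b, `[[`, "vertices"))
  expect_length(a, 3L)
  wt <- vapply(a, is_watertight, logical(1))
  expect_identical(sum(!wt), 1L) # exactly the holed head
  expect_gt(attr(a, "analytic_volume"), 0)
})
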